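# Internal logistic-regression helpers shared by the test modules.
# Thin wrappers around stats::glm.fit (IRLS) with explicit separation
# detection: diverging coefficients with fitted probabilities pinned at
# 0/1 indicate (quasi-)complete separation, for which Wald/LRT inference
# is meaningless.

.logistic_fit <- function(x, d, epsilon = 1e-10, maxit = 50) {
  fit <- suppressWarnings(
    stats::glm.fit(x, d, family = stats::binomial(),
                   control = stats::glm.control(epsilon = epsilon, maxit = maxit))
  )
  mu <- fit$fitted.values
  separated <- any(mu < 1e-8 | mu > 1 - 1e-8) && max(abs(fit$coefficients)) > 10
  list(coefficients = fit$coefficients,
       fitted = mu,
       deviance = fit$deviance,
       converged = fit$converged,
       iterations = fit$iter,
       separated = separated,
       x = x)
}

# Wald p-value for one coefficient (by column index) of a logistic fit
.wald_pvalue <- function(fit, index) {
  v <- fit$fitted * (1 - fit$fitted)
  xv <- fit$x * v
  info <- crossprod(fit$x, xv)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov)) return(NA_real_)
  se <- sqrt(diag(cov))[index]
  z <- fit$coefficients[index] / se
  2 * stats::pnorm(-abs(z))
}
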
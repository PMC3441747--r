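#' Fit the covariate-only null logistic model
#'
#' Maximum-likelihood logistic regression of disease status on the
#' covariates alone (intercept always included), fitted by iteratively
#' reweighted least squares. This is the null model of the kernel machine
#' score test: the SNP-set effect enters only through the residuals
#' `D - mu_hat`.
#'
#' @param d binary outcome vector (1 = affected, 0 = unaffected).
#' @param x optional numeric covariate matrix (n x m), without intercept.
#' @return Object of class `null_model_fit` with `coefficients`,
#'   `fitted_probs`, `variance_weights` (`mu(1-mu)`), `design` (n x (m+1)
#'   including the intercept), `converged`, `iterations`.
#' @export
fit_null_logistic <- function(d, x = NULL) {
  d <- as.numeric(d)
  if (!all(d %in% c(0, 1))) stop("outcome must be coded 0/1", call. = FALSE)
  if (length(unique(d)) < 2)
    stop("degenerate outcome: both classes must be present", call. = FALSE)
  n <- length(d)
  design <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(x)) {
    x <- as.matrix(x)
    if (nrow(x) != n) stop("covariate rows must match outcome length", call. = FALSE)
    if (is.null(colnames(x))) colnames(x) <- paste0("cov", seq_len(ncol(x)))
    design <- cbind(design, x)
  }
  if (n <= ncol(design))
    stop("need more samples than covariates", call. = FALSE)
  fit <- .logistic_fit(design, d, epsilon = 1e-12, maxit = 25)
  if (fit$separated)
    stop("complete separation detected in the null logistic fit", call. = FALSE)
  mu <- fit$fitted
  score <- max(abs(crossprod(design, d - mu)))
  structure(list(coefficients = fit$coefficients,
                 fitted_probs = mu,
                 variance_weights = mu * (1 - mu),
                 design = design,
                 outcome = d,
                 converged = fit$converged && score < 1e-6,
                 iterations = fit$iterations),
            class = "null_model_fit")
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf("null_model_fit: n = %d, %d coefficient(s), converged = %s\n",
              nrow(x$design), length(x$coefficients), x$converged))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Kernel machine score statistic
#'
#' `Q = (D - mu_hat)' K (D - mu_hat)`, the variance-component score
#' statistic for the hypothesis that the kernel random-effect variance is
#' zero.
#'
#' @param k a `kernel_matrix` (or internal low-rank factor).
#' @param fit a [fit_null_logistic()] result sharing the sample order.
#' @return nonnegative scalar.
#' @export
score_statistic <- function(k, fit) {
  stopifnot(inherits(fit, "null_model_fit"))
  d_resid <- fit$outcome - fit$fitted_probs
  if (inherits(k, "kernel_factor")) {
    if (nrow(k$phi) != length(d_resid))
      stop("kernel and null fit dimensions differ", call. = FALSE)
    return(sum(crossprod(k$phi, d_resid)^2))
  }
  stopifnot(inherits(k, "kernel_matrix"))
  if (nrow(k$values) != length(d_resid))
    stop("kernel and null fit dimensions differ", call. = FALSE)
  drop(crossprod(d_resid, k$values %*% d_resid))
}

#' Null eigenvalues of the kernel score statistic
#'
#' Under the null, `Q` is distributed as `sum_i lambda_i chi2_1` with
#' `lambda_i` the eigenvalues of `P0^{1/2} K P0^{1/2}`, where
#' `P0 = V - V X (X' V X)^{-1} X' V` and `V = diag(mu(1-mu))` come from the
#' null fit. For kernels with an exact factorization `K = Phi Phi'`
#' (linear family always; IBS with integer dosages) the identical nonzero
#' spectrum is obtained from the much smaller matrix `Phi' P0 Phi`.
#' Negative numerical eigenvalues below `1e-10 * max` are truncated to 0.
#'
#' @param k a `kernel_matrix` or internal kernel factor.
#' @param fit a [fit_null_logistic()] result.
#' @return numeric vector of nonnegative eigenvalues (descending).
#' @export
null_eigenvalues <- function(k, fit) {
  stopifnot(inherits(fit, "null_model_fit"))
  v <- fit$variance_weights
  x <- fit$design
  xv <- x * v
  xtvx_inv <- solve(crossprod(x, xv))
  if (inherits(k, "kernel_factor")) {
    phi <- k$phi
    if (nrow(phi) != length(v)) stop("dimension mismatch", call. = FALSE)
    pv <- crossprod(phi, phi * v)
    pvx <- crossprod(phi, xv)
    a <- pv - pvx %*% xtvx_inv %*% t(pvx)
  } else {
    stopifnot(inherits(k, "kernel_matrix"))
    km <- k$values
    if (nrow(km) != length(v)) stop("dimension mismatch", call. = FALSE)
    p0 <- diag(v) - xv %*% xtvx_inv %*% t(xv)
    e0 <- eigen((p0 + t(p0)) / 2, symmetric = TRUE)
    pos <- pmax(e0$values, 0)
    p0h <- e0$vectors %*% (sqrt(pos) * t(e0$vectors))
    a <- p0h %*% km %*% p0h
  }
  vals <- eigen((a + t(a)) / 2, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(vals, 0)
  vals[vals < 1e-10 * mx] <- 0
  sort(vals, decreasing = TRUE)
}

#' Tail probability of a mixture of chi-square(1) variables
#'
#' Computes `P(sum_i lambda_i chi2_1,i > q)` by numerical inversion of the
#' characteristic function (Davies-type midpoint integration of the Imhof
#' inversion integral, with aliasing and truncation error control; target
#' accuracy 1e-6). If the inversion fails to converge or returns a
#' non-positive value, a Liu-type four-moment chi-square approximation is
#' used instead and flagged as `method = "moment"`. P-values are floored
#' at 1e-15.
#'
#' @param q nonnegative scalar (the observed statistic).
#' @param lambdas vector of nonnegative mixture weights.
#' @param accuracy target absolute accuracy of the inversion.
#' @return list with `p_value` and `method` (`"davies"` or `"moment"`).
#' @export
pvalue_mixture_chisq <- function(q, lambdas, accuracy = 1e-6) {
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q < 0)
    stop("q must be a nonnegative scalar", call. = FALSE)
  lam <- lambdas[is.finite(lambdas)]
  mx <- if (length(lam)) max(lam) else 0
  lam <- lam[lam > 1e-10 * max(mx, 1e-300)]
  if (length(lam) == 0) {
    if (q <= 1e-8) return(list(p_value = 1, method = "davies"))
    stop("all mixture weights are zero but q > 0", call. = FALSE)
  }
  if (q == 0) return(list(p_value = 1, method = "davies"))
  p <- .davies_inversion(q / mx, lam / mx, accuracy)
  method <- "davies"
  if (is.na(p) || p <= 0) {
    p <- .liu_moment_pvalue(q, lam)
    method <- "moment"
  }
  list(p_value = max(min(p, 1), 1e-15), method = method)
}

# Midpoint-rule inversion of
#   P(Q > q) = 1/2 + (1/pi) Int_0^inf sin(theta(u)) / (u rho(u)) du,
#   theta(u) = (sum_j atan(l_j u) - q u) / 2,
#   rho(u)   = prod_j (1 + l_j^2 u^2)^(1/4).
# Step chosen so the aliasing error P(Q > q + 2*pi/step) is negligible;
# the sum stops when both an oscillation (integration-by-parts) and an
# absolute envelope bound on the remaining tail fall below the target.
# Returns NA on non-convergence.
.davies_inversion <- function(q, lam, accuracy) {
  s1 <- sum(lam)
  s2 <- sum(lam^2)
  cut <- q + s1 + 2 * sqrt(2 * s2) + 100   # lambda_max is 1 after scaling
  step <- 2 * pi / cut
  acc_stop <- accuracy * 0.01
  total <- 0
  k0 <- 0
  chunk <- 2048L
  kmax <- 8e6
  lam2 <- lam^2
  nl <- length(lam)
  repeat {
    u <- (k0 + seq_len(chunk) - 0.5) * step
    ang <- 0.5 * (.colSums(atan(lam * rep(u, each = nl)), nl, chunk) - q * u)
    lrho <- 0.25 * .colSums(log1p(lam2 * rep(u * u, each = nl)), nl, chunk)
    total <- total + sum(sin(ang) * exp(-lrho) / u)
    k0 <- k0 + chunk
    if (chunk < 65536L) chunk <- chunk * 2L
    uend <- k0 * step
    env <- exp(-0.25 * sum(log1p(lam2 * uend^2))) / (pi * uend)
    tail_osc <- 4 * env / max(q, step)
    peff <- sum(lam * uend > 1)
    tail_abs <- if (peff >= 1) env * uend * 2 / peff else Inf
    if (min(tail_osc, tail_abs) < acc_stop) break
    if (k0 >= kmax) return(NA_real_)
  }
  0.5 + (step / pi) * total
}

# Liu-Tang-Zhang four-moment chi-square approximation (central case)
.liu_moment_pvalue <- function(q, lam) {
  c1 <- sum(lam); c2 <- sum(lam^2); c3 <- sum(lam^3); c4 <- sum(lam^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- c2^3 / c3^2
  }
  tstar <- (q - c1) / sqrt(2 * c2)
  qq <- tstar * sqrt(2 * (l + 2 * delta)) + (l + delta)
  stats::pchisq(qq, df = l, ncp = delta, lower.tail = FALSE)
}

#' Logistic kernel machine score test for a SNP set
#'
#' Composes the null covariate-only logistic fit, kernel construction,
#' score statistic, null eigenvalues, and the mixture-of-chi-square tail
#' probability. For linear-family kernels (and IBS kernels on integer
#' dosages) the eigenvalues are computed through the exact low-rank
#' factorization, which is much cheaper than the n x n route; set
#' `path = "dense"` to force the direct computation.
#'
#' @param ds an aligned, imputed `snpset_dataset`; only typed SNPs are used.
#' @param spec a [kernel_spec()].
#' @param path `"auto"` (low-rank factor when exact) or `"dense"`.
#' @param use_typed_only restrict to SNPs with `typed_mask` (default TRUE).
#' @return Object of class `lkm_result`: `q_statistic`, `eigenvalues`,
#'   `p_value`, `pvalue_method`, `spec`, `n`.
#' @export
lkm_test <- function(ds, spec = kernel_spec("linear"),
                     path = c("auto", "dense"), use_typed_only = TRUE) {
  stopifnot(inherits(ds, "snpset_dataset"))
  path <- match.arg(path)
  g <- ds$genotypes
  if (use_typed_only && !all(g$typed_mask)) g <- .subset_snps(g, g$typed_mask)
  fit <- fit_null_logistic(ds$phenotypes$disease, ds$phenotypes$covariates)
  kern <- if (path == "auto") .kernel_factor(g, spec) else NULL
  if (is.null(kern)) kern <- compute_kernel(g, spec)
  q <- score_statistic(kern, fit)
  lambdas <- null_eigenvalues(kern, fit)
  if (all(lambdas <= 0)) {
    pv <- list(p_value = 1, method = "davies")
  } else {
    pv <- pvalue_mixture_chisq(q, lambdas)
  }
  structure(list(q_statistic = q,
                 eigenvalues = lambdas[lambdas > 0],
                 p_value = pv$p_value,
                 pvalue_method = pv$method,
                 spec = spec,
                 n = length(ds$phenotypes$samples)),
            class = "lkm_result")
}

#' @export
print.lkm_result <- function(x, ...) {
  cat(sprintf("Logistic kernel machine test (%s kernel)\n", x$spec$name))
  cat(sprintf("  n = %d, Q = %.4g, %d nonzero eigenvalue(s)\n",
              x$n, x$q_statistic, length(x$eigenvalues)))
  cat(sprintf("  p-value = %.4g (%s)\n", x$p_value, x$pvalue_method))
  invisible(x)
}

# restrict a genotype_matrix to a logical/integer subset of SNPs
.subset_snps <- function(g, keep) {
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  snp_ids = g$snps$snp_id[keep],
                  positions = g$snps$position[keep],
                  samples = g$samples,
                  typed_mask = g$typed_mask[keep])
}
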
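test_that("intercept-only null fit recovers the case fraction", {
  d <- c(rep(1, 40), rep(0, 60))
  fit <- fit_null_logistic(d)
  expect_equal(unname(fit$fitted_probs), rep(0.4, 100), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[1]), log(0.4 / 0.6), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("one binary covariate gives the saturated 2x2 cell fit", {
  # closed form: fitted probability in each covariate cell equals the
  # observed case fraction of that cell
  x <- rep(c(0, 1), c(50, 50))
  d <- c(rep(1, 10), rep(0, 40), rep(1, 30), rep(0, 20))
  fit <- fit_null_logistic(d, cbind(x = x))
  expect_equal(unname(fit$fitted_probs[x == 0]), rep(0.2, 50), tolerance = 1e-6)
  expect_equal(unname(fit$fitted_probs[x == 1]), rep(0.6, 50), tolerance = 1e-6)
})

test_that("degenerate outcomes and separation are rejected", {
  expect_error(fit_null_logistic(rep(1, 20)), "degenerate")
  d <- rep(c(0, 1), each = 25)
  expect_error(fit_null_logistic(d, cbind(z = d)), "separation")
})

test_that("score statistic matches its quadratic form", {
  ds <- toy_dataset(n = 60, seed = 2)
  fit <- fit_null_logistic(ds$phenotypes$disease)
  r <- ds$phenotypes$disease - fit$fitted_probs
  # identity kernel: Q = sum of squared residuals
  k_id <- structure(list(values = diag(length(r)), spec = kernel_spec("linear")),
                    class = "kernel_matrix")
  expect_equal(score_statistic(k_id, fit), sum(r^2))
  # zero kernel: Q = 0
  k0 <- structure(list(values = matrix(0, length(r), length(r)),
                       spec = kernel_spec("linear")), class = "kernel_matrix")
  expect_equal(score_statistic(k0, fit), 0)
  # scaling the kernel scales Q but not the p-value
  k <- compute_kernel(ds$genotypes, kernel_spec("linear"))
  k5 <- k; k5$values <- 5 * k$values
  q1 <- score_statistic(k, fit); q5 <- score_statistic(k5, fit)
  expect_equal(q5, 5 * q1, tolerance = 1e-10)
  p1 <- pvalue_mixture_chisq(q1, null_eigenvalues(k, fit))$p_value
  p5 <- pvalue_mixture_chisq(q5, null_eigenvalues(k5, fit))$p_value
  expect_equal(p1, p5, tolerance = 1e-7)
})

test_that("null eigenvalues agree between the dense and factored routes", {
  # p = 1, intercept only: single nonzero eigenvalue vbar * sum((z-zbar)^2)
  z <- c(0, 1, 2, 1, 0, 2, 1, 1, 0, 2)
  d <- c(1, 0, 1, 0, 0, 1, 0, 1, 0, 1)
  g <- genotype_matrix(cbind(snp1 = z))
  ds <- align_samples(g, phenotype_table(g$samples, d))
  fit <- fit_null_logistic(d)
  vbar <- 0.5 * 0.5
  lam_fac <- null_eigenvalues(snpsetr:::.kernel_factor(g, kernel_spec("linear")), fit)
  lam_dense <- null_eigenvalues(compute_kernel(g, kernel_spec("linear")), fit)
  expect_equal(lam_fac[1], vbar * sum((z - mean(z))^2), tolerance = 1e-8)
  expect_equal(lam_fac[1], lam_dense[1], tolerance = 1e-8)
  # zero kernel: all eigenvalues zero
  k0 <- structure(list(values = matrix(0, 10, 10), spec = kernel_spec("linear")),
                  class = "kernel_matrix")
  expect_true(all(null_eigenvalues(k0, fit) == 0))
})

test_that("duplicating a SNP column rescales but does not grow the spectrum rank", {
  ds <- toy_dataset(n = 80, freqs = c(0.3, 0.4), seed = 3)
  fit <- fit_null_logistic(ds$phenotypes$disease)
  g1 <- ds$genotypes
  dup <- cbind(g1$dosages, dup1 = g1$dosages[, 1])
  g2 <- genotype_matrix(dup, samples = g1$samples)
  lam1 <- null_eigenvalues(snpsetr:::.kernel_factor(g1, kernel_spec("linear")), fit)
  lam2 <- null_eigenvalues(snpsetr:::.kernel_factor(g2, kernel_spec("linear")), fit)
  expect_equal(sum(lam1 > 1e-8), sum(lam2 > 1e-8))
})

test_that("mixture-of-chi-square tail matches chi-square and convolution oracles", {
  # single weight: exact chi-square(1) survival
  expect_equal(pvalue_mixture_chisq(3.841459, 1)$p_value, 0.0500,
               tolerance = 1e-4)
  expect_equal(pvalue_mixture_chisq(3.841459, 1)$p_value,
               pchisq(3.841459, 1, lower.tail = FALSE), tolerance = 1e-6)
  # two equal weights: chi-square(2)
  expect_equal(pvalue_mixture_chisq(5.991465, c(1, 1))$p_value, 0.0500,
               tolerance = 1e-4)
  # frozen values from an independent numerical-convolution oracle
  expect_equal(pvalue_mixture_chisq(5, c(2, 1))$p_value,
               0.186425080921, tolerance = 1e-6)
  expect_equal(pvalue_mixture_chisq(10, c(2, 1))$p_value,
               0.040054871614, tolerance = 1e-6)
  expect_equal(pvalue_mixture_chisq(1.5, c(0.7, 0.3))$p_value,
               0.217378451044, tolerance = 1e-6)
  expect_equal(pvalue_mixture_chisq(8, c(3, 1.5, 0.5))$p_value,
               0.1891121451, tolerance = 1e-6)
  # boundary contracts
  expect_equal(pvalue_mixture_chisq(0, c(1, 2))$p_value, 1)
  expect_equal(pvalue_mixture_chisq(0, c(0, 0))$p_value, 1)
  expect_error(pvalue_mixture_chisq(-1, 1), "nonnegative")
  expect_error(pvalue_mixture_chisq(3, c(0, 0)), "zero")
})

test_that("moment-matching fallback approximates the inversion", {
  lam <- c(2.5, 1, 0.4, 0.1)
  for (q in c(3, 8, 15)) {
    pd <- snpsetr:::.davies_inversion(q / 2.5, lam / 2.5, 1e-6)
    pm <- snpsetr:::.liu_moment_pvalue(q, lam)
    expect_lt(abs(pd - pm), 0.02)
  }
})

test_that("fast and dense kernel test paths agree to 1e-8", {
  for (seed in 1:3) {
    ds <- toy_dataset(n = 50, freqs = c(0.2, 0.35, 0.5, 0.15), seed = seed)
    for (nm in c("linear", "linear.weighted", "ibs", "ibs.weighted")) {
      a <- lkm_test(ds, kernel_spec(nm), path = "auto")
      b <- lkm_test(ds, kernel_spec(nm), path = "dense")
      expect_equal(a$p_value, b$p_value, tolerance = 1e-8)
      expect_equal(a$q_statistic, b$q_statistic, tolerance = 1e-8)
    }
  }
})

test_that("p-value is invariant under simultaneous sample relabeling", {
  ds <- toy_dataset(n = 60, seed = 8)
  p0 <- lkm_test(ds, kernel_spec("linear"))$p_value
  set.seed(21)
  perm <- sample(60)
  g2 <- genotype_matrix(ds$genotypes$dosages[perm, ],
                        samples = paste0("s", 1:60))
  ph2 <- phenotype_table(g2$samples, ds$phenotypes$disease[perm])
  p1 <- lkm_test(align_samples(g2, ph2), kernel_spec("linear"))$p_value
  expect_equal(p0, p1, tolerance = 1e-9)
})

test_that("a covariate orthogonal to outcome and genotypes leaves p unchanged", {
  ds <- toy_dataset(n = 80, seed = 13)
  p0 <- lkm_test(ds, kernel_spec("linear"))$p_value
  set.seed(99)
  raw <- rnorm(80)
  basis <- cbind(1, ds$phenotypes$disease, ds$genotypes$dosages)
  ortho <- raw - basis %*% solve(crossprod(basis), crossprod(basis, raw))
  ph2 <- phenotype_table(ds$genotypes$samples, ds$phenotypes$disease,
                         cbind(orth = drop(ortho)))
  p1 <- lkm_test(align_samples(ds$genotypes, ph2), kernel_spec("linear"))$p_value
  expect_lt(abs(p1 - p0), 1e-6)
})

test_that("null p-values are approximately uniform", {
  panel <- toy_panel(p = 8, rho = 0.6, m = 2000, seed = 31)
  pv <- vapply(1:300, function(r) {
    ds <- sample_case_control(panel, disease_model(), 100, 100, seed = 5000 + r)
    lkm_test(ds, kernel_spec("linear"))$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("constant genotypes yield p = 1 unweighted and an error when weighted", {
  g <- genotype_matrix(cbind(snp1 = rep(1, 40), snp2 = rep(2, 40)))
  d <- rep(c(0, 1), 20)
  ds <- align_samples(g, phenotype_table(g$samples, d))
  res <- lkm_test(ds, kernel_spec("linear"))
  expect_equal(res$p_value, 1)
  expect_error(lkm_test(ds, kernel_spec("linear.weighted")), "strictly")
})
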
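test_that("panel generation is deterministic and respects its spec", {
  spec <- ld_spec(list(list(snp_count = 6, rho = 0.5)), seed = 3)
  p1 <- generate_panel(spec, m = 500)
  p2 <- generate_panel(spec, m = 500)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_error(generate_panel(spec, m = 11), "m >= 2 p")
  expect_error(ld_spec(list(list(snp_count = 3, rho = 1))), "rho")
  expect_error(ld_spec(list(list(snp_count = 3, rho = 0.5)),
                       maf_range = c(0, 0.5)), "maf_range")
})

test_that("zero latent correlation yields near-independent SNPs", {
  spec <- ld_spec(list(list(snp_count = 10, rho = 0)),
                  maf_range = c(0.2, 0.5), seed = 5)
  pan <- generate_panel(spec, m = 50000)
  r2 <- pan$realized_r2
  expect_lt(mean(r2[upper.tri(r2)]), 0.01)
})

test_that("strong latent correlation yields strong allelic r-squared", {
  spec <- ld_spec(list(list(snp_count = 8, rho = 0.95)),
                  maf_range = c(0.3, 0.3), seed = 6)
  pan <- generate_panel(spec, m = 20000)
  r2 <- pan$realized_r2
  expect_gt(mean(r2[upper.tri(r2)]), 0.5)
})

test_that("genotype draws obey panel frequencies and Hardy-Weinberg", {
  pan <- toy_panel(p = 3, rho = 0.4, m = 2000, maf = c(0.2, 0.45), seed = 12)
  set.seed(77)
  z <- draw_genotypes(pan, 10000)
  f_panel <- pan$snp_records$coded_allele_freq
  f_draw <- colMeans(z) / 2
  se <- sqrt(f_panel * (1 - f_panel) / (2 * 10000))
  expect_true(all(abs(f_draw - f_panel) < 3 * se))
  # HW genotype proportions at each SNP within 3 SE
  for (j in 1:3) {
    f <- f_panel[j]
    expected <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    obs <- tabulate(z[, j] + 1, 3) / 10000
    expect_true(all(abs(obs - expected) <
                      3 * sqrt(expected * (1 - expected) / 10000) + 1e-3))
  }
})

test_that("a panel of identical haplotypes always yields doubled dosages", {
  path <- withr::local_tempfile(fileext = ".tsv")
  h <- c(1, 0, 1, 1, 0)
  tab <- data.frame(hap = paste0("h", 1:10),
                    matrix(rep(h, each = 10), 10, 5,
                           dimnames = list(NULL, paste0("snp", 1:5))),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  pan <- read_haplotype_panel(path)
  set.seed(1)
  z <- draw_genotypes(pan, 20)
  expect_true(all(t(z) == 2 * h))
})

test_that("disease probabilities follow the log-additive model", {
  pan <- toy_panel(seed = 14)
  # null: constant prevalence
  m0 <- disease_model(target_prevalence = 0.1)
  m0$beta0 <- calibrate_beta0(pan, m0)
  expect_equal(m0$beta0, qlogis(0.1))
  expect_equal(disease_prob(c(0, 1, 2, 0, 1), m0), 0.1)
  # each risk allele multiplies the odds by RR
  m1 <- disease_model(2, 1.2, beta0 = qlogis(0.1))
  z0 <- c(0, 0, 0, 0, 0); z2 <- c(0, 2, 0, 0, 0)
  odds <- function(p) p / (1 - p)
  expect_equal(odds(disease_prob(z2, m1)) / odds(disease_prob(z0, m1)),
               1.44, tolerance = 1e-12)
  # RR = 1 collapses to the null
  m2 <- disease_model(c(1, 3), c(1, 1), beta0 = qlogis(0.1))
  expect_equal(disease_prob(z2, m2), 0.1)
})

test_that("intercept calibration hits the target prevalence", {
  pan <- toy_panel(p = 4, rho = 0.5, m = 2000, seed = 15)
  mod <- disease_model(c(1, 3), c(1.3, 1.2), target_prevalence = 0.1)
  set.seed(31)
  b0 <- calibrate_beta0(pan, mod)
  expect_lt(b0, qlogis(0.1))      # risk alleles push prevalence up
  mod$beta0 <- b0
  set.seed(32)                     # fresh draws: self-consistency
  z <- draw_genotypes(pan, 100000)
  expect_lt(abs(mean(disease_prob(z, mod)) - 0.1), 0.002)
})

test_that("case-control sampling is deterministic and null-invariant", {
  pan <- toy_panel(p = 4, rho = 0.5, m = 2000, seed = 16)
  ds1 <- sample_case_control(pan, disease_model(), 300, 300, seed = 42)
  ds2 <- sample_case_control(pan, disease_model(), 300, 300, seed = 42)
  expect_dataset_equal(ds1, ds2)
  expect_equal(sum(ds1$phenotypes$disease), 300)
  # null model: case and control allele frequencies agree within 3 SE
  fcase <- colMeans(ds1$genotypes$dosages[ds1$phenotypes$disease == 1, ]) / 2
  fctrl <- colMeans(ds1$genotypes$dosages[ds1$phenotypes$disease == 0, ]) / 2
  fbar <- (fcase + fctrl) / 2
  se <- sqrt(fbar * (1 - fbar) * (1 / 600 + 1 / 600))
  expect_true(all(abs(fcase - fctrl) < 3 * se + 1e-8))
})

test_that("a causal risk allele is enriched in cases", {
  pan <- toy_panel(p = 3, rho = 0.2, m = 2000, maf = c(0.3, 0.4), seed = 18)
  mod <- disease_model(2, 1.5)
  diffs <- vapply(1:30, function(r) {
    ds <- sample_case_control(pan, mod, 150, 150, seed = 800 + r)
    mean(ds$genotypes$dosages[ds$phenotypes$disease == 1, 2]) -
      mean(ds$genotypes$dosages[ds$phenotypes$disease == 0, 2])
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.85)
  expect_gt(t.test(diffs, alternative = "greater")$p.value < 0.001, 0)
})

test_that("typed masking restricts the analysis set", {
  pan <- toy_panel(p = 6, seed = 19)
  ds <- sample_case_control(pan, disease_model(), 50, 50, seed = 2)
  mask <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  dsm <- mask_typed(ds, mask)
  expect_equal(ncol(dsm$genotypes$dosages), 3L)
  expect_equal(dsm$genotypes$snps$snp_id, paste0("snp", c(1, 3, 5)))
  # identity mask
  expect_dataset_equal(mask_typed(ds, rep(TRUE, 6)), ds)
  # the causal column can be masked away
  expect_false("snp2" %in% mask_typed(ds, mask)$genotypes$snps$snp_id)
  expect_error(mask_typed(ds, rep(FALSE, 6)), "no SNPs")
  expect_error(mask_typed(ds, mask[1:3]), "length")
})

test_that("median r-squared with the typed SNPs matches a direct computation", {
  pan <- toy_panel(p = 6, rho = 0.7, m = 5000, seed = 20)
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  direct <- stats::median(
    stats::cor(pan$haplotypes[, 5], pan$haplotypes[, c(1, 2, 3, 6)])^2)
  expect_equal(median_r2_with_typed(pan, 5, mask), direct)
  # a typed causal SNP is excluded from its own median
  m2 <- median_r2_with_typed(pan, 6, mask)
  expect_equal(m2, stats::median(stats::cor(pan$haplotypes[, 6],
                                            pan$haplotypes[, 1:3])^2))
  # independent block: near-zero tagging
  spec <- ld_spec(list(list(snp_count = 5, rho = 0.8),
                       list(snp_count = 1, rho = 0)), seed = 21)
  pan2 <- generate_panel(spec, m = 20000)
  expect_lt(median_r2_with_typed(pan2, 6, c(rep(TRUE, 5), FALSE)), 0.005)
})

test_that("haplotype panels round-trip through TSV", {
  pan <- toy_panel(p = 4, m = 200, seed = 22)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotypes_tsv(pan, path)
  pan2 <- read_haplotype_panel(path)
  expect_equal(unname(pan2$haplotypes), unname(pan$haplotypes))
  expect_equal(pan2$snp_records$maf, pan$snp_records$maf)
})
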
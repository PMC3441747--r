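# shared fixture builders (everything generated in code)

# small deterministic genotype matrix with given dosage columns
toy_genotypes <- function(cols, samples = NULL, typed_mask = NULL) {
  dos <- do.call(cbind, cols)
  colnames(dos) <- names(cols)
  genotype_matrix(dos, samples = samples, typed_mask = typed_mask)
}

# dataset with dosages drawn under HWE at given frequencies, outcome
# independent of genotype unless beta is supplied
toy_dataset <- function(n = 100, freqs = c(0.3, 0.4, 0.2), seed = 1,
                        beta = NULL, covariates = NULL) {
  set.seed(seed)
  dos <- sapply(freqs, function(f) stats::rbinom(n, 2, f))
  colnames(dos) <- paste0("snp", seq_along(freqs))
  eta <- qlogis(0.4)
  if (!is.null(beta)) eta <- eta + drop(dos %*% beta)
  if (!is.null(covariates)) eta <- eta + rowSums(covariates)
  d <- stats::rbinom(n, 1, plogis(eta))
  if (length(unique(d)) < 2) d[1:2] <- c(0, 1)
  g <- genotype_matrix(dos)
  ph <- phenotype_table(g$samples, d, covariates)
  align_samples(g, ph)
}

# tiny single-block panel for simulation tests
toy_panel <- function(p = 5, rho = 0.5, m = 1000, maf = c(0.2, 0.5), seed = 9) {
  generate_panel(ld_spec(list(list(snp_count = p, rho = rho)),
                         maf_range = maf, seed = seed), m = m)
}

expect_dataset_equal <- function(a, b) {
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$phenotypes$disease, b$phenotypes$disease)
}
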
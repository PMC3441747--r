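#' Standardize genotype dosages
#'
#' Rescales each SNP column to mean 0 and standard deviation 1 (n - 1
#' denominator). Zero-variance columns are dropped with a warning before
#' scaling, so the covariance of the result is the SNP correlation matrix.
#'
#' @param g a [genotype_matrix()] with no missing dosages.
#' @return numeric n x p' matrix (p' excludes constant SNPs), with the
#'   retained SNP ids as column names and the retained column indices in
#'   attribute `"kept"`.
#' @export
standardize_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  z <- g$dosages
  if (anyNA(z)) stop("missing dosages; run impute_missing() first", call. = FALSE)
  sds <- apply(z, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all SNP columns are constant", call. = FALSE)
  if (any(!keep))
    warning(sum(!keep), " constant SNP column(s) dropped before standardization: ",
            paste(g$snps$snp_id[!keep], collapse = ", "), call. = FALSE)
  zs <- scale(z[, keep, drop = FALSE])
  zs <- zs[, , drop = FALSE]
  attr(zs, "scaled:center") <- NULL
  attr(zs, "scaled:scale") <- NULL
  attr(zs, "kept") <- which(keep)
  zs
}

#' Principal component decomposition of a standardized SNP matrix
#'
#' Eigendecomposition of the p x p sample covariance of the standardized
#' genotypes (the SNP correlation matrix). Scores are
#' `zstd %*% eigenvectors`. Each eigenvector's sign is fixed so that its
#' largest-magnitude loading is positive, making loading reports
#' deterministic.
#'
#' @param zstd standardized matrix from [standardize_genotypes()].
#' @return Object of class `pc_decomposition`: `eigenvalues` (descending,
#'   clipped at 0), `eigenvectors` (p x p, orthonormal), `scores` (n x p),
#'   `cumulative_proportion`.
#' @export
pc_decompose <- function(zstd) {
  zstd <- as.matrix(zstd)
  if (nrow(zstd) < 2) stop("need at least 2 samples", call. = FALSE)
  v <- stats::cov(zstd)
  e <- eigen((v + t(v)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (l in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, l]))
    if (vecs[i, l] < 0) vecs[, l] <- -vecs[, l]
  }
  rownames(vecs) <- colnames(zstd)
  structure(list(eigenvalues = vals,
                 eigenvectors = vecs,
                 scores = zstd %*% vecs,
                 cumulative_proportion = cumsum(vals) / sum(vals)),
            class = "pc_decomposition")
}

#' @export
print.pc_decomposition <- function(x, ...) {
  cat(sprintf("pc_decomposition: %d PCs; top eigenvalues: %s\n",
              length(x$eigenvalues),
              paste(round(utils::head(x$eigenvalues, 5), 3), collapse = ", ")))
  invisible(x)
}

#' Number of PCs reaching a cumulative-variance threshold
#'
#' Smallest k whose cumulative explained-variance proportion is at least
#' `threshold_pct` percent (always at least 1). So if the top 2, 3 and 4
#' PCs explain 63, 75 and 80 percent of the variation, thresholds of 60,
#' 70 and 80 give k = 2, 3 and 4.
#'
#' @param dec a [pc_decompose()] result, or a numeric vector of cumulative
#'   proportions (in `[0, 1]`).
#' @param threshold_pct threshold in percent, in (0, 100].
#' @return integer k.
#' @export
select_k <- function(dec, threshold_pct) {
  if (!(is.numeric(threshold_pct) && length(threshold_pct) == 1 &&
        threshold_pct > 0 && threshold_pct <= 100))
    stop("threshold_pct must lie in (0, 100]", call. = FALSE)
  cum <- if (inherits(dec, "pc_decomposition")) dec$cumulative_proportion
  else as.numeric(dec)
  hit <- which(cum >= threshold_pct / 100 - 1e-9)
  k <- if (length(hit)) hit[1] else length(cum)
  max(1L, as.integer(k))
}

#' PCA-based SNP-set likelihood ratio test
#'
#' Standardizes the (typed) genotypes, selects the smallest k leading PCs
#' whose cumulative explained variance reaches `threshold_pct` percent, and
#' compares the logistic models `D ~ covariates + PC_1..PC_k` versus
#' `D ~ covariates` with a k-degree-of-freedom likelihood ratio test.
#'
#' @param ds an aligned, imputed `snpset_dataset`.
#' @param threshold_pct cumulative-variance threshold in percent (the Z of
#'   "PCA(Z\%)").
#' @param use_typed_only restrict to SNPs with `typed_mask` (default TRUE).
#' @return Object of class `pca_test_result`: `threshold_pct`, `k`,
#'   `lrt_statistic`, `df`, `p_value`, `pc_coefficients`, `loadings`
#'   (p x k), `decomposition`, `full_fit` (internal, for loading reports).
#' @export
pca_lrt <- function(ds, threshold_pct = 80, use_typed_only = TRUE) {
  stopifnot(inherits(ds, "snpset_dataset"))
  g <- ds$genotypes
  if (use_typed_only && !all(g$typed_mask)) g <- .subset_snps(g, g$typed_mask)
  d <- ds$phenotypes$disease
  if (length(unique(d)) < 2)
    stop("degenerate outcome: both classes must be present", call. = FALSE)
  zstd <- standardize_genotypes(g)
  dec <- pc_decompose(zstd)
  k <- select_k(dec, threshold_pct)
  x0 <- .design_matrix(ds)
  pcs <- dec$scores[, seq_len(k), drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(k))
  reduced <- .logistic_fit(x0, d)
  full <- .logistic_fit(cbind(x0, pcs), d)
  if (reduced$separated || full$separated)
    stop("complete separation in the logistic fit", call. = FALSE)
  lrt <- max(reduced$deviance - full$deviance, 0)
  theta <- full$coefficients[ncol(x0) + seq_len(k)]
  structure(list(threshold_pct = threshold_pct,
                 k = k,
                 lrt_statistic = lrt,
                 df = k,
                 p_value = stats::pchisq(lrt, df = k, lower.tail = FALSE),
                 pc_coefficients = theta,
                 loadings = dec$eigenvectors[, seq_len(k), drop = FALSE],
                 decomposition = dec,
                 full_fit = full),
            class = "pca_test_result")
}

#' @export
print.pca_test_result <- function(x, ...) {
  cat(sprintf("PCA(%g%%) SNP-set test: k = %d PCs, LRT = %.4g on %d df, p = %.4g\n",
              x$threshold_pct, x$k, x$lrt_statistic, x$df, x$p_value))
  invisible(x)
}

#' Per-SNP loadings of the retained PCs with per-PC Wald p-values
#'
#' Reports, for each retained PC, its loading on every SNP together with
#' the Wald p-value of its coefficient in the full logistic model. Heavy
#' loadings on a significant PC point at the SNPs driving the set signal.
#'
#' @param res a [pca_lrt()] result.
#' @return data frame with columns `pc`, `pc_pvalue`, `snp_id`, `loading`.
#' @export
pc_loadings_report <- function(res) {
  stopifnot(inherits(res, "pca_test_result"))
  full <- res$full_fit
  npar <- length(full$coefficients)
  k <- res$k
  pvals <- vapply(seq_len(k), function(l) {
    .wald_pvalue(full, npar - k + l)
  }, numeric(1))
  snp_ids <- rownames(res$loadings)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(nrow(res$loadings)))
  do.call(rbind, lapply(seq_len(k), function(l) {
    data.frame(pc = paste0("PC", l),
               pc_pvalue = pvals[l],
               snp_id = snp_ids,
               loading = res$loadings[, l],
               row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}
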
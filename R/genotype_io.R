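#' Construct a genotype matrix object
#'
#' Container for an n x p additive-dosage genotype matrix together with
#' per-SNP metadata (identifier, position, coded-allele frequency, MAF) and
#' a logical "typed" mask marking which SNPs an analysis is allowed to see
#' (e.g. the subset present on a genotyping array).
#'
#' @param dosages numeric n x p matrix; entries in \{0, 1, 2\} or `NA`
#'   (fractional values are permitted after mean imputation).
#' @param snp_ids character vector of p unique SNP identifiers. Defaults to
#'   the column names of `dosages`, or `snp1..snpP`.
#' @param positions numeric vector of p positions (basepair coordinates for
#'   real data, ordinal indices 1..p for synthetic panels).
#' @param samples character vector of n sample identifiers.
#' @param typed_mask logical vector of length p; `TRUE` marks genotyped
#'   ("typed") SNPs. Defaults to all `TRUE`.
#' @return An object of class `genotype_matrix` with elements `samples`,
#'   `snps` (data frame with `snp_id`, `position`, `coded_allele_freq`,
#'   `maf`), `dosages`, and `typed_mask`.
#' @export
genotype_matrix <- function(dosages, snp_ids = NULL, positions = NULL,
                            samples = NULL, typed_mask = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  p <- ncol(dosages)
  if (p == 0L || n == 0L) stop("empty genotype matrix", call. = FALSE)
  ok <- is.na(dosages) | (dosages >= 0 & dosages <= 2)
  if (!all(ok)) stop("dosage entries must lie in [0, 2] or be missing", call. = FALSE)
  if (is.null(snp_ids)) {
    snp_ids <- colnames(dosages)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(p))
  }
  if (anyDuplicated(snp_ids)) stop("SNP identifiers must be unique", call. = FALSE)
  if (length(snp_ids) != p) stop("snp_ids length must equal ncol(dosages)", call. = FALSE)
  if (is.null(positions)) positions <- seq_len(p)
  if (is.null(samples)) {
    samples <- rownames(dosages)
    if (is.null(samples)) samples <- paste0("ind", seq_len(n))
  }
  if (length(samples) != n) stop("samples length must equal nrow(dosages)", call. = FALSE)
  if (is.null(typed_mask)) typed_mask <- rep(TRUE, p)
  if (length(typed_mask) != p || !is.logical(typed_mask))
    stop("typed_mask must be a logical vector of length p", call. = FALSE)
  dimnames(dosages) <- list(samples, snp_ids)
  caf <- colMeans(dosages, na.rm = TRUE) / 2
  obj <- list(
    samples = as.character(samples),
    snps = data.frame(snp_id = as.character(snp_ids),
                      position = positions,
                      coded_allele_freq = unname(caf),
                      maf = unname(pmin(caf, 1 - caf)),
                      stringsAsFactors = FALSE),
    dosages = dosages,
    typed_mask = typed_mask
  )
  class(obj) <- "genotype_matrix"
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%d typed, %d missing entries)\n",
              length(x$samples), nrow(x$snps), sum(x$typed_mask),
              sum(is.na(x$dosages))))
  invisible(x)
}

#' Construct a phenotype table
#'
#' @param samples character vector of sample identifiers.
#' @param disease binary vector (1 = affected, 0 = unaffected).
#' @param covariates optional numeric matrix/data frame of covariates with
#'   named columns, one row per sample.
#' @return Object of class `phenotype_table`.
#' @export
phenotype_table <- function(samples, disease, covariates = NULL) {
  samples <- as.character(samples)
  disease <- as.numeric(disease)
  if (length(disease) != length(samples))
    stop("disease length must match samples", call. = FALSE)
  if (!all(disease %in% c(0, 1)))
    stop("disease must be coded 0/1", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != length(samples))
      stop("covariates must have one row per sample", call. = FALSE)
    if (any(!is.finite(covariates)))
      stop("covariate values must be finite", call. = FALSE)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    rownames(covariates) <- samples
  }
  obj <- list(samples = samples, disease = disease, covariates = covariates)
  class(obj) <- "phenotype_table"
  obj
}

#' @export
print.phenotype_table <- function(x, ...) {
  m <- if (is.null(x$covariates)) 0L else ncol(x$covariates)
  cat(sprintf("phenotype_table: %d samples (%d cases / %d controls), %d covariates\n",
              length(x$samples), sum(x$disease == 1), sum(x$disease == 0), m))
  invisible(x)
}

#' Read genotypes from VCF or a dosage TSV
#'
#' Dosages are coded as the count of the VCF ALT allele (or of the coded
#' allele implied by the TSV, whose header is
#' `sample<TAB>snp1<TAB>...` with one row of 0/1/2 dosages per sample).
#' Multi-allelic VCF records are rejected.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"dosage"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "dosage"
  }
  if (format == "vcf") .read_vcf_genotypes(path) else .read_dosage_tsv(path)
}

.read_vcf_genotypes <- function(path) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    stop("unsupported multi-allelic variant at record ", which(multi)[1],
         " (", fix[which(multi)[1], "ID"], ")", call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(fix[, "ID"], names(gt)))
  # alleles separated by / or |; count ALT ("1") alleles, "." -> missing
  count_alt <- function(cell) {
    if (is.na(cell)) return(NA_real_)
    al <- strsplit(cell, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    if (!all(al %in% c("0", "1")))
      stop("unsupported allele code '", cell, "' in VCF", call. = FALSE)
    sum(al == "1")
  }
  dos <- t(apply(gt, c(1, 2), count_alt))  # samples x snps
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  genotype_matrix(dos, snp_ids = ids, positions = as.numeric(fix[, "POS"]),
                  samples = colnames(gt))
}

.read_dosage_tsv <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse dosage TSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(tab) < 2 || names(tab)[1] != "sample")
    stop("dosage TSV must have header 'sample<TAB>snp1<TAB>...'", call. = FALSE)
  dos <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  bad <- which(!(is.na(dos) | dos %in% c(0, 1, 2) |
                   (dos >= 0 & dos <= 2)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("parse error at line ", bad[1, 1] + 1L, " of '", path,
         "': dosage outside [0,2]", call. = FALSE)
  genotype_matrix(dos, snp_ids = colnames(dos), samples = tab$sample)
}

#' Write a genotype matrix as a dosage TSV
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- data.frame(sample = g$samples, g$dosages, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate TSV
#'
#' Expected header: `sample<TAB>status<TAB>cov1...` with `status` in \{0,1\}.
#'
#' @param path file path.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample", "status") %in% names(tab)))
    stop("phenotype TSV must have columns 'sample' and 'status'", call. = FALSE)
  covs <- tab[, setdiff(names(tab), c("sample", "status")), drop = FALSE]
  phenotype_table(tab$sample, tab$status,
                  if (ncol(covs) > 0) covs else NULL)
}

#' Per-SNP coded-allele frequency and MAF
#'
#' For SNP j the coded-allele frequency is `sum(z[, j]) / (2 n)` and the MAF
#' folds it onto `[0, 0.5]`. Run after [impute_missing()] so no entries are
#' missing.
#'
#' @param g a [genotype_matrix()] without missing entries.
#' @return data frame with `snp_id`, `coded_allele_freq`, `maf`.
#' @export
compute_maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(g$samples) == 0) stop("no samples", call. = FALSE)
  if (anyNA(g$dosages))
    stop("missing dosages present; run impute_missing() first", call. = FALSE)
  f <- colMeans(g$dosages) / 2
  data.frame(snp_id = g$snps$snp_id, coded_allele_freq = unname(f),
             maf = unname(pmin(f, 1 - f)), stringsAsFactors = FALSE)
}

#' Mean-impute missing dosages
#'
#' Each missing entry is replaced by the per-SNP mean dosage of the observed
#' entries. SNPs with all entries missing are dropped with a warning.
#'
#' @param g a [genotype_matrix()].
#' @return A [genotype_matrix()] with no missing entries.
#' @export
impute_missing <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  dos <- g$dosages
  all_na <- colSums(!is.na(dos)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " SNP(s) with all entries missing dropped: ",
            paste(g$snps$snp_id[all_na], collapse = ", "), call. = FALSE)
    dos <- dos[, !all_na, drop = FALSE]
    g$snps <- g$snps[!all_na, , drop = FALSE]
    g$typed_mask <- g$typed_mask[!all_na]
    if (ncol(dos) == 0) stop("no SNPs left after dropping all-missing columns",
                             call. = FALSE)
  }
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  genotype_matrix(dos, snp_ids = g$snps$snp_id, positions = g$snps$position,
                  samples = g$samples, typed_mask = g$typed_mask)
}

#' Align a genotype matrix with a phenotype table
#'
#' Restricts both to the intersection of their sample identifiers, in
#' genotype order, and bundles them as a `snpset_dataset`.
#'
#' @param g a [genotype_matrix()].
#' @param p a [phenotype_table()].
#' @return Object of class `snpset_dataset` with elements `genotypes` and
#'   `phenotypes` sharing an identical sample order.
#' @export
align_samples <- function(g, p) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(p, "phenotype_table"))
  keep <- g$samples[g$samples %in% p$samples]
  if (length(keep) == 0)
    stop("no overlapping samples between genotypes and phenotypes", call. = FALSE)
  dropped <- (length(g$samples) - length(keep)) +
    (length(p$samples) - length(keep))
  if (dropped > 0)
    message(dropped, " non-overlapping sample record(s) dropped during alignment")
  gi <- match(keep, g$samples)
  pi <- match(keep, p$samples)
  g2 <- genotype_matrix(g$dosages[gi, , drop = FALSE],
                        snp_ids = g$snps$snp_id, positions = g$snps$position,
                        samples = keep, typed_mask = g$typed_mask)
  p2 <- phenotype_table(keep, p$disease[pi],
                        if (is.null(p$covariates)) NULL
                        else p$covariates[pi, , drop = FALSE])
  structure(list(genotypes = g2, phenotypes = p2), class = "snpset_dataset")
}

#' @export
print.snpset_dataset <- function(x, ...) {
  cat("snpset_dataset\n")
  print(x$genotypes)
  print(x$phenotypes)
  invisible(x)
}

# covariate design matrix (with intercept) for a dataset
.design_matrix <- function(ds) {
  n <- length(ds$phenotypes$samples)
  x <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(ds$phenotypes$covariates)) x <- cbind(x, ds$phenotypes$covariates)
  x
}
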
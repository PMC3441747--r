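# Synthetic-data engine: LD-structured haplotype panels via a Gaussian
# copula threshold model, retrospective case-control sampling under a
# log-additive relative-risk logistic disease model.

# evaluate code with a temporary RNG seed, restoring global RNG state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  code
}

#' LD specification for a synthetic haplotype panel
#'
#' Describes a panel as consecutive LD blocks. Within a block, haplotype
#' alleles share an exchangeable latent Gaussian correlation `rho`; allele
#' frequencies are drawn uniformly from `maf_range` (a per-block
#' `maf_range` may override the global one, e.g. to plant a low-MAF
#' block).
#'
#' @param blocks list of blocks, each a list with `snp_count` (integer) and
#'   `rho` (latent correlation in `[0, 1)`), optionally `maf_range`.
#' @param maf_range global allele-frequency range, within (0, 0.5].
#' @param seed integer seed making panel generation reproducible.
#' @return Object of class `ld_spec`.
#' @export
ld_spec <- function(blocks, maf_range = c(0.05, 0.5), seed = 1) {
  if (!is.list(blocks) || length(blocks) == 0)
    stop("blocks must be a nonempty list", call. = FALSE)
  for (b in blocks) {
    if (is.null(b$snp_count) || b$snp_count < 1)
      stop("each block needs snp_count >= 1", call. = FALSE)
    if (is.null(b$rho) || b$rho < 0 || b$rho >= 1)
      stop("each block needs latent correlation rho in [0, 1)", call. = FALSE)
    mr <- if (is.null(b$maf_range)) maf_range else b$maf_range
    if (mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
      stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  structure(list(blocks = blocks, maf_range = maf_range, seed = seed),
            class = "ld_spec")
}

# theoretical correlation of two threshold-Gaussian binary alleles with
# frequencies f1, f2 and latent correlation rho
.binary_corr <- function(f1, f2, rho) {
  if (rho <= 0) return(0)
  if (rho >= 1 - 1e-12) {
    p11 <- min(f1, f2)
  } else {
    t1 <- stats::qnorm(f1)
    t2 <- stats::qnorm(f2)
    p11 <- stats::integrate(function(x) {
      stats::dnorm(x) * stats::pnorm((t2 - rho * x) / sqrt(1 - rho^2))
    }, -Inf, t1, rel.tol = 1e-9)$value
  }
  (p11 - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
}

#' Generate an LD-structured haplotype panel
#'
#' Latent multivariate-normal threshold scheme: within each block the
#' latent variables are exchangeable with correlation `rho`, and the
#' allele at SNP j is 1 iff the latent value falls below `qnorm(f_j)`,
#' with `f_j` drawn uniformly from the block's frequency range. For panels
#' with `m >= 10000` haplotypes, a calibration check verifies that the
#' realized allele frequencies stay inside the frequency range (within
#' 0.02) and that the realized mean within-block `r^2` agrees with its
#' theoretical Gaussian-copula value (within 0.05); failure signals an
#' infeasible specification.
#'
#' @param spec an [ld_spec()].
#' @param m number of haplotypes (must be at least `2 p`).
#' @return Object of class `haplotype_panel`: `haplotypes` (m x p 0/1
#'   matrix), `snp_records`, `realized_r2` (p x p), `block` (block index
#'   per SNP), `spec`.
#' @export
generate_panel <- function(spec, m = 10000) {
  stopifnot(inherits(spec, "ld_spec"))
  p <- sum(vapply(spec$blocks, function(b) as.integer(b$snp_count), integer(1)))
  if (m < 2 * p)
    stop("panel needs m >= 2 p haplotypes (m = ", m, ", p = ", p, ")", call. = FALSE)
  .with_seed(spec$seed, {
    haps <- matrix(0L, m, 0)
    freqs <- numeric(0)
    block_id <- integer(0)
    target_r2 <- numeric(length(spec$blocks))
    for (bi in seq_along(spec$blocks)) {
      b <- spec$blocks[[bi]]
      pb <- as.integer(b$snp_count)
      mr <- if (is.null(b$maf_range)) spec$maf_range else b$maf_range
      f <- stats::runif(pb, mr[1], mr[2])
      common <- stats::rnorm(m)
      lat <- sqrt(b$rho) * common +
        sqrt(1 - b$rho) * matrix(stats::rnorm(m * pb), m, pb)
      h <- matrix(0L, m, pb)
      for (j in seq_len(pb)) h[, j] <- as.integer(lat[, j] < stats::qnorm(f[j]))
      haps <- cbind(haps, h)
      freqs <- c(freqs, f)
      block_id <- c(block_id, rep(bi, pb))
      if (pb > 1) {
        pairs <- utils::combn(pb, 2)
        if (ncol(pairs) > 50) pairs <- pairs[, sample(ncol(pairs), 50), drop = FALSE]
        target_r2[bi] <- mean(apply(pairs, 2, function(ij) {
          .binary_corr(f[ij[1]], f[ij[2]], b$rho)^2
        }))
      } else {
        target_r2[bi] <- NA_real_
      }
    }
    colnames(haps) <- paste0("snp", seq_len(p))
    cr <- suppressWarnings(stats::cor(haps))
    cr[!is.finite(cr)] <- 0
    panel <- structure(list(haplotypes = haps,
                            snp_records = data.frame(
                              snp_id = colnames(haps),
                              position = seq_len(p),
                              coded_allele_freq = colMeans(haps),
                              maf = pmin(colMeans(haps), 1 - colMeans(haps)),
                              stringsAsFactors = FALSE),
                            realized_r2 = cr^2,
                            block = block_id,
                            spec = spec),
                       class = "haplotype_panel")
    if (m >= 10000) .check_panel_calibration(panel, target_r2)
    panel
  })
}

.check_panel_calibration <- function(panel, target_r2) {
  spec <- panel$spec
  f <- panel$snp_records$coded_allele_freq
  for (bi in seq_along(spec$blocks)) {
    b <- spec$blocks[[bi]]
    mr <- if (is.null(b$maf_range)) spec$maf_range else b$maf_range
    fb <- f[panel$block == bi]
    if (any(fb < mr[1] - 0.02) || any(fb > mr[2] + 0.02))
      stop("panel calibration failed: realized allele frequencies leave [",
           mr[1], ", ", mr[2], "] in block ", bi, call. = FALSE)
    if (is.na(target_r2[bi])) next
    idx <- which(panel$block == bi)
    rr <- panel$realized_r2[idx, idx]
    realized <- mean(rr[upper.tri(rr)])
    if (abs(realized - target_r2[bi]) > 0.05)
      stop("panel calibration failed: block ", bi, " realized mean r^2 (",
           round(realized, 3), ") is incompatible with its specification (",
           round(target_r2[bi], 3), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d SNPs, %d block(s)\n",
              nrow(x$haplotypes), ncol(x$haplotypes), length(unique(x$block))))
  invisible(x)
}

#' Draw genotypes from a haplotype panel
#'
#' Each individual is the sum of two haplotypes drawn independently with
#' replacement (random mating), giving dosages in \{0, 1, 2\} in
#' Hardy-Weinberg proportions at the panel allele frequencies. Uses the
#' current RNG stream; seed with `set.seed()` (or let the higher-level
#' samplers do it) for reproducibility.
#'
#' @param panel a [generate_panel()] result or imported panel.
#' @param n number of individuals.
#' @return n x p dosage matrix.
#' @export
draw_genotypes <- function(panel, n = 1) {
  stopifnot(inherits(panel, "haplotype_panel"), n >= 1)
  m <- nrow(panel$haplotypes)
  i1 <- sample.int(m, n, replace = TRUE)
  i2 <- sample.int(m, n, replace = TRUE)
  z <- panel$haplotypes[i1, , drop = FALSE] + panel$haplotypes[i2, , drop = FALSE]
  storage.mode(z) <- "double"
  rownames(z) <- NULL
  z
}

#' Log-additive relative-risk disease model
#'
#' Disease probability `expit(beta0 + sum_j beta_j z_j)` over the causal
#' SNPs, with `beta_j = log(rr_j)`: each additional risk allele multiplies
#' the disease odds by its relative risk. `C = 0` causal SNPs gives the
#' null model.
#'
#' @param causal_indices integer indices of the causal SNPs (possibly
#'   empty).
#' @param rr per-causal relative risks (> 0), recycled to the number of
#'   causal SNPs.
#' @param target_prevalence population disease probability used to
#'   calibrate the intercept (default 0.10).
#' @param beta0 optional intercept; left `NULL` until calibrated.
#' @return Object of class `disease_model` with `causal_indices`, `rr`,
#'   `beta` (`log(rr)`), `beta0`, `target_prevalence`.
#' @export
disease_model <- function(causal_indices = integer(0), rr = numeric(0),
                          target_prevalence = 0.1, beta0 = NULL) {
  causal_indices <- as.integer(causal_indices)
  if (length(causal_indices)) {
    if (length(rr) == 0) stop("rr required when causal SNPs are given", call. = FALSE)
    rr <- rep_len(rr, length(causal_indices))
    if (any(rr <= 0)) stop("relative risks must be positive", call. = FALSE)
  } else {
    rr <- numeric(0)
  }
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("target_prevalence must lie in (0, 1)", call. = FALSE)
  structure(list(causal_indices = causal_indices, rr = rr, beta = log(rr),
                 beta0 = beta0, target_prevalence = target_prevalence),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  if (length(x$causal_indices) == 0) {
    cat("disease_model: null (no causal SNPs), prevalence",
        x$target_prevalence, "\n")
  } else {
    cat(sprintf("disease_model: %d causal SNP(s) at %s, RR %s, prevalence %g\n",
                length(x$causal_indices),
                paste(x$causal_indices, collapse = ","),
                paste(x$rr, collapse = ","), x$target_prevalence))
  }
  invisible(x)
}

#' Disease probability under the log-additive model
#'
#' @param z dosage vector (length p) or n x p matrix.
#' @param model a [disease_model()] with `beta0` set (see
#'   [calibrate_beta0()]).
#' @return numeric probability (vector of length n).
#' @export
disease_prob <- function(z, model) {
  stopifnot(inherits(model, "disease_model"))
  if (is.null(model$beta0))
    stop("model intercept beta0 is not set; run calibrate_beta0() first",
         call. = FALSE)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  eta <- rep(model$beta0, nrow(z))
  if (length(model$causal_indices))
    eta <- eta + drop(z[, model$causal_indices, drop = FALSE] %*% model$beta)
  stats::plogis(eta)
}

#' Calibrate the disease-model intercept to a target prevalence
#'
#' Finds `beta0` such that the Monte-Carlo mean of the disease probability
#' over `n_mc` panel genotype draws equals the target prevalence (monotone
#' 1-d root finding). With no causal SNPs the answer is
#' `qlogis(target_prevalence)` exactly.
#'
#' @param panel a [generate_panel()] result.
#' @param model a [disease_model()].
#' @param target_prevalence target disease probability; defaults to the
#'   model's.
#' @param n_mc Monte-Carlo draws (default 1e5, giving self-consistency
#'   well within 0.002).
#' @return the calibrated `beta0` (scalar).
#' @export
calibrate_beta0 <- function(panel, model, target_prevalence = NULL,
                            n_mc = 100000) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(model, "disease_model"))
  target <- if (is.null(target_prevalence)) model$target_prevalence
  else target_prevalence
  if (target <= 0 || target >= 1)
    stop("target prevalence must lie in (0, 1)", call. = FALSE)
  if (length(model$causal_indices) == 0) return(stats::qlogis(target))
  z <- draw_genotypes(panel, n_mc)
  gscore <- drop(z[, model$causal_indices, drop = FALSE] %*% model$beta)
  fn <- function(b0) mean(stats::plogis(b0 + gscore)) - target
  root <- tryCatch(
    stats::uniroot(fn, interval = stats::qlogis(target) + c(-30, 30),
                   tol = 1e-10),
    error = function(e) stop("intercept calibration failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  root$root
}

#' Sample a case-control dataset under the disease model
#'
#' Retrospective rejection sampling: genotypes are drawn from the panel,
#' disease status assigned with probability `disease_prob`, and
#' individuals kept until both the case and control quotas are filled.
#' Deterministic given `seed`. If `model$beta0` is unset it is calibrated
#' first (inside the same seeded stream).
#'
#' @param panel a [generate_panel()] result.
#' @param model a [disease_model()].
#' @param n_case,n_ctrl case and control quotas.
#' @param seed integer seed.
#' @return A `snpset_dataset` (cases first, then controls; no covariates).
#' @export
sample_case_control <- function(panel, model, n_case, n_ctrl, seed = 1) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(model, "disease_model"))
  .with_seed(seed, {
    if (is.null(model$beta0))
      model$beta0 <- calibrate_beta0(panel, model)
    tp <- model$target_prevalence
    p <- ncol(panel$haplotypes)
    cases <- matrix(0, 0, p)
    ctrls <- matrix(0, 0, p)
    drawn <- 0
    while (nrow(cases) < n_case || nrow(ctrls) < n_ctrl) {
      need_case <- n_case - nrow(cases)
      need_ctrl <- n_ctrl - nrow(ctrls)
      batch <- ceiling(1.3 * max(need_case / max(tp, 0.01),
                                 need_ctrl / max(1 - tp, 0.01)))
      batch <- min(max(batch, 1000), 500000)
      z <- draw_genotypes(panel, batch)
      pr <- disease_prob(z, model)
      d <- stats::rbinom(batch, 1, pr)
      if (need_case > 0) {
        idx <- which(d == 1)
        cases <- rbind(cases, z[utils::head(idx, need_case), , drop = FALSE])
      }
      if (need_ctrl > 0) {
        idx <- which(d == 0)
        ctrls <- rbind(ctrls, z[utils::head(idx, need_ctrl), , drop = FALSE])
      }
      drawn <- drawn + batch
      if (drawn > 1e7)
        stop("case/control quota unreachable within 1e7 draws", call. = FALSE)
    }
    dos <- rbind(cases, ctrls)
    n <- nrow(dos)
    g <- genotype_matrix(dos,
                         snp_ids = panel$snp_records$snp_id,
                         positions = panel$snp_records$position,
                         samples = paste0("ind", seq_len(n)))
    ph <- phenotype_table(g$samples, c(rep(1, n_case), rep(0, n_ctrl)))
    structure(list(genotypes = g, phenotypes = ph), class = "snpset_dataset")
  })
}

#' Restrict a dataset to its typed SNPs
#'
#' Emulates array genotyping: the analysis only sees the SNPs flagged by
#' the mask; causal SNPs may or may not survive.
#'
#' @param ds a `snpset_dataset`.
#' @param typed_mask logical vector of length p with at least one `TRUE`.
#' @return A `snpset_dataset` containing only the typed SNPs.
#' @export
mask_typed <- function(ds, typed_mask) {
  stopifnot(inherits(ds, "snpset_dataset"))
  p <- ncol(ds$genotypes$dosages)
  if (length(typed_mask) != p)
    stop("typed_mask length must equal the SNP count", call. = FALSE)
  if (!any(typed_mask)) stop("typed_mask selects no SNPs", call. = FALSE)
  structure(list(genotypes = .subset_snps(ds$genotypes, typed_mask),
                 phenotypes = ds$phenotypes),
            class = "snpset_dataset")
}

#' Median r-squared between a causal SNP and the typed SNPs
#'
#' Median, over the typed SNPs (the causal SNP itself excluded), of the
#' squared Pearson correlation between the causal-SNP and typed-SNP
#' haplotype alleles. This is the LD summary the power of set tests on
#' untyped causal SNPs is driven by.
#'
#' @param panel a [generate_panel()] result.
#' @param causal_index index of the causal SNP.
#' @param typed_mask logical vector of length p.
#' @return scalar median r-squared.
#' @export
median_r2_with_typed <- function(panel, causal_index, typed_mask) {
  stopifnot(inherits(panel, "haplotype_panel"))
  p <- ncol(panel$haplotypes)
  if (causal_index < 1 || causal_index > p)
    stop("causal_index out of range", call. = FALSE)
  typed <- setdiff(which(typed_mask), causal_index)
  if (length(typed) == 0) stop("no typed SNPs besides the causal one", call. = FALSE)
  r <- suppressWarnings(
    stats::cor(panel$haplotypes[, causal_index], panel$haplotypes[, typed])
  )
  r[!is.finite(r)] <- 0
  stats::median(drop(r)^2)
}

#' Export a haplotype panel as TSV
#'
#' Plain-text dialect `hap<TAB>snp1<TAB>...` with one 0/1 row per
#' haplotype, the import counterpart of [read_haplotype_panel()] for users
#' holding phased reference haplotypes.
#'
#' @param panel a `haplotype_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotypes_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  tab <- data.frame(hap = paste0("hap", seq_len(nrow(panel$haplotypes))),
                    panel$haplotypes, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a phased haplotype panel from TSV
#'
#' @param path TSV with header `hap<TAB>snp1<TAB>...` and 0/1 entries.
#' @return A `haplotype_panel` (single pseudo-block, realized r-squared
#'   computed from the data).
#' @export
read_haplotype_panel <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "hap")
    stop("haplotype TSV must have header 'hap<TAB>snp1<TAB>...'", call. = FALSE)
  h <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(h) <- "integer"
  if (!all(h %in% c(0L, 1L)))
    stop("haplotype entries must be 0/1", call. = FALSE)
  f <- colMeans(h)
  cr <- suppressWarnings(stats::cor(h))
  cr[!is.finite(cr)] <- 0
  structure(list(haplotypes = h,
                 snp_records = data.frame(snp_id = colnames(h),
                                          position = seq_len(ncol(h)),
                                          coded_allele_freq = f,
                                          maf = pmin(f, 1 - f),
                                          stringsAsFactors = FALSE),
                 realized_r2 = cr^2,
                 block = rep(1L, ncol(h)),
                 spec = NULL),
            class = "haplotype_panel")
}
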
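#' Kernel specification for the kernel machine test
#'
#' The four kernels compared in the package are the linear kernel, the
#' identical-by-state (IBS) kernel, and their Beta-MAF-weighted versions.
#' For SNP j with minor allele frequency `maf_j`, the weighted kernels use
#' `w_j = dbeta(maf_j, a1, a2)`; the defaults `a1 = 1`, `a2 = 25` strongly
#' up-weight low-MAF SNPs. Weights enter the kernel squared,
#' `K = Z W^2 Z'` for the linear family.
#'
#' @param name one of `"linear"`, `"ibs"`, `"linear.weighted"`,
#'   `"ibs.weighted"`.
#' @param a1,a2 positive Beta-density shape parameters for the weighted
#'   kernels.
#' @param explicit_weights optional vector of per-SNP positive weights that
#'   overrides the Beta-density weights.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(name = c("linear", "ibs", "linear.weighted", "ibs.weighted"),
                        a1 = 1, a2 = 25, explicit_weights = NULL) {
  name <- match.arg(name)
  if (!(is.numeric(a1) && length(a1) == 1 && a1 > 0) ||
      !(is.numeric(a2) && length(a2) == 1 && a2 > 0))
    stop("a1 and a2 must be positive scalars", call. = FALSE)
  if (!is.null(explicit_weights) && any(explicit_weights <= 0))
    stop("explicit_weights must be positive", call. = FALSE)
  structure(list(name = name, a1 = a1, a2 = a2,
                 explicit_weights = explicit_weights),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  w <- if (!is.null(x$explicit_weights)) "explicit weights"
  else if (grepl("weighted", x$name)) sprintf("Beta(%g, %g) MAF weights", x$a1, x$a2)
  else "unweighted"
  cat(sprintf("kernel_spec: %s (%s)\n", x$name, w))
  invisible(x)
}

#' Beta-density MAF weights
#'
#' `w_j = dbeta(maf_j; a1, a2) = maf_j^(a1-1) (1-maf_j)^(a2-1) / B(a1, a2)`.
#' Monomorphic SNPs (MAF 0 or 1) must be removed upstream.
#'
#' @param maf vector of minor allele frequencies, each in (0, 1).
#' @param a1,a2 positive shape parameters (defaults 1 and 25).
#' @return vector of positive weights.
#' @export
beta_weights <- function(maf, a1 = 1, a2 = 25) {
  if (any(maf <= 0 | maf >= 1))
    stop("MAF must lie strictly in (0, 1); drop monomorphic SNPs upstream",
         call. = FALSE)
  stats::dbeta(maf, a1, a2)
}

# resolve per-SNP weights for a spec: 1 for unweighted kernels
.kernel_weights <- function(g, spec) {
  p <- ncol(g$dosages)
  if (!is.null(spec$explicit_weights)) {
    if (length(spec$explicit_weights) != p)
      stop("explicit_weights length must equal the number of SNPs", call. = FALSE)
    return(spec$explicit_weights)
  }
  if (grepl("weighted", spec$name)) {
    maf <- compute_maf(g)$maf
    beta_weights(maf, spec$a1, spec$a2)
  } else {
    rep(1, p)
  }
}

#' Compute a kernel matrix
#'
#' Linear family: `K(i, i') = sum_j w_j^2 z_ij z_i'j`. IBS family:
#' `K(i, i') = sum_j w_j^2 (2 - |z_ij - z_i'j|)`, the weighted count of
#' alleles shared identical by state. Unweighted kernels use `w_j = 1`.
#'
#' @param g a [genotype_matrix()] with no missing dosages.
#' @param spec a [kernel_spec()].
#' @return Object of class `kernel_matrix`: list with the symmetric n x n
#'   `values` matrix and the `spec`.
#' @export
compute_kernel <- function(g, spec = kernel_spec("linear")) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(spec, "kernel_spec"))
  z <- g$dosages
  if (ncol(z) == 0) stop("empty SNP set", call. = FALSE)
  if (anyNA(z)) stop("missing dosages; run impute_missing() first", call. = FALSE)
  w <- .kernel_weights(g, spec)
  if (grepl("^linear", spec$name)) {
    k <- tcrossprod(sweep(z, 2, w, `*`))
  } else {
    n <- nrow(z)
    k <- matrix(0, n, n)
    w2 <- w^2
    for (j in seq_len(ncol(z))) {
      k <- k + w2[j] * (2 - abs(outer(z[, j], z[, j], `-`)))
    }
  }
  k <- (k + t(k)) / 2
  structure(list(values = k, spec = spec), class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix: %d x %d, kernel %s\n",
              nrow(x$values), ncol(x$values), x$spec$name))
  invisible(x)
}

# Low-rank factorization K = Phi Phi' when one exists:
#  * linear family: Phi = Z diag(w), n x p.
#  * IBS family with integer {0,1,2} dosages: per-SNP 3-column feature map
#    from the Cholesky factor of the 3x3 IBS similarity matrix
#    M[a+1, b+1] = 2 - |a - b| (positive definite), scaled by w_j.
# Returns NULL when no exact factor is available (fractional IBS dosages).
.kernel_factor <- function(g, spec) {
  z <- g$dosages
  w <- .kernel_weights(g, spec)
  if (grepl("^linear", spec$name)) {
    phi <- sweep(z, 2, w, `*`)
    return(structure(list(phi = phi, spec = spec), class = "kernel_factor"))
  }
  if (!all(z %in% c(0, 1, 2))) return(NULL)
  m <- matrix(c(2, 1, 0, 1, 2, 1, 0, 1, 2), 3, 3)
  l <- t(chol(m))                       # l %*% t(l) == m
  n <- nrow(z)
  p <- ncol(z)
  phi <- matrix(0, n, 3L * p)
  for (j in seq_len(p)) {
    phi[, (3L * j - 2L):(3L * j)] <- l[z[, j] + 1L, , drop = FALSE] * w[j]
  }
  structure(list(phi = phi, spec = spec), class = "kernel_factor")
}
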
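#' Built-in simulation scenarios
#'
#' A small library of ready-made scenario configurations spanning the
#' situations the package's simulation study covers. The synthetic panels
#' (the "regions") are generated from fixed internal seeds so that each
#' scenario always refers to the same region; `seed` only drives the
#' case-control sampling, so rerunning with a different seed redraws the
#' datasets but not the LD structure.
#'
#' Available scenarios:
#' \describe{
#'   \item{`null-small-region`}{31-SNP single LD block (latent correlation
#'     0.85, MAF 0.05-0.5), 8 typed SNPs, no causal SNP. Type-I-error
#'     benchmark; defaults 500 cases/500 controls, 1000 replicates.}
#'   \item{`null-large-region`}{154-SNP two-block region (119 + 35 SNPs,
#'     latent correlation 0.8), 39 typed (26 + 13), no causal SNP.
#'     Defaults 500/500, 1000 replicates.}
#'   \item{`null-redundant-typed`}{31-SNP block with very strong LD
#'     (latent correlation 0.95, MAF 0.2-0.5), 8 highly correlated typed
#'     SNPs, no causal SNP. Exposes the conservativeness of the min-p
#'     test. Defaults 500/500, 2000 replicates.}
#'   \item{`two-typed-causal`}{31-SNP block (latent correlation 0.9, MAF
#'     0.2-0.5); the two causal SNPs (positions 14 and 22) are both typed,
#'     each with relative risk 1.1. Defaults 1000/1000, 1000 replicates.}
#'   \item{`lowmaf-causal-pair`}{Two blocks: 23 common SNPs (MAF
#'     0.25-0.5) and 8 low-MAF SNPs (MAF 0.08-0.15). Two low-MAF causal
#'     SNPs (one typed, one not), relative risk 1.1 each; 8 typed SNPs
#'     overall. The regime where Beta(1, 25) MAF weighting pays off.
#'     Defaults 1000/1000, 1000 replicates.}
#'   \item{`ld-gradient-1` .. `ld-gradient-8`}{31-SNP single blocks with
#'     increasing latent correlation (0 to 0.92); the causal SNP
#'     (position 31, untyped, relative risk 1.2) is tagged by the 8 typed
#'     SNPs with increasing median r-squared. Power-versus-LD harness.
#'     Defaults 1000/1000, 1000 replicates.}
#' }
#'
#' @param name scenario name (see Details).
#' @param seed sampling seed for the scenario.
#' @param replicates,n_case,n_ctrl optional overrides of the scenario
#'   defaults.
#' @param panel_m haplotypes in the generated panel.
#' @return A [scenario_config()].
#' @export
builtin_scenario <- function(name, seed = 1, replicates = NULL,
                             n_case = NULL, n_ctrl = NULL, panel_m = 10000) {
  mask31 <- rep(FALSE, 31)
  mask31[round(seq(2, 30, length.out = 8))] <- TRUE   # 2,6,10,14,18,22,26,30
  def <- NULL
  if (grepl("^ld-gradient-[1-8]$", name)) {
    i <- as.integer(sub("^ld-gradient-", "", name))
    rhos <- c(0, 0.2, 0.35, 0.5, 0.62, 0.72, 0.82, 0.92)
    def <- list(
      spec = ld_spec(list(list(snp_count = 31, rho = rhos[i])),
                     maf_range = c(0.2, 0.5), seed = 400 + i),
      model = disease_model(31, 1.2),
      typed_mask = mask31, n_case = 1000, n_ctrl = 1000, replicates = 1000)
  } else {
    def <- switch(
      name,
      "null-small-region" = list(
        spec = ld_spec(list(list(snp_count = 31, rho = 0.85)),
                       maf_range = c(0.05, 0.5), seed = 11),
        model = disease_model(),
        typed_mask = mask31, n_case = 500, n_ctrl = 500, replicates = 1000),
      "null-large-region" = {
        mask154 <- rep(FALSE, 154)
        mask154[round(seq(2, 118, length.out = 26))] <- TRUE
        mask154[round(seq(121, 153, length.out = 13))] <- TRUE
        list(
          spec = ld_spec(list(list(snp_count = 119, rho = 0.8),
                              list(snp_count = 35, rho = 0.8)),
                         maf_range = c(0.05, 0.5), seed = 78),
          model = disease_model(),
          typed_mask = mask154, n_case = 500, n_ctrl = 500, replicates = 1000)
      },
      "null-redundant-typed" = list(
        spec = ld_spec(list(list(snp_count = 31, rho = 0.95)),
                       maf_range = c(0.2, 0.5), seed = 77),
        model = disease_model(),
        typed_mask = mask31, n_case = 500, n_ctrl = 500, replicates = 2000),
      "two-typed-causal" = list(
        spec = ld_spec(list(list(snp_count = 31, rho = 0.9)),
                       maf_range = c(0.2, 0.5), seed = 211),
        model = disease_model(c(14, 22), 1.1),
        typed_mask = mask31, n_case = 1000, n_ctrl = 1000, replicates = 1000),
      "lowmaf-causal-pair" = {
        mask <- rep(FALSE, 31)
        mask[c(2, 6, 10, 14, 18, 22, 25, 29)] <- TRUE
        list(
          spec = ld_spec(list(list(snp_count = 23, rho = 0.85,
                                   maf_range = c(0.25, 0.5)),
                              list(snp_count = 8, rho = 0.85,
                                   maf_range = c(0.08, 0.15))),
                         seed = 212),
          model = disease_model(c(25, 27), 1.1),
          typed_mask = mask, n_case = 1000, n_ctrl = 1000, replicates = 1000)
      },
      stop("unknown scenario '", name, "'", call. = FALSE))
  }
  scenario_config(def$spec, def$model,
                  n_case = if (is.null(n_case)) def$n_case else n_case,
                  n_ctrl = if (is.null(n_ctrl)) def$n_ctrl else n_ctrl,
                  typed_mask = def$typed_mask,
                  replicates = if (is.null(replicates)) def$replicates else replicates,
                  seed = seed, scenario_id = name, panel_m = panel_m)
}
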
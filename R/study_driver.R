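#' Scenario configuration for a simulation study
#'
#' Bundles a haplotype panel (or the [ld_spec()] to generate one), a
#' disease model, sampling quotas, the typed-SNP mask and replication
#' settings. The disease-model intercept is calibrated once here (under
#' the scenario seed) so that every replicate shares the same model.
#'
#' @param panel a `haplotype_panel` or an [ld_spec()] (generated with
#'   `panel_m` haplotypes).
#' @param model a [disease_model()].
#' @param n_case,n_ctrl per-replicate case and control quotas.
#' @param typed_mask logical vector (default: all SNPs typed).
#' @param replicates number of simulated datasets.
#' @param alpha_levels nominal significance levels to evaluate.
#' @param seed master seed for the scenario.
#' @param scenario_id label used in summaries.
#' @param panel_m haplotypes to generate when `panel` is an [ld_spec()].
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(panel, model, n_case, n_ctrl,
                            typed_mask = NULL, replicates = 1000,
                            alpha_levels = c(0.05, 0.01), seed = 1,
                            scenario_id = "scenario", panel_m = 10000) {
  if (inherits(panel, "ld_spec")) panel <- generate_panel(panel, m = panel_m)
  stopifnot(inherits(panel, "haplotype_panel"), inherits(model, "disease_model"))
  p <- ncol(panel$haplotypes)
  if (is.null(typed_mask)) typed_mask <- rep(TRUE, p)
  if (length(typed_mask) != p || !any(typed_mask))
    stop("typed_mask must have length p with at least one TRUE entry", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (is.null(model$beta0)) {
    model$beta0 <- .with_seed(seed, calibrate_beta0(panel, model))
  }
  structure(list(panel = panel, model = model, n_case = n_case,
                 n_ctrl = n_ctrl, typed_mask = typed_mask,
                 replicates = replicates, alpha_levels = alpha_levels,
                 seed = seed, scenario_id = scenario_id),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario_config '%s': %d+%d per replicate, %d replicates, %d/%d SNPs typed\n",
              x$scenario_id, x$n_case, x$n_ctrl, x$replicates,
              sum(x$typed_mask), ncol(x$panel$haplotypes)))
  print(x$model)
  invisible(x)
}

#' Analysis-method grid
#'
#' A list of methods to apply to every simulated replicate. Each entry is
#' a list with `kind` in \{`"lkm"`, `"pca"`, `"minp"`\} plus, for `lkm`, a
#' `spec` ([kernel_spec()]); for `pca`, a `threshold_pct`.
#'
#' @param methods list of method entries.
#' @return Object of class `method_grid` with auto-generated labels.
#' @export
method_grid <- function(methods) {
  if (!is.list(methods) || length(methods) == 0)
    stop("methods must be a nonempty list", call. = FALSE)
  labels <- vapply(methods, function(mm) {
    if (is.null(mm$kind) || !mm$kind %in% c("lkm", "pca", "minp"))
      stop("method kind must be one of lkm, pca, minp", call. = FALSE)
    switch(mm$kind,
           lkm = {
             if (!inherits(mm$spec, "kernel_spec"))
               stop("lkm method needs a kernel_spec", call. = FALSE)
             paste0("lkm.", mm$spec$name)
           },
           pca = {
             if (is.null(mm$threshold_pct))
               stop("pca method needs threshold_pct", call. = FALSE)
             paste0("pca.", mm$threshold_pct)
           },
           minp = "minp")
  }, character(1))
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  structure(list(methods = methods, labels = labels), class = "method_grid")
}

#' The nine-column default method grid
#'
#' Individual-SNP min-p, the four kernel machine tests (linear, IBS, and
#' their Beta(1, 25)-weighted versions), and the PCA test at 80/60/40/20
#' percent cumulative variance.
#'
#' @return A [method_grid()].
#' @export
default_method_grid <- function() {
  method_grid(c(
    list(list(kind = "minp")),
    lapply(c("linear", "ibs", "linear.weighted", "ibs.weighted"),
           function(nm) list(kind = "lkm", spec = kernel_spec(nm))),
    lapply(c(80, 60, 40, 20),
           function(th) list(kind = "pca", threshold_pct = th))
  ))
}

# apply one grid method to a masked dataset; failures become NA
.apply_method <- function(mm, ds) {
  tryCatch(
    suppressWarnings(switch(mm$kind,
                            lkm = lkm_test(ds, mm$spec)$p_value,
                            pca = pca_lrt(ds, mm$threshold_pct)$p_value,
                            minp = minp_set_test(ds)$p_set)),
    error = function(e) NA_real_
  )
}

#' Run one simulation replicate
#'
#' Simulates one case-control dataset (seeded by the scenario seed and the
#' replicate index), masks it to the typed SNPs, and applies every grid
#' method. Method failures are downgraded to `NA` so one method cannot
#' poison the others.
#'
#' @param cfg a [scenario_config()].
#' @param grid a [method_grid()].
#' @param rep_index replicate number (1-based).
#' @return named numeric vector of p-values (NA on failure).
#' @export
run_replicate <- function(cfg, grid, rep_index) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(grid, "method_grid"))
  rep_seed <- (cfg$seed + 1000003 * as.numeric(rep_index)) %% 2147483647
  ds <- sample_case_control(cfg$panel, cfg$model, cfg$n_case, cfg$n_ctrl,
                            seed = rep_seed)
  ds <- mask_typed(ds, cfg$typed_mask)
  out <- vapply(grid$methods, .apply_method, numeric(1), ds = ds)
  names(out) <- grid$labels
  out
}

#' Empirical rejection rate with its binomial standard error
#'
#' The proportion of non-missing p-values below `alpha`, with
#' `SE = sqrt(phat (1 - phat) / R)`. Under a null scenario this is the
#' empirical type I error; under an alternative it is the empirical power.
#'
#' @param pvalues vector of p-values (NAs dropped).
#' @param alpha nominal level.
#' @return list with `proportion`, `std_error`, `replicates_used`.
#' @export
empirical_rate <- function(pvalues, alpha) {
  pv <- pvalues[!is.na(pvalues)]
  if (length(pv) == 0) stop("no non-missing p-values", call. = FALSE)
  phat <- mean(pv < alpha)
  list(proportion = phat,
       std_error = sqrt(phat * (1 - phat) / length(pv)),
       replicates_used = length(pv))
}

#' Run a replicated simulation study
#'
#' Applies every grid method to every replicate of every scenario and
#' tabulates empirical rejection rates at each nominal level.
#'
#' @param cfgs a [scenario_config()] or list of them.
#' @param grid a [method_grid()] (default [default_method_grid()]).
#' @param verbose print progress messages.
#' @return data frame (class `simulation_summary`) with columns
#'   `scenario`, `method`, `alpha`, `rate`, `se`, `replicates_used`.
#'   The per-replicate p-value matrices are attached as attribute
#'   `"pvalues"` (a named list of R x n_method matrices).
#' @export
run_study <- function(cfgs, grid = default_method_grid(), verbose = FALSE) {
  if (inherits(cfgs, "scenario_config")) cfgs <- list(cfgs)
  rows <- list()
  pmat_list <- list()
  for (cfg in cfgs) {
    pm <- matrix(NA_real_, cfg$replicates, length(grid$labels),
                 dimnames = list(NULL, grid$labels))
    for (r in seq_len(cfg$replicates)) {
      pm[r, ] <- run_replicate(cfg, grid, r)
      if (verbose && r %% 200 == 0)
        message(cfg$scenario_id, ": replicate ", r, "/", cfg$replicates)
    }
    pmat_list[[cfg$scenario_id]] <- pm
    for (lab in grid$labels) {
      for (a in cfg$alpha_levels) {
        er <- empirical_rate(pm[, lab], a)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = cfg$scenario_id, method = lab, alpha = a,
          rate = er$proportion, se = er$std_error,
          replicates_used = er$replicates_used,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pvalues") <- pmat_list
  class(out) <- c("simulation_summary", "data.frame")
  out
}

#' Write a simulation summary as TSV
#'
#' @param summary a [run_study()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
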
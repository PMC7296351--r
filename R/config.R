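#' Analysis configuration
#'
#' Collects every numeric threshold the pipeline uses in one place, with the
#' defaults of the original analysis: 200 bp summit windows, top-25,000-peak
#' median normalization, a 2-fold replicate-consistent rule for
#' condition-specific DHSs, a 3-fold inducibility filter, expression filters
#' (minimum count 50, universe mean >= 3, 10-fold high-variation set),
#' 50 kb / 100 kb proximity distances, +/-100 bp motif scanning, and
#' 2,000 bp / 10 bp tag-density windows.
#'
#' @param window_halfwidth Half-width in bp of the summit-centered counting
#'   window. The window is half-open, \code{[summit - hw, summit + hw)},
#'   i.e. \code{2 * hw} bp wide.
#' @param top_n_for_norm Number of strongest peaks whose count median defines
#'   each sample's normalization reference.
#' @param specific_fc Fold change required in every replicate pair for a DHS
#'   to be called condition-specific.
#' @param inducible_fc Fold change (stimulated vs resting) required for a
#'   specific DHS to be called inducible.
#' @param expr_min_count Minimum expression (max of the two compared
#'   condition means) for a gene to enter a specific group.
#' @param expr_universe_min_mean Minimum per-condition mean expression (in at
#'   least one condition) for a gene to count as expressed.
#' @param high_var_fc Fold change defining the high-variation gene set.
#' @param proximity_dist Distance in bp for "fraction of genes within"
#'   summaries (TSS to DHS summit).
#' @param closest_gene_max_dist Maximum TSS distance in bp when assigning a
#'   peak to its closest gene.
#' @param motif_scan_halfwidth Half-width in bp of the motif scan window
#'   around summits.
#' @param density_window,density_bin Window and bin size in bp for tag
#'   density matrices and average profiles.
#' @param pseudocount Offset added to both sides of every fold-change ratio.
#' @param significance_count_cutoff Normalized-count cutoff separating
#'   significant peaks from background; \code{NULL} means "derive from the
#'   data" (the pipeline uses the 99th percentile of background-only windows
#'   when simulation truth is available).
#' @param fdr_alpha Benjamini-Hochberg FDR level for the count-rate test and
#'   the footprint caller.
#' @param fp_width_grid Candidate footprint widths (bp) scanned per DHS.
#' @param fp_flank Flank width in bp on each side of a candidate footprint.
#' @param fp_min_cuts Minimum cuts in candidate + flanks for a candidate to
#'   be evaluable.
#' @param fp_scan_radius Half-width in bp of the region around each summit
#'   in which candidate footprints are scanned.
#' @param fp_min_imbalance Minimum strand-imbalance statistic for a footprint
#'   call.
#' @param rng_seed Seed from which all randomness in a run flows.
#' @return An object of class \code{analysis_config} (a validated list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$specific_fc
analysis_config <- function(window_halfwidth = 200,
                            top_n_for_norm = 25000,
                            specific_fc = 2.0,
                            inducible_fc = 3.0,
                            expr_min_count = 50,
                            expr_universe_min_mean = 3.0,
                            high_var_fc = 10.0,
                            proximity_dist = 50000,
                            closest_gene_max_dist = 100000,
                            motif_scan_halfwidth = 100,
                            density_window = 2000,
                            density_bin = 10,
                            pseudocount = 1.0,
                            significance_count_cutoff = NULL,
                            fdr_alpha = 0.05,
                            fp_width_grid = seq(11L, 25L, by = 2L),
                            fp_flank = 35,
                            fp_min_cuts = 30,
                            fp_scan_radius = 50,
                            fp_min_imbalance = 0.6,
                            rng_seed = 1L) {
  cfg <- list(
    window_halfwidth = window_halfwidth,
    top_n_for_norm = top_n_for_norm,
    specific_fc = specific_fc,
    inducible_fc = inducible_fc,
    expr_min_count = expr_min_count,
    expr_universe_min_mean = expr_universe_min_mean,
    high_var_fc = high_var_fc,
    proximity_dist = proximity_dist,
    closest_gene_max_dist = closest_gene_max_dist,
    motif_scan_halfwidth = motif_scan_halfwidth,
    density_window = density_window,
    density_bin = density_bin,
    pseudocount = pseudocount,
    significance_count_cutoff = significance_count_cutoff,
    fdr_alpha = fdr_alpha,
    fp_width_grid = fp_width_grid,
    fp_flank = fp_flank,
    fp_min_cuts = fp_min_cuts,
    fp_scan_radius = fp_scan_radius,
    fp_min_imbalance = fp_min_imbalance,
    rng_seed = rng_seed
  )
  class(cfg) <- "analysis_config"
  validate_config(cfg)
}

#' Validate (and normalize) an analysis configuration
#'
#' Accepts an \code{analysis_config}, a plain named list of overrides, or a
#' path to a YAML file containing such overrides; fills defaults, rejects
#' unknown keys and non-positive thresholds, and returns the normalized
#' configuration. Normalization is idempotent.
#'
#' @param config An \code{analysis_config}, a named list, or a YAML path.
#' @return A validated \code{analysis_config}.
#' @export
validate_config <- function(config) {
  defaults <- formals(analysis_config)
  known <- names(defaults)
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (inherits(config, "analysis_config")) {
    cfg <- unclass(config)
  } else {
    if (!is.list(config)) stop_fmt("config must be a list or YAML path")
    if (length(config) && is.null(names(config))) {
      stop_fmt("config entries must be named")
    }
    unknown <- setdiff(names(config), known)
    if (length(unknown)) {
      stop_fmt("unknown config key(s): %s", paste(unknown, collapse = ", "))
    }
    cfg <- lapply(known, function(k) {
      if (k %in% names(config)) config[[k]] else eval(defaults[[k]])
    })
    names(cfg) <- known
  }

  positive <- c(
    "window_halfwidth", "top_n_for_norm", "specific_fc", "inducible_fc",
    "expr_min_count", "expr_universe_min_mean", "high_var_fc",
    "proximity_dist", "closest_gene_max_dist", "motif_scan_halfwidth",
    "density_window", "density_bin", "fdr_alpha", "fp_flank", "fp_min_cuts",
    "fp_scan_radius"
  )
  for (k in positive) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop_fmt("config key '%s' must be a single positive number", k)
    }
  }
  if (!is.numeric(cfg$pseudocount) || cfg$pseudocount < 0) {
    stop_fmt("pseudocount must be >= 0")
  }
  if (!is.null(cfg$significance_count_cutoff) &&
      cfg$significance_count_cutoff <= 0) {
    stop_fmt("significance_count_cutoff must be positive (or NULL)")
  }
  if (!is.numeric(cfg$fp_width_grid) || any(cfg$fp_width_grid <= 0)) {
    stop_fmt("fp_width_grid must be positive")
  }
  if (cfg$fp_min_imbalance < 0 || cfg$fp_min_imbalance > 1) {
    stop_fmt("fp_min_imbalance must lie in [0, 1]")
  }
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-26s %s\n", k,
                if (is.null(v)) "<derive from data>"
                else paste(format(v), collapse = " ")))
  }
  invisible(x)
}
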
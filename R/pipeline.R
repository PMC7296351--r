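# End-to-end orchestration over a synthetic (or pre-built) study bundle.
# Stage outputs are plain files in outdir; a manifest records the config
# hash so resumed runs cannot silently mix configurations.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on a synthetic bundle:
#' quantify (counts come with the bundle) -> normalize -> significant peaks
#' / union / repeat exclusion -> DHS classification (specific + inducible)
#' -> expression groups -> proximity & overlap integration -> profiles and
#' footprints (when cut tracks are present) -> run report. All outputs are
#' plain files under \code{outdir}; rerunning with the same seed gives
#' byte-identical files. With \code{resume = TRUE}, stages whose output
#' files already exist are loaded rather than recomputed; the stored config
#' hash must match.
#'
#' @param config An \code{\link{analysis_config}} (or overrides list/YAML
#'   path accepted by \code{\link{validate_config}}).
#' @param sim A \code{\link{sim_params}} object or a ready
#'   \code{chromaprime_sim} bundle.
#' @param outdir Output directory (created if needed).
#' @param n_perm Permutations for the proximity enrichment test.
#' @param resume Load existing stage outputs instead of recomputing.
#' @param emit_tracks Passed to \code{\link{simulate_study}} when \code{sim}
#'   is a parameter object.
#' @return A \code{chromaprime_run} report (invisibly also written as
#'   \code{report.json}).
#' @export
run_pipeline <- function(config = analysis_config(), sim = sim_params(),
                         outdir, n_perm = 1000, resume = FALSE,
                         emit_tracks = TRUE) {
  config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  manifest_path <- file.path(outdir, "manifest.json")
  if (resume && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (!identical(old$config_hash, hash)) {
      stop_fmt("config hash mismatch on resume (%s vs %s)",
               old$config_hash, hash)
    }
  } else if (resume) {
    stop_fmt("cannot resume: no manifest in %s", outdir)
  }

  timings <- c()
  executed <- c()
  stage <- function(name, outputs, compute, load) {
    paths <- file.path(outdir, outputs)
    t0 <- proc.time()[["elapsed"]]
    if (resume && all(file.exists(paths))) {
      res <- load(paths)
      executed[[name]] <<- FALSE
    } else {
      res <- compute(paths)
      executed[[name]] <<- TRUE
    }
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  # --- simulate -----------------------------------------------------------
  if (inherits(sim, "sim_params")) {
    bundle <- simulate_study(sim, emit_tracks = emit_tracks)
  } else if (inherits(sim, "chromaprime_sim")) {
    bundle <- sim
  } else {
    stop_fmt("sim must be sim_params or a chromaprime_sim bundle")
  }
  p <- bundle$params

  stage("inputs",
        c("peaks.bed", "counts.tsv", "genes.tsv", "design.tsv",
          "repeats.bed", "chip.bed", "truth.json"),
        compute = function(paths) {
          write_bed(bundle$peaks, paths[1])
          write_matrix(bundle$counts, paths[2])
          utils::write.table(bundle$genes, paths[3], sep = "\t",
                             quote = FALSE, row.names = FALSE)
          utils::write.table(bundle$design, paths[4], sep = "\t",
                             quote = FALSE, row.names = FALSE)
          write_bed(bundle$repeats, paths[5])
          write_bed(bundle$chip, paths[6])
          write_json_file(list(peaks = bundle$truth_peaks,
                               genes = bundle$truth_genes), paths[7])
          NULL
        },
        load = function(paths) NULL)

  design <- bundle$design
  counts <- bundle$counts

  # --- normalize ----------------------------------------------------------
  top_n <- min(config$top_n_for_norm, nrow(counts))
  norm <- stage("normalize", c("factors.json", "normalized.tsv"),
                compute = function(paths) {
                  fac <- correction_factors(counts, n = top_n)
                  nm <- normalize_counts(counts, fac)
                  write_json_file(list(factors = as.list(fac$factors),
                                       reference_median = fac$reference_median,
                                       top_n = fac$top_n), paths[1])
                  write_matrix(nm, paths[2])
                  list(factors = fac, normalized = nm)
                },
                load = function(paths) {
                  fj <- jsonlite::read_json(paths[1])
                  fac <- list(factors = unlist(fj$factors),
                              reference_median = fj$reference_median,
                              top_n = fj$top_n)
                  class(fac) <- "norm_factors"
                  list(factors = fac, normalized = read_matrix(paths[2]))
                })
  normed <- norm$normalized

  # --- union of significant peaks, repeat exclusion -----------------------
  cutoff <- config$significance_count_cutoff %||%
    (stats::qpois(0.99, p$background_rate * 2 * 2 *
                    config$window_halfwidth) + 1)
  cond_mean <- function(cond) {
    cols <- design$sample_id[design$condition == cond]
    rowMeans(normed[, cols, drop = FALSE])
  }
  union_df <- stage("union", "union.bed",
                    compute = function(paths) {
                      sig <- unique(unlist(lapply(colnames(normed),
                        function(s) significant_peaks(normed[, s], cutoff))))
                      upk <- bundle$peaks[bundle$peaks$peak_id %in% sig, ,
                                          drop = FALSE]
                      u <- merge_union(list(all = upk),
                                       counts = rowMeans(normed))
                      # carry original ids: disjoint simulated peaks merge
                      # to themselves, so match by summit
                      key <- match(paste(u$chrom, u$summit),
                                   paste(upk$chrom, upk$summit))
                      u$peak_id[!is.na(key)] <- upk$peak_id[key[!is.na(key)]]
                      u <- exclude_repeats(u, bundle$repeats)
                      write_bed(u[, c("chrom", "start", "end", "peak_id",
                                      "summit")], paths)
                      u
                    },
                    load = function(paths) read_bed(paths))

  # --- classify -----------------------------------------------------------
  uids <- union_df$peak_id
  rep_cols <- function(cond) design$sample_id[design$condition == cond]
  cls <- stage("classify", "labels.tsv",
               compute = function(paths) {
                 tc <- rep_cols("T_0"); nc <- rep_cols("N_0")
                 lab <- classify_specific(
                   normed[uids, tc[1]], normed[uids, tc[2]],
                   normed[uids, nc[1]], normed[uids, nc[2]],
                   fc = config$specific_fc,
                   pseudocount = config$pseudocount)
                 t_spec <- lab$peak_id[lab$label == "A_specific"]
                 n_spec <- lab$peak_id[lab$label == "B_specific"]
                 mt_ag <- cond_mean("T_Ag")[uids]
                 mt_0 <- cond_mean("T_0")[uids]
                 mn_ag <- cond_mean("N_Ag")[uids]
                 mn_0 <- cond_mean("N_0")[uids]
                 idhs_t <- inducible_filter(t_spec, mt_ag, mt_0,
                                            fc = config$inducible_fc,
                                            pseudocount = config$pseudocount)
                 idhs_n <- inducible_filter(n_spec, mn_ag, mn_0,
                                            fc = config$inducible_fc,
                                            pseudocount = config$pseudocount)
                 lab$inducible <- lab$peak_id %in% c(idhs_t, idhs_n)
                 utils::write.table(lab, paths, sep = "\t", quote = FALSE,
                                    row.names = FALSE)
                 lab
               },
               load = function(paths)
                 utils::read.delim(paths, stringsAsFactors = FALSE))

  # --- expression groups --------------------------------------------------
  gdesign <- data.frame(
    sample_id = grep("_r[0-9]+$", names(bundle$genes), value = TRUE),
    stringsAsFactors = FALSE
  )
  gdesign$condition <- sub("_r[0-9]+$", "", gdesign$sample_id)
  genes <- condition_means(bundle$genes, gdesign)
  conds <- unique(gdesign$condition)
  groups <- stage("groups", "groups.json",
                  compute = function(paths) {
                    uni <- expressed_universe(genes, conds,
                                              config$expr_universe_min_mean)
                    gr <- list(
                      universe = uni,
                      T0_specific = condition_specific_genes(
                        genes, "T_0", "N_0", fc = 2,
                        min_count = config$expr_min_count,
                        pseudocount = config$pseudocount, universe = uni),
                      N0_specific = condition_specific_genes(
                        genes, "N_0", "T_0", fc = 2,
                        min_count = config$expr_min_count,
                        pseudocount = config$pseudocount, universe = uni),
                      TAg_specific = inducible_specific_genes(
                        genes, "T_Ag", "N_Ag", "T_0", fc = 2,
                        min_count = config$expr_min_count,
                        pseudocount = config$pseudocount, universe = uni),
                      NAg_specific = inducible_specific_genes(
                        genes, "N_Ag", "T_Ag", "N_0", fc = 2,
                        min_count = config$expr_min_count,
                        pseudocount = config$pseudocount, universe = uni),
                      high_variation = high_variation_set(
                        genes, list(c("T_0", "N_0"), c("T_Ag", "N_Ag"),
                                    c("T_Ag", "T_0"), c("N_Ag", "N_0")),
                        fc = config$high_var_fc,
                        pseudocount = config$pseudocount, universe = uni)
                    )
                    write_json_file(gr, paths)
                    gr
                  },
                  load = function(paths) {
                    gr <- jsonlite::read_json(paths)
                    lapply(gr, function(x) unlist(x) %||% character(0))
                  })

  # --- integrate ----------------------------------------------------------
  integ <- stage("integrate", "proximity.json",
                 compute = function(paths) {
                   t_spec_pk <- union_df[union_df$peak_id %in%
                     cls$peak_id[cls$label == "A_specific"], , drop = FALSE]
                   uni_g <- genes[genes$gene_id %in% groups$universe, ,
                                  drop = FALSE]
                   grp_g <- genes[genes$gene_id %in% groups$TAg_specific, ,
                                  drop = FALSE]
                   res <- list()
                   if (nrow(grp_g) && nrow(grp_g) < nrow(uni_g) &&
                         nrow(t_spec_pk)) {
                     res$fraction_within <- fraction_within(
                       grp_g, t_spec_pk, config$proximity_dist)
                     enr <- permutation_enrichment(
                       grp_g, uni_g, t_spec_pk, config$proximity_dist,
                       n_perm = n_perm, seed = config$rng_seed)
                     res$permutation_p <- enr$p
                     res$null_mean <- enr$null_mean
                   }
                   if (nrow(t_spec_pk) && nrow(bundle$chip)) {
                     v <- overlap_venn(t_spec_pk, bundle$chip)
                     res$venn <- v[c("A_only", "B_only", "both_A", "both_B")]
                   }
                   write_json_file(res, paths)
                   res
                 },
                 load = function(paths) jsonlite::read_json(paths))

  # --- profiles + footprints (need tracks) --------------------------------
  fps <- NULL
  if (!is.null(bundle$tracks)) {
    fps <- stage("footprints", c("footprints.tsv", "avg_profile.tsv"),
                 compute = function(paths) {
                   tr <- bundle$tracks[[1]]
                   t_spec_pk <- union_df[union_df$peak_id %in%
                     cls$peak_id[cls$label == "A_specific"], , drop = FALSE]
                   if (!nrow(t_spec_pk)) return(NULL)
                   fp <- call_footprints(
                     t_spec_pk, tr, widths = config$fp_width_grid,
                     flank = config$fp_flank,
                     scan_radius = config$fp_scan_radius,
                     min_cuts = config$fp_min_cuts,
                     alpha = config$fdr_alpha,
                     min_imbalance = config$fp_min_imbalance)
                   utils::write.table(fp, paths[1], sep = "\t",
                                      quote = FALSE, row.names = FALSE)
                   prof <- average_profile(t_spec_pk, tr,
                                           window = config$density_window,
                                           bin = config$density_bin)
                   utils::write.table(
                     data.frame(offset = names(prof), mean_cuts = prof),
                     paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
                   fp
                 },
                 load = function(paths)
                   utils::read.delim(paths[1], stringsAsFactors = FALSE))
  }

  report <- list(
    config_hash = hash,
    seed = p$seed,
    n_peaks_input = nrow(bundle$peaks),
    n_union = nrow(union_df),
    n_T_specific = sum(cls$label == "A_specific"),
    n_N_specific = sum(cls$label == "B_specific"),
    n_shared = sum(cls$label == "shared"),
    n_inducible = sum(cls$inducible),
    group_sizes = lapply(groups, length),
    fraction_within = integ$fraction_within %||% NA,
    permutation_p = integ$permutation_p %||% NA,
    venn = integ$venn %||% NA,
    n_footprints_called = if (is.null(fps)) NA else sum(fps$called)
  )
  write_json_file(report, file.path(outdir, "report.json"))
  write_json_file(
    list(config_hash = hash,
         files = sort(setdiff(list.files(outdir), "manifest.json"))),
    manifest_path)

  out <- c(report, list(timings = timings, executed = executed,
                        outdir = outdir))
  class(out) <- "chromaprime_run"
  invisible(out)
}

#' @export
print.chromaprime_run <- function(x, ...) {
  cat("chromaprime pipeline run\n")
  cat(sprintf("  union peaks        %d\n", x$n_union))
  cat(sprintf("  T-specific DHSs    %d (inducible %d)\n",
              x$n_T_specific, x$n_inducible))
  cat(sprintf("  N-specific DHSs    %d\n", x$n_N_specific))
  cat(sprintf("  gene groups        %s\n",
              paste(sprintf("%s=%d", names(x$group_sizes),
                            unlist(x$group_sizes)), collapse = ", ")))
  if (!is.na(x$fraction_within)) {
    cat(sprintf("  fraction within    %.3f (perm p %.4g)\n",
                x$fraction_within, x$permutation_p))
  }
  if (!is.null(x$n_footprints_called) && !is.na(x$n_footprints_called)) {
    cat(sprintf("  footprints called  %d\n", x$n_footprints_called))
  }
  invisible(x)
}
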
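#' Simulation parameters for the synthetic DNase-seq / RNA-seq generator
#'
#' Defaults emulate the statistical structure the analysis assumes: 20,000
#' peaks on a toy multi-chromosome genome, 5\% specific to each condition at
#' 4-fold effect, half of the specific peaks inducible (a further 4-fold in
#' the stimulated samples of their own side), negative-binomially dispersed
#' cut counts (dispersion 0.05) around 50 expected cuts per shared peak,
#' two replicates per condition, and an expression table whose
#' stimulation-specific gene group is enriched for proximity to specific
#' DHSs (planted within-50-kb fraction 0.25 against a 0.05 background).
#'
#' @param n_peaks Number of peaks.
#' @param peak_spacing Summit grid spacing in bp (keeps +/-200 bp windows
#'   disjoint).
#' @param peak_halfwidth Peak interval half-width in bp.
#' @param n_chroms Number of peak-bearing chromosomes.
#' @param frac_A_specific,frac_B_specific Fractions of peaks specific to
#'   condition A (tolerized, "T") and B (naive, "N").
#' @param frac_inducible Fraction of specific peaks that are inducible.
#' @param effect_specific,effect_inducible Fold effects for specific and
#'   inducible peaks.
#' @param dispersion Negative-binomial dispersion of peak cut counts.
#' @param mean_cuts Expected cuts per shared peak window at depth 1.
#' @param background_rate Background cut rate per bp per strand.
#' @param n_replicates DNase replicates per condition.
#' @param depth_range Per-sample depth factors drawn uniformly from this
#'   range.
#' @param n_genes Total genes; \code{n_group_genes} of them form the
#'   stimulation-specific group used for proximity recovery.
#' @param n_group_genes Genes in the A-stimulation-specific group.
#' @param n_rest_specific_genes Genes specific to resting condition A.
#' @param n_high_var_genes Genes with an extreme (16-fold) effect feeding
#'   the high-variation set.
#' @param base_expr Baseline expression mean.
#' @param expr_dispersion NB dispersion of expression values.
#' @param gene_effect Fold effect of differential genes.
#' @param n_expr_replicates Expression replicates per condition.
#' @param link_prob Probability a group gene is placed within
#'   \code{link_dist} of a specific DHS summit.
#' @param background_link_prob Same probability for non-group genes.
#' @param link_dist Planted proximity distance in bp.
#' @param motif_prob_target,motif_prob_background Probability of planting a
#'   motif instance in an A-specific / other peak's scan window.
#' @param frac_footprint Fraction of A-specific peaks with a planted
#'   footprint (carved into the cut tracks).
#' @param fp_width,fp_depletion,fp_strand_bias,fp_flank_boost Footprint
#'   plant geometry: width in bp, central cut thinning probability,
#'   probability that added flank cuts take the occupancy-signature strand,
#'   and the added flank cuts as a fraction of the peak's cuts.
#' @param frac_repeat Fraction of shared peaks overlapped by a planted
#'   repeat (SINE-like) interval.
#' @param n_chip_background Background intervals in the synthetic ChIP set.
#' @param chip_frac Fraction of A-specific peaks covered by a ChIP peak.
#' @param seed RNG seed; the full bundle is reproducible from it.
#' @return A validated list of class \code{sim_params}.
#' @export
sim_params <- function(n_peaks = 20000,
                       peak_spacing = 600,
                       peak_halfwidth = 150,
                       n_chroms = 4,
                       frac_A_specific = 0.05,
                       frac_B_specific = 0.05,
                       frac_inducible = 0.5,
                       effect_specific = 4,
                       effect_inducible = 4,
                       dispersion = 0.05,
                       mean_cuts = 50,
                       background_rate = 5e-4,
                       n_replicates = 2,
                       depth_range = c(0.6, 1.5),
                       n_genes = 1200,
                       n_group_genes = 200,
                       n_rest_specific_genes = 100,
                       n_high_var_genes = 50,
                       base_expr = 100,
                       expr_dispersion = 0.1,
                       gene_effect = 4,
                       n_expr_replicates = 3,
                       link_prob = 0.25,
                       background_link_prob = 0.05,
                       link_dist = 50000,
                       motif_prob_target = 0.7,
                       motif_prob_background = 0.1,
                       frac_footprint = 0.3,
                       fp_width = 15,
                       fp_depletion = 0.6,
                       fp_strand_bias = 0.8,
                       fp_flank_boost = 0.7,
                       frac_repeat = 0.02,
                       n_chip_background = 500,
                       chip_frac = 0.6,
                       seed = 7L) {
  p <- as.list(environment())
  if (p$frac_A_specific + p$frac_B_specific > 1) {
    stop_fmt("class fractions must sum to <= 1")
  }
  stopifnot(p$n_peaks >= 0, p$peak_spacing > 2 * p$peak_halfwidth,
            p$dispersion > 0, p$mean_cuts > 0, p$n_replicates >= 1,
            p$fp_depletion >= 0, p$fp_depletion <= 1)
  class(p) <- "sim_params"
  p
}

sim_conditions <- function() {
  data.frame(
    condition = c("T_0", "T_Ag", "N_0", "N_Ag"),
    side = c("A", "A", "B", "B"),
    stimulated = c(FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

# Expected cut mean of one peak in one condition (depth 1).
peak_mu <- function(class, inducible, side, stimulated, p) {
  mu <- rep(p$mean_cuts, length(class))
  own <- (class == "A_specific" & side == "A") |
    (class == "B_specific" & side == "B")
  mu[own] <- mu[own] * p$effect_specific
  ind <- own & inducible & stimulated
  mu[ind] <- mu[ind] * p$effect_inducible
  mu
}

#' Generate a synthetic study bundle with planted ground truth
#'
#' Draws a complete desk-scale study from \code{\link{sim_params}}: peaks
#' with summits, per-sample stranded cut tracks (optional), the raw count
#' matrix, a gene table with TSS positions and per-replicate expression, a
#' motif-planted sequence set, repeat and ChIP interval sets, and truth
#' tables recording every planted class, effect, link and footprint.
#' Identical seeds give identical bundles.
#'
#' When \code{emit_tracks} is \code{TRUE}, the count matrix is obtained by
#' counting the realized cut positions in the summit windows, so window
#' counting and the matrix agree exactly; otherwise counts are drawn
#' directly at the count level (no tracks, no planted footprints).
#'
#' @param params A \code{\link{sim_params}} object.
#' @param emit_tracks Generate per-sample cut tracks (and carve planted
#'   footprints into them).
#' @param emit_sequences Generate per-peak scan-window sequences with
#'   planted motif instances.
#' @return A list of class \code{chromaprime_sim}; see Details for
#'   components.
#' @export
simulate_study <- function(params = sim_params(), emit_tracks = TRUE,
                           emit_sequences = TRUE) {
  p <- params
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(p$seed)

  hw <- 200L  # quantification window half-width the bundle is built for
  conds <- sim_conditions()
  design <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    data.frame(sample_id = paste0(conds$condition[i], "_r",
                                  seq_len(p$n_replicates)),
               condition = conds$condition[i],
               side = conds$side[i],
               stimulated = conds$stimulated[i],
               replicate = seq_len(p$n_replicates),
               stringsAsFactors = FALSE)
  }))
  design$depth <- stats::runif(nrow(design), p$depth_range[1],
                               p$depth_range[2])

  # --- peaks on a summit grid ---------------------------------------------
  per_chrom <- rep(p$n_peaks %/% p$n_chroms, p$n_chroms)
  extra <- p$n_peaks %% p$n_chroms
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  chroms <- paste0("chr", seq_len(p$n_chroms))
  chrom_sizes <- stats::setNames(
    as.integer((per_chrom + 1L) * p$peak_spacing), chroms)
  gene_desert <- c(chrG = 10000000L)
  off <- p$peak_spacing %/% 2L
  peaks <- do.call(rbind, lapply(seq_len(p$n_chroms), function(ci) {
    n <- per_chrom[ci]
    if (!n) return(NULL)
    summit <- off + p$peak_spacing * (seq_len(n) - 1L)
    data.frame(chrom = chroms[ci], start = summit - p$peak_halfwidth,
               end = summit + p$peak_halfwidth, summit = summit,
               stringsAsFactors = FALSE)
  }))
  if (is.null(peaks)) {
    peaks <- data.frame(chrom = character(), start = integer(),
                        end = integer(), summit = integer(),
                        stringsAsFactors = FALSE)
  }
  if (nrow(peaks)) {
    peaks$peak_id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
    peaks <- peaks[, c("chrom", "start", "end", "peak_id", "summit")]
  } else {
    peaks$peak_id <- character(0)
  }

  n <- nrow(peaks)
  nA <- round(p$frac_A_specific * n)
  nB <- round(p$frac_B_specific * n)
  class <- rep("shared", n)
  if (n) {
    idx <- sample.int(n, nA + nB)
    class[idx[seq_len(nA)]] <- "A_specific"
    if (nB) class[idx[nA + seq_len(nB)]] <- "B_specific"
  }
  inducible <- rep(FALSE, n)
  spec <- which(class != "shared")
  if (length(spec)) {
    inducible[sample(spec, round(p$frac_inducible * length(spec)))] <- TRUE
  }
  fp_flag <- rep(FALSE, n)
  aspec <- which(class == "A_specific")
  if (length(aspec) && p$frac_footprint > 0) {
    fp_flag[sample(aspec, round(p$frac_footprint * length(aspec)))] <- TRUE
  }
  truth_peaks <- data.frame(
    peak_id = peaks$peak_id, class = class, inducible = inducible,
    footprint = fp_flag,
    effect = ifelse(class == "shared", 1, p$effect_specific),
    stringsAsFactors = FALSE
  )

  # --- raw counts (and tracks) --------------------------------------------
  counts <- matrix(0L, n, nrow(design),
                   dimnames = list(peaks$peak_id, design$sample_id))
  tracks <- NULL
  if (n) {
    mus <- vapply(seq_len(nrow(design)), function(si) {
      peak_mu(class, inducible, design$side[si], design$stimulated[si], p) *
        design$depth[si]
    }, numeric(n))
    draws <- matrix(stats::rnbinom(length(mus), mu = mus,
                                   size = 1 / p$dispersion),
                    n, nrow(design), dimnames = dimnames(counts))
    if (emit_tracks) {
      tracks <- lapply(seq_len(nrow(design)), function(si) {
        realize_track(peaks, draws[, si], fp_flag, chrom_sizes, p, hw)
      })
      names(tracks) <- design$sample_id
      counts <- count_matrix(peaks, tracks, halfwidth = hw)
    } else {
      bg <- matrix(stats::rpois(length(draws),
                                p$background_rate * 2 * 2 * hw),
                   n, nrow(design))
      counts <- draws + bg
      attr(counts, "normalized") <- FALSE
    }
  }

  # --- genes ---------------------------------------------------------------
  genes <- simulate_genes(p, peaks, truth_peaks, gene_desert, chrom_sizes)

  # --- sequences + motif truth --------------------------------------------
  sequences <- NULL
  motif_truth <- NULL
  if (emit_sequences && n) {
    sq <- plant_motif_sequences(peaks, class, p)
    sequences <- sq$sequences
    motif_truth <- sq$truth
  }

  # --- repeats -------------------------------------------------------------
  shared_idx <- which(class == "shared")
  n_rep <- round(p$frac_repeat * length(shared_idx))
  rep_idx <- if (n_rep) sample(shared_idx, n_rep) else integer(0)
  repeats <- if (length(rep_idx)) {
    data.frame(chrom = peaks$chrom[rep_idx],
               start = peaks$summit[rep_idx] - 50L,
               end = peaks$summit[rep_idx] + 50L,
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  }

  # --- ChIP set ------------------------------------------------------------
  chip_idx <- if (length(aspec)) {
    sort(sample(aspec, round(p$chip_frac * length(aspec))))
  } else integer(0)
  chip_fg <- if (length(chip_idx)) {
    data.frame(chrom = peaks$chrom[chip_idx],
               start = peaks$summit[chip_idx] - 150L,
               end = peaks$summit[chip_idx] + 150L,
               stringsAsFactors = FALSE)
  } else NULL
  chip_bg <- if (p$n_chip_background > 0) {
    bgpos <- sample.int(gene_desert[["chrG"]] - 301L, p$n_chip_background)
    data.frame(chrom = "chrG", start = bgpos, end = bgpos + 300L,
               stringsAsFactors = FALSE)
  } else NULL
  chip <- rbind(chip_fg, chip_bg)
  if (is.null(chip)) {
    chip <- data.frame(chrom = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  }

  out <- list(
    params = p,
    chrom_sizes = c(chrom_sizes, gene_desert),
    design = design,
    peaks = peaks,
    truth_peaks = truth_peaks,
    counts = counts,
    tracks = tracks,
    genes = genes$table,
    truth_genes = genes$truth,
    sequences = sequences,
    motif_truth = motif_truth,
    repeats = repeats,
    chip = chip,
    truth_repeat_peaks = peaks$peak_id[rep_idx],
    truth_chip_peaks = peaks$peak_id[chip_idx]
  )
  class(out) <- "chromaprime_sim"
  out
}

#' @export
print.chromaprime_sim <- function(x, ...) {
  cat(sprintf(
    "chromaprime_sim: %d peaks (%d A-spec, %d B-spec), %d samples, %d genes%s\n",
    nrow(x$peaks), sum(x$truth_peaks$class == "A_specific"),
    sum(x$truth_peaks$class == "B_specific"), nrow(x$design),
    nrow(x$genes), if (is.null(x$tracks)) ", counts only" else ", with tracks"))
  invisible(x)
}

# Place one sample's cuts on the genome: per-peak draws uniformly inside the
# +/-hw summit window (footprint peaks get central thinning plus
# strand-biased flank cuts), plus Poisson background outside windows.
realize_track <- function(peaks, draws, fp_flag, chrom_sizes, p, hw) {
  n <- nrow(peaks)
  pk <- rep.int(seq_len(n), draws)
  summit <- peaks$summit[pk]
  pos <- summit - hw + floor(stats::runif(length(pk)) * (2 * hw))
  strand_plus <- stats::runif(length(pk)) < 0.5
  chrom <- peaks$chrom[pk]

  half_w <- p$fp_width %/% 2L
  in_central <- fp_flag[pk] & abs(pos - summit) <= half_w
  drop <- in_central & stats::runif(length(pk)) < p$fp_depletion
  pos <- pos[!drop]; strand_plus <- strand_plus[!drop]
  chrom <- chrom[!drop]

  # strand-offset flank cuts for footprint peaks
  fp_idx <- which(fp_flag)
  if (length(fp_idx)) {
    n_add <- round(p$fp_flank_boost * draws[fp_idx])
    tot <- sum(n_add)
    if (tot > 0) {
      fpk <- rep.int(fp_idx, n_add)
      fsummit <- peaks$summit[fpk]
      upstream <- stats::runif(tot) < 0.5
      flank_lo <- ifelse(upstream, fsummit - half_w - 35L, fsummit + half_w + 1L)
      fpos <- flank_lo + floor(stats::runif(tot) * 35)
      # occupancy signature: plus strand upstream, minus strand downstream
      sig <- stats::runif(tot) < p$fp_strand_bias
      fplus <- ifelse(upstream, sig, !sig)
      pos <- c(pos, fpos)
      strand_plus <- c(strand_plus, fplus)
      chrom <- c(chrom, peaks$chrom[fpk])
    }
  }

  plus <- list(); minus <- list()
  spacing <- p$peak_spacing
  off <- spacing %/% 2L
  for (ch in names(chrom_sizes)) {
    L <- chrom_sizes[[ch]]
    sel <- chrom == ch
    pv <- integer(L); mv <- integer(L)
    if (any(sel)) {
      cp <- pos[sel]; sp <- strand_plus[sel]
      keep <- cp >= 0 & cp < L
      cp <- cp[keep]; sp <- sp[keep]
      if (any(sp)) pv <- tabulate(cp[sp] + 1L, nbins = L)
      if (any(!sp)) mv <- tabulate(cp[!sp] + 1L, nbins = L)
    }
    # background cuts outside summit windows
    for (side in c("p", "m")) {
      nbg <- stats::rpois(1, p$background_rate * L)
      if (nbg > 0) {
        bpos <- floor(stats::runif(nbg) * L)
        rel <- (bpos - off) %% spacing
        bpos <- bpos[rel >= hw & rel < spacing - hw]
        if (length(bpos)) {
          add <- tabulate(bpos + 1L, nbins = L)
          if (side == "p") pv <- pv + add else mv <- mv + add
        }
      }
    }
    plus[[ch]] <- pv
    minus[[ch]] <- mv
  }
  cut_track(chrom_sizes, plus = plus, minus = minus)
}

# Gene table with planted expression groups and planted DHS proximity.
simulate_genes <- function(p, peaks, truth_peaks, gene_desert, chrom_sizes) {
  ng <- p$n_genes
  cls <- rep("stable", ng)
  n_named <- p$n_group_genes + p$n_rest_specific_genes + p$n_high_var_genes
  if (n_named > ng) stop_fmt("gene class counts exceed n_genes")
  idx <- sample.int(ng, n_named)
  cls[idx[seq_len(p$n_group_genes)]] <- "TAg_specific"
  cls[idx[p$n_group_genes + seq_len(p$n_rest_specific_genes)]] <-
    "T0_specific"
  cls[idx[p$n_group_genes + p$n_rest_specific_genes +
            seq_len(p$n_high_var_genes)]] <- "high_var"
  gene_id <- sprintf("gene_%04d", seq_len(ng))

  # planted proximity: linked genes land within link_dist of an A-specific
  # summit, all others in a peak-free gene desert. Exactly round(prob * n)
  # genes per stratum are linked, so the planted fraction is exact by
  # design rather than a Bernoulli realization.
  aspec <- which(truth_peaks$class == "A_specific")
  linked <- logical(ng)
  for (stratum in list(which(cls == "TAg_specific"),
                       which(cls != "TAg_specific"))) {
    prob <- if (length(stratum) && cls[stratum[1]] == "TAg_specific")
      p$link_prob else p$background_link_prob
    k <- round(prob * length(stratum))
    if (k > 0) linked[sample(stratum, k)] <- TRUE
  }
  if (!length(aspec)) linked[] <- FALSE
  chrom <- rep("chrG", ng)
  tss <- floor(stats::runif(ng) * (gene_desert[["chrG"]] - 1L))
  if (any(linked)) {
    anchor <- aspec[sample.int(length(aspec), sum(linked), replace = TRUE)]
    offset <- floor(stats::runif(sum(linked), -p$link_dist, p$link_dist + 1))
    chrom[linked] <- peaks$chrom[anchor]
    tss[linked] <- pmax(0L, pmin(chrom_sizes[peaks$chrom[anchor]] - 1L,
                                 peaks$summit[anchor] + offset))
    linked_peak <- rep(NA_character_, ng)
    linked_peak[linked] <- peaks$peak_id[anchor]
  } else {
    linked_peak <- rep(NA_character_, ng)
  }

  # per-condition expression means
  mu <- matrix(p$base_expr, ng, 4,
               dimnames = list(gene_id, sim_conditions()$condition))
  e <- p$gene_effect
  mu[cls == "TAg_specific", "T_Ag"] <- p$base_expr * e
  mu[cls == "T0_specific", "T_0"] <- p$base_expr * e
  mu[cls == "T0_specific", "T_Ag"] <- p$base_expr * e
  mu[cls == "high_var", "T_Ag"] <- p$base_expr * 16

  tab <- data.frame(gene_id = gene_id, chrom = chrom, tss = as.integer(tss),
                    strand = "+", stringsAsFactors = FALSE)
  for (cond in colnames(mu)) {
    for (r in seq_len(p$n_expr_replicates)) {
      tab[[paste0(cond, "_r", r)]] <-
        stats::rnbinom(ng, mu = mu[, cond], size = 1 / p$expr_dispersion)
    }
  }
  truth <- data.frame(gene_id = gene_id, class = cls, linked = linked,
                      linked_peak = linked_peak, stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

# Random scan-window sequences with AP-1 instances planted preferentially
# in A-specific peaks. Returns per-peak sequences plus a truth table.
plant_motif_sequences <- function(peaks, class, p, halfwidth = 100) {
  n <- nrow(peaks)
  width <- 2L * halfwidth
  bases <- c("A", "C", "G", "T")
  mat <- matrix(sample(bases, n * width, replace = TRUE), n, width)
  instance <- c("T", "G", "A", "C", "T", "C", "A")  # matches TGASTCA
  has <- stats::runif(n) < ifelse(class == "A_specific",
                                  p$motif_prob_target,
                                  p$motif_prob_background)
  offs <- rep(NA_integer_, n)
  if (any(has)) {
    offs[has] <- sample.int(width - length(instance), sum(has),
                            replace = TRUE)
    for (i in which(has)) {
      mat[i, offs[i] + seq_along(instance) - 1L] <- instance
    }
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- peaks$peak_id
  truth <- data.frame(peak_id = peaks$peak_id, planted = has,
                      offset = offs, stringsAsFactors = FALSE)
  list(sequences = seqs, truth = truth)
}

#' Focused footprint simulation
#'
#' A compact bundle for footprint-caller evaluation: \code{n_dhs} DHSs on
#' one chromosome, a fraction with a planted footprint (central depletion
#' of width \code{fp_width}, strand-offset flank cuts), the rest uniform.
#' With \code{frac_planted = 0} and \code{fp_flank_boost = 0} the cuts are
#' homogeneous, giving the null calibration set.
#'
#' @param n_dhs Number of DHSs.
#' @param frac_planted Fraction with a planted footprint.
#' @param cuts_per_dhs Expected cuts per DHS window.
#' @param fp_width,fp_depletion,fp_strand_bias,fp_flank_boost Plant
#'   geometry as in \code{\link{sim_params}}.
#' @param window_halfwidth DHS cut window half-width in bp (default 100).
#' @param seed RNG seed.
#' @return List: \code{peaks}, \code{track}, \code{truth} (logical vector).
#' @export
simulate_footprint_dhs <- function(n_dhs = 500, frac_planted = 0.5,
                                   cuts_per_dhs = 250, fp_width = 15,
                                   fp_depletion = 0.6, fp_strand_bias = 0.8,
                                   fp_flank_boost = 0.7,
                                   window_halfwidth = 100, seed = 7L) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(seed)
  spacing <- 600L
  chrom_sizes <- c(chrF = as.integer((n_dhs + 1L) * spacing))
  summit <- spacing %/% 2L + spacing * (seq_len(n_dhs) - 1L)
  peaks <- data.frame(chrom = "chrF", start = summit - 150L,
                      end = summit + 150L,
                      peak_id = sprintf("dhs_%04d", seq_len(n_dhs)),
                      summit = summit, stringsAsFactors = FALSE)
  truth <- stats::runif(n_dhs) < frac_planted
  draws <- stats::rpois(n_dhs, cuts_per_dhs)
  pars <- sim_params(n_peaks = 0, fp_width = fp_width,
                     fp_depletion = fp_depletion,
                     fp_strand_bias = fp_strand_bias,
                     fp_flank_boost = fp_flank_boost,
                     background_rate = 0, seed = seed)
  track <- realize_track(peaks, draws, truth, chrom_sizes, pars,
                         hw = window_halfwidth)
  list(peaks = peaks, track = track, truth = truth)
}
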
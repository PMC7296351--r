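small_params <- function(seed = 7, ...) {
  sim_params(n_peaks = 400, n_genes = 300, n_group_genes = 60,
             n_rest_specific_genes = 30, n_high_var_genes = 15,
             n_chip_background = 40, seed = seed, ...)
}

test_that("simulation is deterministic in the seed and varies across seeds", {
  s1 <- simulate_study(small_params(seed = 7))
  s2 <- simulate_study(small_params(seed = 7))
  s3 <- simulate_study(small_params(seed = 8))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$tracks[[1]]$plus, s2$tracks[[1]]$plus)
  expect_identical(s1$sequences, s2$sequences)
  expect_false(identical(s1$counts, s3$counts))
  # simulation does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(simulate_study(small_params())); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("truth tables and emitted objects are mutually consistent", {
  s <- simulate_study(small_params())
  expect_setequal(s$truth_peaks$peak_id, s$peaks$peak_id)
  expect_setequal(s$truth_genes$gene_id, s$genes$gene_id)
  expect_true(all(stats::na.omit(s$truth_genes$linked_peak) %in%
                    s$peaks$peak_id))
  expect_true(all(s$truth_repeat_peaks %in% s$peaks$peak_id))
  # every linked gene's TSS really is within link_dist of its peak summit
  linked <- s$truth_genes[s$truth_genes$linked, ]
  smt <- setNames(s$peaks$summit, s$peaks$peak_id)
  tss <- setNames(s$genes$tss, s$genes$gene_id)
  expect_true(all(abs(tss[linked$gene_id] - smt[linked$linked_peak]) <=
                    s$params$link_dist))
  # planted repeats overlap their peaks
  kept <- exclude_repeats(s$peaks, s$repeats)
  expect_setequal(setdiff(s$peaks$peak_id, kept$peak_id),
                  s$truth_repeat_peaks)
  # counts from tracks equal fresh window counting (internal consistency)
  recount <- count_matrix(s$peaks, s$tracks, halfwidth = 200)
  expect_equal(unclass(s$counts), unclass(recount), ignore_attr = TRUE)
})

test_that("realized class means track the planted effects", {
  s <- simulate_study(sim_params(n_peaks = 4000, seed = 11),
                      emit_tracks = FALSE, emit_sequences = FALSE)
  d <- s$design
  cls <- s$truth_peaks$class
  t0 <- rowMeans(s$counts[, d$sample_id[d$condition == "T_0"]]) /
    mean(d$depth[d$condition == "T_0"])
  shared_mean <- mean(t0[cls == "shared"])
  spec_mean <- mean(t0[cls == "A_specific"])
  # shared ~ mean_cuts, A-specific ~ mean_cuts * effect, each within 3 SE
  se_shared <- sd(t0[cls == "shared"]) / sqrt(sum(cls == "shared"))
  se_spec <- sd(t0[cls == "A_specific"]) / sqrt(sum(cls == "A_specific"))
  expect_lt(abs(shared_mean - 50), 3 * se_shared + 1)
  expect_lt(abs(spec_mean - 200), 3 * se_spec + 4)
  # inducible peaks gain their extra fold only when stimulated
  tag <- rowMeans(s$counts[, d$sample_id[d$condition == "T_Ag"]]) /
    mean(d$depth[d$condition == "T_Ag"])
  ind <- cls == "A_specific" & s$truth_peaks$inducible
  notind <- cls == "A_specific" & !s$truth_peaks$inducible
  expect_gt(mean(tag[ind]) / mean(tag[notind]), 3)
  expect_lt(abs(mean(t0[ind]) / mean(t0[notind]) - 1), 0.15)
})

test_that("flat effects produce only FDR-consistent false calls", {
  s <- simulate_study(sim_params(n_peaks = 2000, n_genes = 300,
                                 n_group_genes = 60,
                                 n_rest_specific_genes = 30,
                                 n_high_var_genes = 15, seed = 5,
                                 effect_specific = 1, effect_inducible = 1),
                      emit_tracks = FALSE, emit_sequences = FALSE)
  fac <- correction_factors(s$counts, n = nrow(s$counts))
  nm <- normalize_counts(s$counts, fac)
  d <- s$design
  tc <- d$sample_id[d$condition == "T_0"]; nc <- d$sample_id[d$condition == "N_0"]
  lab <- classify_specific(nm[, tc[1]], nm[, tc[2]], nm[, nc[1]], nm[, nc[2]])
  expect_lt(mean(lab$label != "shared"), 0.01)
})

test_that("an empty simulation is a valid bundle", {
  s <- simulate_study(sim_params(n_peaks = 0, n_genes = 10,
                                 n_group_genes = 2,
                                 n_rest_specific_genes = 2,
                                 n_high_var_genes = 2, seed = 1),
                      emit_tracks = FALSE)
  expect_equal(nrow(s$peaks), 0)
  expect_equal(nrow(s$truth_peaks), 0)
  expect_equal(nrow(s$counts), 0)
  expect_equal(nrow(s$genes), 10)
  expect_false(any(s$truth_genes$linked))
})

test_that("planted motifs are recovered preferentially in target peaks", {
  s <- simulate_study(small_params(seed = 13))
  hits <- scan_motif("TGASTCA", s$sequences, s$peaks, halfwidth = 100)
  got <- unique(hits$peak_id)
  planted <- s$motif_truth$peak_id[s$motif_truth$planted]
  expect_true(all(planted %in% got))  # planted instances always match
  aspec <- s$truth_peaks$peak_id[s$truth_peaks$class == "A_specific"]
  rate_target <- mean(aspec %in% got)
  rate_bg <- mean(setdiff(s$peaks$peak_id, aspec) %in% got)
  expect_gt(rate_target, rate_bg + 0.3)
})

test_that("worked fixture straddles every threshold per its answer key", {
  fx <- worked_fixture()
  key <- fx$answer_key
  m <- fx$norm_counts
  genes <- fx$genes

  lab <- classify_specific(m[, "T_0_r1"], m[, "T_0_r2"],
                           m[, "N_0_r1"], m[, "N_0_r2"])
  expect_setequal(lab$peak_id[lab$label == "A_specific"], key$tdhs)
  expect_setequal(lab$peak_id[lab$label == "B_specific"], key$ndhs)
  stim <- rowMeans(m[, c("T_Ag_r1", "T_Ag_r2")])
  rest <- rowMeans(m[, c("T_0_r1", "T_0_r2")])
  expect_setequal(inducible_filter(key$tdhs, stim, rest, fc = 3), key$idhs)

  conds <- c("T_0", "N_0", "T_Ag", "N_Ag")
  expect_setequal(expressed_universe(genes, conds, 3), key$universe)
  expect_setequal(condition_specific_genes(genes, "T_0", "N_0"),
                  key$T0_specific)
  expect_setequal(condition_specific_genes(genes, "N_0", "T_0"),
                  key$N0_specific)
  expect_setequal(condition_specific_genes(genes, "T_Ag", "N_Ag"),
                  key$TAg_specific_plain)
  expect_setequal(inducible_specific_genes(genes, "T_Ag", "N_Ag", "T_0"),
                  key$TAg_specific_inducible)
  expect_setequal(inducible_specific_genes(genes, "N_Ag", "T_Ag", "N_0"),
                  key$NAg_specific_inducible)
  expect_setequal(
    high_variation_set(genes, list(c("T_0", "N_0"), c("T_Ag", "N_Ag"),
                                   c("T_Ag", "T_0"), c("N_Ag", "N_0"))),
    key$high_variation)

  tdhs_pk <- fx$peaks[fx$peaks$peak_id %in% key$tdhs, ]
  prox <- genes[genes$gene_id %in% key$proximity_genes, ]
  expect_equal(fraction_within(prox, tdhs_pk, 50000),
               key$fraction_within_50kb)
  expect_equal(unname(distance_bins(prox, tdhs_pk, key$distance_bin_edges)),
               key$distance_bin_fractions)
  v <- overlap_venn(tdhs_pk, fx$chip)
  expect_equal(v$A_only, key$venn$A_only)
  expect_equal(v$both_A, key$venn$both_A)
  expect_equal(v$B_only, key$venn$B_only)
  expect_equal(nrow(exclude_repeats(fx$peaks, fx$repeats)),
               key$n_after_repeat_exclusion)
  asn <- closest_tss_assignment(fx$peaks, genes)
  expect_equal(asn$gene_id[asn$peak_id == "p01"], key$closest$p01)
  expect_equal(asn$gene_id[asn$peak_id == "p30"], key$closest$p30)
  expect_equal(asn$distance[asn$peak_id == "p30"], key$closest$p30_distance)
  expect_equal(asn$gene_id[asn$peak_id == "p07"], key$closest$p07)
})

test_that("single-value perturbations flip exactly the expected memberships", {
  fx <- worked_fixture()
  m <- fx$norm_counts
  genes <- fx$genes

  # ratio boundary: nudging one replicate drops p03 from the tDHS set
  m2 <- m; m2["p03", "N_0_r1"] <- 10
  lab <- classify_specific(m2[, "T_0_r1"], m2[, "T_0_r2"],
                           m2[, "N_0_r1"], m2[, "N_0_r2"])
  expect_setequal(lab$peak_id[lab$label == "A_specific"],
                  setdiff(fx$answer_key$tdhs, "p03"))
  # inducibility boundary: 128 -> 127 moves p01 off the exact 3.0 ratio
  m3 <- m; m3["p01", c("T_Ag_r1", "T_Ag_r2")] <- 127
  stim <- rowMeans(m3[, c("T_Ag_r1", "T_Ag_r2")])
  rest <- rowMeans(m3[, c("T_0_r1", "T_0_r2")])
  expect_setequal(inducible_filter(fx$answer_key$tdhs, stim, rest, fc = 3),
                  setdiff(fx$answer_key$idhs, "p01"))
  # expression ratio boundary: g01 at 100 instead of 101 leaves the group
  g2 <- genes; g2$mean_T_0[g2$gene_id == "g01"] <- 100
  expect_setequal(condition_specific_genes(g2, "T_0", "N_0"),
                  setdiff(fx$answer_key$T0_specific, "g01"))
  # min-count boundary: g04 at 49 fails the minimum read count
  g3 <- genes; g3$mean_T_0[g3$gene_id == "g04"] <- 49
  expect_setequal(condition_specific_genes(g3, "T_0", "N_0"),
                  setdiff(fx$answer_key$T0_specific, "g04"))
  # distance boundary: moving g15 one bp further drops the 50-kb fraction
  g4 <- genes; g4$tss[g4$gene_id == "g15"] <- 125001L
  tdhs_pk <- fx$peaks[fx$peaks$peak_id %in% fx$answer_key$tdhs, ]
  prox <- g4[g4$gene_id %in% fx$answer_key$proximity_genes, ]
  expect_equal(fraction_within(prox, tdhs_pk, 50000), 0.25)
})
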
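test_that("significant_peaks filters by cutoff", {
  col <- c(a = 1, b = 5, c = 10)
  expect_equal(significant_peaks(col, 5), c("b", "c"))
  expect_equal(significant_peaks(col, 1e-9), c("a", "b", "c"))
  expect_error(significant_peaks(col, 0), "positive")
  withr::with_seed(2, {
    rc <- setNames(rpois(500, 20), sprintf("p%03d", 1:500))
    cut <- runif(1, 1, 40)
  })
  expect_equal(significant_peaks(rc, cut), names(rc)[rc >= cut])
})

test_that("merge_union equals the pairwise-merge-to-fixpoint oracle", {
  # bookended intervals merge
  two <- data.frame(chrom = "chr1", start = c(100L, 200L),
                    end = c(200L, 300L))
  m <- merge_union(list(x = two))
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 100L)
  expect_equal(m$end, 300L)
  # single set is itself
  one <- data.frame(chrom = "chr1", start = 10L, end = 40L)
  expect_equal(merge_union(list(a = one))[, c("start", "end")],
               data.frame(start = 10L, end = 40L))
  # random instances against the O(n^2) oracle
  for (seed in 1:5) {
    withr::with_seed(seed, df <- random_intervals(200, max_pos = 4000))
    got <- merge_union(list(r = df))
    want <- oracle_merge(df)
    expect_equal(got[, c("chrom", "start", "end")], want)
  }
})

test_that("merged peaks keep the summit of the strongest contributor", {
  a <- data.frame(chrom = "chr1", start = 100L, end = 250L,
                  peak_id = "a1", summit = 150L)
  b <- data.frame(chrom = "chr1", start = 200L, end = 400L,
                  peak_id = "b1", summit = 320L)
  m <- merge_union(list(A = a, B = b), counts = c(a1 = 5, b1 = 9))
  expect_equal(m$summit, 320L)
  expect_equal(m$provenance, "A,B")
  m2 <- merge_union(list(A = a, B = b), counts = c(a1 = 9, b1 = 5))
  expect_equal(m2$summit, 150L)
  # tie goes to the smaller coordinate
  m3 <- merge_union(list(A = a, B = b), counts = c(a1 = 7, b1 = 7))
  expect_equal(m3$summit, 150L)
})

test_that("repeat exclusion removes overlapping peaks only", {
  withr::with_seed(17, peaks <- random_peaks(80, max_pos = 5000))
  expect_identical(exclude_repeats(peaks, NULL), peaks)
  reps <- data.frame(chrom = "chr1", start = 1000L, end = 2000L)
  kept <- exclude_repeats(peaks, reps)
  manual <- peaks[!(peaks$chrom == "chr1" & peaks$start < 2000 &
                      peaks$end > 1000), ]
  rownames(manual) <- NULL
  expect_equal(kept, manual)
  inside <- data.frame(chrom = "chr1", start = 1200L, end = 1250L,
                       peak_id = "in", summit = 1225L)
  expect_equal(nrow(exclude_repeats(inside, reps)), 0)
})

test_that("specific classification applies the both-replicates rule", {
  mk <- function(x) setNames(x, paste0("p", seq_along(x)))
  lab <- classify_specific(mk(c(40, 40)), mk(c(44, 15)),
                           mk(c(10, 10)), mk(c(9, 9)),
                           fc = 2, pseudocount = 1)
  # (40,44) vs (10,9): ratios 41/11 and 45/10, both >= 2
  expect_equal(lab$label[1], "A_specific")
  # (40,15) vs (10,9): second-pair ratio 16/10 = 1.6 breaks the rule
  expect_equal(lab$label[2], "shared")
  expect_equal(lab$fc_pair1[1], 41 / 11)
  expect_equal(lab$fc_pair2[1], 45 / 10)
  expect_error(
    classify_specific(mk(c(1, 2)), mk(c(1, 2)), mk(c(1, 2)),
                      setNames(c(1, 2), c("q1", "q2"))),
    "universe")
})

test_that("classification matches per-peak recomputation and is symmetric, nested, exhaustive", {
  withr::with_seed(23, {
    n <- 10000
    a1 <- rpois(n, 40); a2 <- rpois(n, 40)
    b1 <- rpois(n, 40); b2 <- rpois(n, 40)
  })
  ids <- sprintf("pk%05d", 1:n)
  mk <- function(x) setNames(x, ids)
  lab <- classify_specific(mk(a1), mk(a2), mk(b1), mk(b2), fc = 2)
  # independent per-peak oracle
  want <- vapply(seq_len(n), function(i) {
    r1 <- (a1[i] + 1) / (b1[i] + 1); r2 <- (a2[i] + 1) / (b2[i] + 1)
    if (r1 >= 2 && r2 >= 2) "A_specific"
    else if (1 / r1 >= 2 && 1 / r2 >= 2) "B_specific"
    else "shared"
  }, character(1))
  expect_equal(lab$label, want)
  # every peak gets exactly one label
  expect_true(all(lab$label %in% c("A_specific", "B_specific", "shared")))
  # swapping A and B swaps the specific labels exactly
  swap <- classify_specific(mk(b1), mk(b2), mk(a1), mk(a2), fc = 2)
  expect_equal(swap$label == "A_specific", lab$label == "B_specific")
  expect_equal(swap$label == "B_specific", lab$label == "A_specific")
  # raising fc nests the specific sets
  lab4 <- classify_specific(mk(a1), mk(a2), mk(b1), mk(b2), fc = 4)
  expect_true(all(lab4$peak_id[lab4$label == "A_specific"] %in%
                    lab$peak_id[lab$label == "A_specific"]))
})

test_that("inducible filter honors the at-least boundary and nests over fc", {
  stim <- c(p1 = 30, p2 = 29, p3 = 10)
  rest <- c(p1 = 9, p2 = 9, p3 = 9)
  # 31/10 = 3.1 retained; 30/10 = 3.0 exactly retained ("at least")
  expect_equal(inducible_filter(names(stim), stim, rest, fc = 3),
               c("p1", "p2"))
  withr::with_seed(29, {
    s <- setNames(rpois(2000, 30), sprintf("q%04d", 1:2000))
    r <- setNames(rpois(2000, 15), names(s))
  })
  grids <- lapply(c(1.5, 2, 3, 5), function(fc)
    inducible_filter(names(s), s, r, fc = fc))
  for (i in 2:4) expect_true(all(grids[[i]] %in% grids[[i - 1]]))
})

test_that("count rate test: null identity, planted recovery, BH agreement", {
  ids <- sprintf("p%05d", 1:4000)
  withr::with_seed(37, {
    base <- matrix(rnbinom(8000, mu = 200, size = 20), 4000, 2)
    a <- matrix(rnbinom(8000, mu = 200, size = 20), 4000, 2)
    b <- matrix(rnbinom(8000, mu = 200, size = 20), 4000, 2)
  })
  rownames(base) <- rownames(a) <- rownames(b) <- ids
  # identical columns: p exactly 1 everywhere
  same <- count_rate_test(base, base)
  expect_true(all(same$p >= 0.5))
  # planted 8-fold peaks at high depth: q < 0.05 for >= 95%
  planted <- a
  hot <- 1:200
  withr::with_seed(38,
    planted[hot, ] <- matrix(rnbinom(400, mu = 1600, size = 20), 200, 2))
  res <- count_rate_test(planted, b)
  expect_gte(mean(res$q[hot] < 0.05), 0.95)
  # false-positive control among null peaks
  expect_lte(mean(res$q[-hot] < 0.05), 0.05)
  # BH output equals the step-up oracle
  expect_equal(res$q, oracle_bh(res$p), tolerance = 1e-12)
  expect_error(count_rate_test(base[, 1, drop = FALSE], b), "2 replicates")
})
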
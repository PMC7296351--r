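test_that("tag density matrix: bin arithmetic, ordering, conservation", {
  sizes <- c(chr1 = 4000L)
  ztr <- cut_track(sizes)
  peaks <- data.frame(chrom = "chr1", summit = c(1000L, 2000L),
                      peak_id = c("b", "a"), stringsAsFactors = FALSE)
  zm <- tag_density_matrix(peaks, ztr, window = 200, bin = 10)
  expect_true(all(zm == 0))
  expect_equal(rownames(zm), c("b", "a"))  # given order, not sorted
  # one cut at the summit lands in the single central-right bin
  v <- integer(4000); v[1001] <- 1L
  tr1 <- cut_track(sizes, plus = list(chr1 = v))
  m1 <- tag_density_matrix(peaks, tr1, window = 200, bin = 10)
  expect_equal(sum(m1), 1)
  expect_equal(unname(m1["b", "0"]), 1)
  expect_error(tag_density_matrix(peaks, tr1, window = 200, bin = 30),
               "divide")
  # random case: per-base oracle and exact row-sum conservation
  withr::with_seed(41, tr <- random_track(sizes, n_cuts = 3000))
  withr::with_seed(42, pk <- data.frame(
    chrom = "chr1", summit = sample(300:3700, 30),
    peak_id = sprintf("p%02d", 1:30), stringsAsFactors = FALSE))
  dm <- tag_density_matrix(pk, tr, window = 400, bin = 20)
  for (i in c(1, 7, 30)) {
    for (j in c(1, 10, 20)) {
      lo <- pk$summit[i] - 200 + (j - 1) * 20
      expect_equal(dm[i, j], oracle_window_sum(tr, "chr1", lo, lo + 20))
    }
  }
  expect_equal(unname(rowSums(dm)),
               unname(count_cuts_in_windows(pk, tr, halfwidth = 200)))
})

test_that("average profile is the column mean and reflects planted symmetry", {
  sizes <- c(chr1 = 4000L)
  withr::with_seed(43, tr <- random_track(sizes, n_cuts = 2000))
  pk <- data.frame(chrom = "chr1", summit = seq(500L, 3500L, 500L))
  pk$peak_id <- sprintf("p%d", seq_len(nrow(pk)))
  prof <- average_profile(pk, tr, window = 400, bin = 10)
  expect_equal(unname(prof),
               unname(colMeans(tag_density_matrix(pk, tr, 400, 10))))
  expect_error(average_profile(pk[0, ], tr), "empty")
  # symmetric planted signal gives a symmetric profile within noise
  withr::with_seed(44, {
    sym <- simulate_footprint_dhs(n_dhs = 300, frac_planted = 0,
                                  fp_flank_boost = 0, cuts_per_dhs = 300,
                                  seed = 9)
  })
  sp <- average_profile(sym$peaks, sym$track, window = 160, bin = 20)
  expect_lt(max(abs(sp - rev(sp))) / mean(sp), 0.15)
})

test_that("IUPAC motif scan equals the exhaustive oracle on both strands", {
  peaks <- data.frame(chrom = "chr1", summit = 500L, peak_id = "pk1",
                      stringsAsFactors = FALSE)
  seqs <- c(pk1 = paste0(strrep("A", 90), "TGACTCA", strrep("A", 103)))
  hits <- scan_motif("TGASTCA", seqs, peaks, halfwidth = 100)
  # plus-strand hit at offset 90, plus its reverse complement TGAGTCA
  # does not occur; AP-1 TGACTCA reverse-complements to TGAGTCA
  expect_equal(sum(hits$strand == "+"), 1)
  expect_equal(hits$start[hits$strand == "+"], 400 + 90)
  expect_equal(hits$end[hits$strand == "+"], 400 + 97)
  expect_equal(nrow(scan_motif("TGASTCA",
                               c(pk1 = strrep("C", 200)), peaks)), 0)
  expect_error(scan_motif("TGAZTCA", seqs, peaks), "IUPAC")

  # random sequences, all 15 letters, vs character-level oracle
  withr::with_seed(51, {
    for (consensus in c("GGGRNNYYCC", "TGASTCA", "BDHVKM")) {
      sq <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
      pk <- data.frame(chrom = "chr1", summit = 300L, peak_id = "x",
                       stringsAsFactors = FALSE)
      got <- scan_motif(consensus, c(x = sq), pk, halfwidth = 300)
      fwd <- oracle_iupac_match(consensus, sq)
      rev_ <- oracle_iupac_match(oracle_revcomp(consensus), sq)
      expect_equal(sort(got$start[got$strand == "+"]), sort(fwd),
                   ignore_attr = TRUE)
      expect_equal(sort(got$start[got$strand == "-"]), sort(rev_),
                   ignore_attr = TRUE)
    }
  })
})

test_that("motif presence matrix is a ranked membership indicator", {
  pk <- data.frame(peak_id = c("p3", "p1", "p2"), stringsAsFactors = FALSE)
  hits <- list(
    AP1 = data.frame(peak_id = c("p1", "p1")),
    NFKB = data.frame(peak_id = character(0))
  )
  m <- motif_presence_matrix(pk, hits)
  expect_equal(rownames(m), c("p3", "p1", "p2"))
  expect_equal(unname(m[, "AP1"]), c(0L, 1L, 0L))
  expect_true(all(m[, "NFKB"] == 0))
})

test_that("footprint score matches the closed-form binomial tail", {
  # 0 cuts in candidate, 200 in flanks, w = 15, flank = 35:
  # p = pbinom(0, 200, 15/85) = (70/85)^200
  sizes <- c(chr1 = 2000L)
  v <- integer(2000)
  v[(951 - 35 + 1):951] <- 3L   # 35 bp upstream flank, 105 cuts (plus)
  v2 <- integer(2000)
  v2[(966 + 1):(966 + 35)] <- 3L  # wait adjust below
  # candidate [951, 966) width 15; upstream [916, 951), downstream [966, 1001)
  v <- integer(2000); v[917:951] <- 3L
  v2 <- integer(2000); v2[967:1001] <- 2L
  tr <- cut_track(sizes, plus = list(chr1 = v), minus = list(chr1 = v2))
  sc <- footprint_score(tr, "chr1", 951, 966, flank = 35)
  total <- 35 * 3 + 35 * 2
  expect_equal(sc$total, total)
  expect_equal(sc$k, 0)
  expect_equal(sc$p, pbinom(0, total, 15 / 85), tolerance = 1e-12)
  expect_equal(sc$p, (1 - 15 / 85)^total, tolerance = 1e-12)
  expect_equal(sc$score, -log10((70 / 85)^total), tolerance = 1e-9)
  # perfect occupancy signature: all flank cuts on signature strands
  expect_equal(sc$imbalance, 1)
  # monotone decreasing in candidate cut count
  scores <- vapply(c(0L, 5L, 12L), function(k) {
    vv <- v; if (k > 0) vv[955:(954 + k)] <- 1L
    trk <- cut_track(sizes, plus = list(chr1 = vv), minus = list(chr1 = v2))
    footprint_score(trk, "chr1", 951, 966, flank = 35)$score
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("uniform cuts do not trigger footprint calls", {
  sizes <- c(chr1 = 2000L)
  v <- integer(2000); v[800:1200] <- 2L
  tr <- cut_track(sizes, plus = list(chr1 = v), minus = list(chr1 = v))
  sc <- footprint_score(tr, "chr1", 993, 1008, flank = 35)
  expect_gt(sc$p, 0.05)
  expect_lt(sc$score, 2)
})

test_that("cut profiles around motifs accumulate and flip strands correctly", {
  sizes <- c(chr1 = 1000L)
  v <- integer(1000); v[501] <- 4L  # plus cut at 0-based 500
  tr <- cut_track(sizes, plus = list(chr1 = v))
  hit <- data.frame(chrom = "chr1", start = 498L, end = 505L, strand = "+",
                    stringsAsFactors = FALSE)
  prof <- cut_profile_around_motifs(hit, tr, window = 20)
  mid <- (hit$start + hit$end) %/% 2  # 501
  relpos <- 500 - mid                 # -1
  expect_equal(prof$forward[prof$position == relpos], 4)
  expect_equal(sum(prof$forward), 4)
  expect_equal(sum(prof$reverse), 0)
  # minus-strand hit: same cut appears mirrored on the reverse profile
  hitm <- transform(hit, strand = "-")
  profm <- cut_profile_around_motifs(hitm, tr, window = 20)
  expect_equal(sum(profm$reverse), 4)
  expect_equal(profm$reverse[profm$position == -relpos - 1], 4)
  expect_error(cut_profile_around_motifs(hit[0, ], tr), "empty")
  # random case vs per-hit accumulation oracle
  withr::with_seed(71, {
    tr2 <- random_track(c(chr1 = 5000L), n_cuts = 2000)
    hits <- data.frame(chrom = "chr1",
                       start = sample(500:4400, 25),
                       strand = sample(c("+", "-"), 25, TRUE),
                       stringsAsFactors = FALSE)
    hits$end <- hits$start + 7L
  })
  got <- cut_profile_around_motifs(hits, tr2, window = 40)
  fwd <- numeric(40); rev_ <- numeric(40)
  for (i in seq_len(nrow(hits))) {
    mid <- (hits$start[i] + hits$end[i]) %/% 2
    pos <- (mid - 20):(mid + 19)
    p <- tr2$plus$chr1[pos + 1]; m <- tr2$minus$chr1[pos + 1]
    if (hits$strand[i] == "-") { tmp <- rev(m); m <- rev(p); p <- tmp }
    fwd <- fwd + p; rev_ <- rev_ + m
  }
  expect_equal(got$forward, fwd / nrow(hits))
  expect_equal(got$reverse, rev_ / nrow(hits))
})
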
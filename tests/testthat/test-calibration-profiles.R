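test_that("occupancy ratio follows (W_c * IP_x) / (W_x * IP_c)", {
  expect_equal(occupancy_ratio(calibration_counts(50, 50, 80, 80))$OR, 1)
  r <- occupancy_ratio(calibration_counts(W_x = 100, W_c = 100, IP_x = 200, IP_c = 50))
  expect_equal(r$OR, 4.0)
  expect_identical(r$total_ip_experimental_reads, 200)
  # scale invariance under multiplying all four counts
  r7 <- occupancy_ratio(calibration_counts(700, 700, 1400, 350))
  expect_equal(r7$OR, 4.0)
  expect_error(occupancy_ratio(calibration_counts(0, 10, 10, 10)), "W_x")
  expect_error(occupancy_ratio(calibration_counts(10, 10, 10, 0)), "IP_c")
  # per-million denominator config
  expect_identical(occupancy_ratio(calibration_counts(100, 100, 200, 50),
                                   denominator = "all")$total_ip_experimental_reads,
                   250)
})

test_that("zero-filled pileup covers every base and conserves depth", {
  none <- zero_filled_pileup(
    data.frame(read_id = character(), genome = character(), chrom = character(),
               start = integer(), strand = character(), aligned_length = integer()),
    "chrA", 300)
  expect_identical(none$depth, rep(0, 300))
  expect_identical(none$state, "raw")

  one <- data.frame(read_id = "r", genome = "experimental", chrom = "chrA",
                    start = 101L, strand = "+", aligned_length = 50L)
  tr <- zero_filled_pileup(one, "chrA", 1000)
  expect_identical(tr$depth[101:150], rep(1, 50))
  expect_identical(sum(tr$depth), 50)
  expect_true(all(tr$depth[-(101:150)] == 0))

  bad <- one; bad$start <- 990L
  expect_error(zero_filled_pileup(bad, "chrA", 1000), "bounds")
})

test_that("pileup equals the brute-force per-base interval count", {
  set.seed(101)
  for (case in 1:25) {
    L <- sample(500:2000, 1)
    n <- sample(1:30, 1)
    lens <- sample(10:60, n, replace = TRUE)
    starts <- vapply(lens, function(l) sample(L - l + 1L, 1L), 0L)
    a <- data.frame(read_id = seq_len(n), genome = "experimental", chrom = "c",
                    start = starts, strand = "+", aligned_length = lens)
    expect_identical(zero_filled_pileup(a, "c", L)$depth,
                     oracle_pileup(starts, lens, L))
  }
})

test_that("meta-profile averages per offset with end truncation", {
  mk_track <- function(chrom, depth) {
    structure(list(chrom = chrom, length = length(depth), depth = depth,
                   state = "raw"), class = "coverage_track")
  }
  uni <- list(mk_track("a", rep(3, 200)), mk_track("b", rep(3, 150)))
  mp <- anchor_meta_profile(uni, c(a = 100L, b = 75L), W = 50)
  expect_identical(nrow(mp), 101L)
  expect_true(all(mp$value == 3))
  expect_true(all(mp$n_contributing == 2L))

  # W = 60000 gives exactly 120001 offsets
  big <- anchor_meta_profile(list(mk_track("a", rep(1, 100))), c(a = 50L), W = 60000)
  expect_identical(nrow(big), 120001L)
  expect_identical(big$value[big$offset == 0], 1)
  expect_true(is.na(big$value[big$offset == 60000]))

  # hand-computed two-chromosome case with one truncated window
  t1 <- mk_track("a", c(1, 2, 3, 4, 5))          # anchor 2: offsets -1..3 in bounds
  t2 <- mk_track("b", c(10, 20, 30, 40, 50, 60)) # anchor 4: offsets -3..2
  # offset -3: only t2 (pos 1); offset -2: only t2 (t1 pos 0 out of bounds);
  # offsets -1..+2: both; offset +3: only t1 (t2 pos 7 out of bounds)
  mp2 <- anchor_meta_profile(list(t1, t2), c(a = 2L, b = 4L), W = 3)
  expect_identical(mp2$n_contributing, c(1L, 1L, 2L, 2L, 2L, 2L, 1L))
  expect_equal(mp2$value, c(10, 20, (1 + 30) / 2, (2 + 40) / 2,
                            (3 + 50) / 2, (4 + 60) / 2, 5))
  expect_equal(mp2$value, unname(oracle_meta_profile(list(t1, t2), c(a = 2L, b = 4L), 3)))

  expect_error(anchor_meta_profile(uni, c(a = 100L, b = 75L), W = -1), "W")
  expect_error(anchor_meta_profile(uni, c(a = 100L), W = 5), "anchor missing.*b")
})

test_that("meta-profile matches the brute-force oracle on random tracks", {
  set.seed(202)
  for (case in 1:25) {
    n_tr <- sample(1:4, 1)
    tracks <- lapply(seq_len(n_tr), function(i) {
      L <- sample(50:300, 1)
      structure(list(chrom = paste0("t", i), length = L,
                     depth = as.numeric(rpois(L, 3)), state = "raw"),
                class = "coverage_track")
    })
    anchors <- setNames(vapply(tracks, function(t) sample(t$length, 1L), 0L),
                        vapply(tracks, function(t) t$chrom, ""))
    W <- sample(10:120, 1)
    mp <- anchor_meta_profile(tracks, anchors, W)
    expect_equal(mp$value, unname(oracle_meta_profile(tracks, anchors, W)))
  }
})

test_that("calibration scaling is OR x per-million, applied exactly once", {
  tr <- structure(list(chrom = "a", length = 5, depth = c(0, 1, 2, 3, 0),
                       state = "raw"), class = "coverage_track")
  id_cal <- structure(list(OR = 1, total_ip_experimental_reads = 1e6),
                      class = "calibration_result")
  expect_identical(calibrate_profile(tr, id_cal)$depth, tr$depth)

  half_cal <- structure(list(OR = 2, total_ip_experimental_reads = 2e6),
                        class = "calibration_result")
  expect_identical(calibrate_profile(tr, half_cal)$depth, tr$depth)

  cal <- calibrate_profile(tr, structure(list(OR = 3, total_ip_experimental_reads = 1e5),
                                         class = "calibration_result"))
  expect_equal(cal$depth, tr$depth * 30)
  expect_identical(cal$state, "calibrated")
  expect_error(calibrate_profile(cal, id_cal), "already calibrated")
})

test_that("track export round-trips and converts coordinates correctly", {
  zero <- structure(list(chrom = "z", length = 400, depth = rep(0, 400),
                         state = "raw"), class = "coverage_track")
  expect_identical(export_track(zero, "bedGraph"), "z\t0\t400\t0")

  tr <- structure(list(chrom = "c", length = 1000,
                       depth = c(rep(0, 100), rep(1, 50), rep(0, 850)),
                       state = "raw"), class = "coverage_track")
  expect_identical(export_track(tr, "bedGraph"),
                   c("c\t0\t100\t0", "c\t100\t150\t1", "c\t150\t1000\t0"))

  set.seed(7)
  for (case in 1:10) {
    depth <- as.numeric(rpois(sample(50:400, 1), 2))
    if (case > 5) depth <- depth * pi / 3  # non-integer calibrated values
    rt <- structure(list(chrom = "r", length = length(depth), depth = depth,
                         state = "raw"), class = "coverage_track")
    for (dialect in c("bedGraph", "wiggle")) {
      back <- parse_track(export_track(rt, dialect))
      expect_identical(back$depth, rt$depth)
      expect_identical(back$chrom, "r")
      expect_identical(back$length, rt$length)
    }
  }
  expect_error(export_track(zero, "bigwig"))
})
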
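test_that("toy genome pairs satisfy their invariants, with midpoint anchors", {
  pair <- make_toy_genome_pair(1, 1000, 1, 1000, read_length = 50, seed = 7)
  expect_s3_class(pair, "toy_genome_pair")
  expect_identical(unname(pair$anchors), 500L)
  expect_silent(validate_toy_genome_pair(pair))
  # uniqueness across both strands of both genomes combined
  seqs <- c(as.character(pair$experimental), as.character(pair$calibration))
  kmers <- unlist(lapply(seqs, function(s) substring(s, 1:(nchar(s) - 49), 50:nchar(s))))
  expect_identical(anyDuplicated(c(kmers, revcomp(kmers))), 0L)
})

test_that("genome generation is deterministic and byte-identical on disk", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_genome_pair(make_toy_genome_pair(2, 800, 1, 600, 30, seed = 11), d1)
  write_genome_pair(make_toy_genome_pair(2, 800, 1, 600, 30, seed = 11), d2)
  for (f in c("experimental.fasta", "calibration.fasta", "anchors.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("unsatisfiable k-mer uniqueness raises 'genome too repetitive'", {
  expect_error(
    make_toy_genome_pair(1, 100, 1, 100, read_length = 1, seed = 1, max_tries = 3),
    "genome too repetitive"
  )
  expect_error(make_toy_genome_pair(0, 100, 1, 100, 10, seed = 1), "positive")
  expect_error(make_toy_genome_pair(1, 20, 1, 100, 10, seed = 1), "exceed")
})

test_that("read simulation conserves requested counts and is seed-deterministic", {
  pair <- tiny_pair()
  prof <- occupancy_profile_spec(peak_enrichment = 5, decay_span = 500)
  r1 <- simulate_chip_experiment(pair, prof, 3, n_reads_ip = 500, n_reads_wce = 700, seed = 5)
  r2 <- simulate_chip_experiment(pair, prof, 3, n_reads_ip = 500, n_reads_wce = 700, seed = 5)
  expect_identical(r1, r2)
  expect_identical(sum(r1$sample == "IP"), 500L)
  expect_identical(sum(r1$sample == "WCE"), 700L)
  wce <- r1[r1$sample == "WCE", ]
  expect_identical(sum(wce$truth_genome == "experimental") +
                     sum(wce$truth_genome == "calibration"), 700L)
  # truth fields consistent with the genome sequence
  i <- which(r1$truth_strand == "+")[1:20]
  for (j in i) {
    s <- as.character(pair[[r1$truth_genome[j]]][[r1$truth_chrom[j]]])
    expect_identical(substr(s, r1$truth_pos[j], r1$truth_pos[j] + 39L), r1$sequence[j])
  }
  j <- which(r1$truth_strand == "-")[1]
  s <- as.character(pair[[r1$truth_genome[j]]][[r1$truth_chrom[j]]])
  expect_identical(revcomp(substr(s, r1$truth_pos[j], r1$truth_pos[j] + 39L)),
                   r1$sequence[j])
})

test_that("flat enrichment profile gives uniform IP start positions", {
  pair <- tiny_pair()
  prof <- occupancy_profile_spec(peak_enrichment = 1)
  pvals <- vapply(1:10, function(seed) {
    reads <- simulate_chip_experiment(pair, prof, 3, 2000, 100, seed = seed)
    ip <- reads[reads$sample == "IP" & reads$truth_genome == "experimental" &
                  reads$truth_chrom == "chr01", ]
    n_starts <- 3000 - pair$read_length + 1  # uniform support is 1..L-k+1
    bins <- cut(ip$truth_pos, breaks = seq(0, n_starts, length.out = 11))
    suppressWarnings(chisq.test(table(bins))$p.value)
  }, 0)
  # under uniformity ~10% of 10-seed families show one rejection at alpha=0.01
  # by chance; two or more would indicate real non-uniformity (P ~ 0.4%)
  expect_lte(sum(pvals <= 0.01), 1L)
  expect_gt(median(pvals), 0.05)
})

test_that("WCE calibration fraction follows the cell-ratio binomial", {
  # equal genome lengths, 3:1 cells -> calibration fraction 1/4
  pair <- make_toy_genome_pair(1, 2000, 1, 2000, read_length = 40, seed = 9)
  n <- 40000
  reads <- simulate_chip_experiment(pair, occupancy_profile_spec(), 3,
                                    n_reads_ip = 10, n_reads_wce = n, seed = 21)
  n_cal <- sum(reads$sample == "WCE" & reads$truth_genome == "calibration")
  expect_gte(n_cal, qbinom(0.005, n, 0.25))
  expect_lte(n_cal, qbinom(0.995, n, 0.25))
})

test_that("IP enrichment at the anchor reflects the sampling weights", {
  pair <- make_toy_genome_pair(1, 20000, 1, 2000, read_length = 40, seed = 13)
  prof <- occupancy_profile_spec(peak_enrichment = 10, decay_span = 3000)
  reads <- simulate_chip_experiment(pair, prof, 3, n_reads_ip = 40000,
                                    n_reads_wce = 10, seed = 17)
  ip <- assign_reads_sequential(reads[reads$sample == "IP", ], pair)
  tr <- zero_filled_pileup(ip, "chr01", 20000)
  anchor <- pair$anchors[["chr01"]]
  peak <- mean(tr$depth[(anchor - 100):(anchor + 100)])
  flank <- mean(tr$depth[c(1000:5000, 15000:19000)])
  expect_lt(abs(peak / flank - 10) / 10, 0.2)
})

test_that("simulated lanes hit the model expectation in the noiseless limit", {
  m <- tetraploid_design("4x6C", k = 1)
  lanes <- simulate_entrapment_assay(m, n_replicates = 3, noise_sd = 0, seed = 2)
  fr <- expected_species_fractions(m)
  for (ln in lanes) {
    expect_equal(unname(ln$bands[["CM"]]), 100 * fr$CM_detectable)
    expect_equal(unname(ln$bands[["CD"]]), 100 * fr$CD_detectable)
  }
  l2 <- simulate_entrapment_assay(m, 3, 0.1, seed = 8)
  expect_identical(l2, simulate_entrapment_assay(m, 3, 0.1, seed = 8))
})

test_that("noiseless lanes reproduce the ring-model and handcuff predictions", {
  for (k in 1:2) {
    ctrl <- simulate_entrapment_assay(tetraploid_design("4x6C", k = k), 1, 0, seed = 1)
    test <- simulate_entrapment_assay(tetraploid_design("1x6C+3x5C", k = k), 1, 0, seed = 1)
    rr <- cd_cm_ratio(test[[1]]) / cd_cm_ratio(ctrl[[1]])
    expect_equal(rr, if (k == 1) 1 else 0.25)
  }
})

test_that("absorbance series follow the constructed kinetics", {
  cv <- standard_curve(slope = 0.01, intercept = 0.1)
  flat <- simulate_atpase_series(0, curve = cv, noise_sd = 0, seed = 1)
  expect_true(all(flat$au == 0.1))
  s <- simulate_atpase_series(2, curve = cv, noise_sd = 0, seed = 1)
  expect_equal(s$au[s$time == 10] - s$au[s$time == 0], 0.2)
  sat <- simulate_atpase_series(2, curve = cv, saturation_time = 10,
                                noise_sd = 0, seed = 1)
  post <- sat$au[sat$time >= 10]
  expect_true(all(post == post[1]))
  expect_identical(simulate_atpase_series(1, curve = cv, noise_sd = 0.05, seed = 3),
                   simulate_atpase_series(1, curve = cv, noise_sd = 0.05, seed = 3))
})
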
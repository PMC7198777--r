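# Marker frequency analysis: read trimming, depth import, ratio profiles,
# origin detection and the ori/ter ratio.

test_that("read trimming clips ends and enforces the minimum length", {
  # 116 nt, all high quality: 116 - 15 - 2 = 99 < 100 -> discarded
  r1 <- read_records(strrep("A", 116), list(rep(40L, 116)))
  out1 <- trim_reads(r1)
  expect_equal(out1$qc$n_retained, 0L)
  expect_equal(out1$qc$retained_fraction, 0)
  # 200 nt, all high quality: retained at 183
  r2 <- read_records(strrep("A", 200), list(rep(40L, 200)))
  out2 <- trim_reads(r2)
  expect_equal(nchar(out2$reads$bases), 183L)
  expect_equal(out2$reads$qualities[[1]], rep(40L, 183))
  # empty input warns
  expect_warning(trim_reads(read_records(character(0), list())), "no reads")
})

test_that("quality trimming matches a brute-force per-read oracle", {
  set.seed(31)
  params <- trim_params()
  n <- 60
  lens <- sample(110:250, n, replace = TRUE)
  reads <- read_records(
    vapply(lens, function(l)
      paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""),
      character(1)),
    lapply(lens, function(l) {
      q <- rep(38L, l)
      # low-quality 3' tail of random length, sometimes an internal dip
      tail_len <- sample(0:60, 1)
      if (tail_len > 0) q[(l - tail_len + 1):l] <- sample(2:20, tail_len, TRUE)
      if (runif(1) < 0.3) q[sample(l, 1)] <- 10L
      q
    })
  )
  got <- trim_reads(reads, params)
  # oracle: independent O(n^2) scan for the longest all-passing subsegment
  # of the end-clipped read
  oracle_bases <- character(0)
  for (i in seq_len(n)) {
    q <- reads$qualities[[i]]
    l <- length(q)
    from <- params$trim_5prime + 1L
    to <- l - params$trim_3prime
    if (to < from) next
    best <- c(0L, 0L)
    for (a in from:to) for (b in a:to) {
      if (all(q[a:b] > params$min_phred) && b - a + 1L > best[2])
        best <- c(a, b - a + 1L)
    }
    if (best[2] >= params$min_length)
      oracle_bases <- c(oracle_bases,
                        substring(reads$bases[i], best[1],
                                  best[1] + best[2] - 1L))
  }
  expect_identical(got$reads$bases, oracle_bases)
})

test_that("bedGraph depth import aggregates counts pro-rata over windows", {
  tmp <- withr::local_tempfile(fileext = ".bedgraph")
  # one interval exactly covering window 2 of a 10 x 100 bp grid
  writeLines("chr\t100\t200\t500", tmp)
  prof <- depth_from_bedgraph(tmp, window = 100L, genome_length = 1000L)
  expect_equal(prof$counts, c(0, 500, rep(0, 8)))
  expect_equal(prof$total_reads, 500)

  # boundary-split intervals: pro-rata matches a per-base expansion oracle
  writeLines(c("chr\t50\t150\t300", "chr\t150\t330\t90"), tmp)
  prof2 <- depth_from_bedgraph(tmp, window = 100L, genome_length = 1000L)
  per_base <- numeric(1000)
  per_base[51:150] <- per_base[51:150] + 300 / 100
  per_base[151:330] <- per_base[151:330] + 90 / 180
  oracle <- as.numeric(tapply(per_base, (0:999) %/% 100, sum))
  expect_equal(prof2$counts, oracle)

  # empty file: all-zero profile plus QC flag
  writeLines(character(0), tmp)
  expect_warning(
    prof3 <- depth_from_bedgraph(tmp, window = 100L, genome_length = 1000L),
    "empty")
  expect_true(all(prof3$counts == 0))
  expect_true(prof3$qc$empty_input)

  # out-of-range interval is a hard error naming the record
  writeLines("chr\t900\t1100\t50", tmp)
  expect_error(depth_from_bedgraph(tmp, window = 100L, genome_length = 1000L),
               "record 1")
})

test_that("depth profiles round-trip through bedGraph", {
  m <- replication_model("single_origin", 50000, 0,
                         replicating_fraction = 0.5, seed = 41)
  dp <- simulate_depth_profiles(m, 1000L, 200)
  tmp <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(dp$exponential, tmp)
  back <- depth_from_bedgraph(tmp, window = 1000L, genome_length = 50000)
  expect_equal(back$counts, dp$exponential$counts)
})

test_that("MFA ratio is exactly 1 for identical samples and is normalization-invariant", {
  m <- replication_model("multifork", 2e6, 0, fork_intensity = 1, seed = 51)
  dp <- simulate_depth_profiles(m, 1000L, 300)
  same <- mfa_ratio(dp$stationary, dp$stationary)
  expect_true(all(same$fine_ratio[!is.na(same$fine_ratio)] == 1))
  # scaling one sample's counts and total by the same constant changes nothing
  base <- mfa_ratio(dp$exponential, dp$stationary)
  scaled <- dp$exponential
  scaled$counts <- scaled$counts * 7
  scaled$total_reads <- scaled$total_reads * 7
  rescaled <- mfa_ratio(scaled, dp$stationary)
  expect_equal(rescaled$fine_ratio, base$fine_ratio)
  expect_equal(rescaled$coarse_ratio, base$coarse_ratio)
})

test_that("zero stationary windows are masked and counted in QC", {
  e <- depth_profile(c(10, 10, 10, 10), 250L, 1000L, "exponential")
  s <- depth_profile(c(10, 0, 10, 10), 250L, 1000L, "stationary")
  expect_warning(mfa <- mfa_ratio(e, s, coarse_window = 250L), "masked")
  expect_true(is.na(mfa$fine_ratio[2]))
  expect_equal(mfa$qc$masked_fine_fraction, 0.25)
})

test_that("origin detection on a noiseless V profile is exact", {
  m <- replication_model("single_origin", 3e6, ori_position = 1.2e6,
                         replicating_fraction = 0.4)
  mfa <- noiseless_mfa(m, fine = 1000L, coarse = 100000L)
  oc <- detect_origin(mfa, seed = 1)
  expect_equal(oc$mode, "single_origin_V")
  # peak window midpoint within half a coarse window of the true origin
  expect_lte(circular_distance(oc$origin_position, 1.2e6, 3e6), 50000)
  # the apex falls inside a coarse window, so the tent fit is near- but not
  # exactly perfect
  expect_gte(oc$v_r2, 0.95)
  expect_gte(oc$peak_trough_ratio, 1)
})

test_that("origin detection is rotation-equivariant", {
  # ori off any window boundary so the smoothed argmax is unique (at an
  # exact boundary the two flanking windows tie and the tie-break is
  # positional, not rotational)
  r <- 0.4
  mfa0 <- noiseless_mfa(
    replication_model("single_origin", 3e6, 30000, replicating_fraction = r),
    fine = 1000L, coarse = 100000L)
  mfa_shift <- noiseless_mfa(
    replication_model("single_origin", 3e6, 1530000,
                      replicating_fraction = r),
    fine = 1000L, coarse = 100000L)
  oc0 <- detect_origin(mfa0, seed = 2)
  oc1 <- detect_origin(mfa_shift, seed = 2)
  expect_equal(circular_distance(oc1$origin_position,
                                 (oc0$origin_position + 1.5e6) %% 3e6, 3e6), 0)
  expect_equal(oc1$peak_trough_ratio, oc0$peak_trough_ratio, tolerance = 1e-9)
})

test_that("ori/ter ratio equals the closed-form model ratio on noiseless input", {
  # single-origin: window-averaged closed form, exact to machine precision
  r <- 0.4
  L <- 1e6
  w <- 50000
  mfa <- noiseless_mfa(
    replication_model("single_origin", L, 0, replicating_fraction = r),
    fine = 10000L, coarse = w)
  oracle <- (1 + r * (1 - w / L)) / (1 + r * w / L)  # analytic window means
  expect_equal(as.numeric(ori_ter_ratio(mfa, 0)), oracle, tolerance = 1e-12)
  # flat model: ratio identically 1
  mfa_flat <- noiseless_mfa(replication_model("multi_origin_async", L),
                            fine = 10000L, coarse = w)
  expect_equal(as.numeric(ori_ter_ratio(mfa_flat, 0)), 1, tolerance = 1e-12)
})

test_that("multifork simulation reproduces the 2^k ori/ter ratio", {
  k <- 1.5
  L <- 3e6
  m <- replication_model("multifork", L, 0, fork_intensity = k, seed = 61)
  dp <- simulate_depth_profiles(m, 1000L, 500)
  mfa <- mfa_ratio(dp$exponential, dp$stationary)
  got <- ori_ter_ratio(mfa, 0)
  # expected: coarse-window averages of 2^(k(1-delta)) at ori vs ter
  grid_mids <- seq(500, L - 500, by = 1000)
  mvals <- 2^(k * (1 - origin_delta(grid_mids, 0, L)))
  expected <- mean(mvals[1:100]) / mean(mvals[1501:1600])
  se <- expected * sqrt(2 / (500 * 100) * 2)
  expect_lt(abs(got - expected), 4 * se)
})

test_that("small replicating fractions give ratios near 1 at high depth", {
  m <- replication_model("single_origin", 3e6, 0,
                         replicating_fraction = 0.03, seed = 71)
  dp <- simulate_depth_profiles(m, 1000L, 2000)
  mfa <- mfa_ratio(dp$exponential, dp$stationary)
  got <- ori_ter_ratio(mfa, 0)
  expect_lt(abs(got - 1.03), 0.02)
})

test_that("heavily masked profiles are declared indeterminate", {
  m <- replication_model("single_origin", 3e6, 0,
                         replicating_fraction = 0.3, seed = 81)
  dp <- simulate_depth_profiles(m, 1000L, 100)
  suppressWarnings({
    dp$stationary$counts[1:900] <- 0  # 30% of fine windows -> masked coarse
    mfa <- mfa_ratio(dp$exponential, dp$stationary)
  })
  oc <- detect_origin(mfa, seed = 1)
  expect_equal(oc$mode, "indeterminate")
  expect_match(oc$diagnostic, "masked")
})

test_that("masked antipodal windows fall back to the nearest unmasked neighbour", {
  e <- depth_profile(rep(10, 40), 250L, 10000L, "exponential")
  s_counts <- rep(10, 40)
  s_counts[21:22] <- 0  # mask the antipodal coarse windows
  s <- depth_profile(s_counts, 250L, 10000L, "stationary")
  suppressWarnings(mfa <- mfa_ratio(e, s, coarse_window = 250L))
  got <- ori_ter_ratio(mfa, 0)
  expect_true(attr(got, "fallback"))
  expect_equal(as.numeric(got), 1)
})

test_that("FASTQ reads round-trip into read records", {
  tmp <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII",
               "@r2", "GGGCCCAA", "+", "!!IIII!!"), tmp)
  reads <- read_fastq_reads(tmp)
  expect_equal(length(reads), 2L)
  expect_equal(reads$bases[1], "ACGTACGT")
  expect_equal(reads$qualities[[1]], rep(40L, 8))
  expect_equal(reads$qualities[[2]], c(0L, 0L, 40L, 40L, 40L, 40L, 0L, 0L))
})
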
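test_that("window inconsistency counts only SNPs with two or more resolved aHaps", {
  A <- matrix(1L, nrow = 3, ncol = 100)
  expect_equal(window_inconsistency(A), 0)           # fully identical
  A2 <- A; A2[1, 1:5] <- 2L
  expect_equal(window_inconsistency(A2), 0.05)       # 5 of 100 disagree
  A3 <- A; A3[1, 1:4] <- 2L
  expect_equal(window_inconsistency(A3), 0.04)
  # a disagreeing SNP with <2 resolved alleles is excluded from both sides
  A4 <- A; A4[1, 1:10] <- 2L; A4[2:3, 1:10] <- NA_integer_
  expect_equal(window_inconsistency(A4), 0)
  expect_true(is.na(window_inconsistency(matrix(NA_integer_, 2, 50))))
})

test_that("the 5% tolerance bound is strict: exactly 5% inconsistent is not homozygous", {
  # regular 10-kb grid; every 20th SNP inconsistent -> every 400-kb window
  # holds exactly 40 SNPs of which exactly 2 (5%) disagree
  n <- 2000L
  pos <- seq(10e3, by = 10e3, length.out = n)
  A <- matrix(1L, nrow = 2, ncol = n)
  bad <- seq(20L, n, by = 20L)
  A_5 <- A; A_5[1, bad] <- 2L
  map <- marker_map("1", sprintf("s%d", 1:n), pos)
  params <- scan_params(window_kb = 400, step_kb = 400, tolerance = 0.05,
                        min_snps = 20)
  segs <- scan_chromosome(ahapset_from_matrix(A_5), map, params, "1")
  expect_equal(nrow(segs), 0L)
  # every 25th SNP with a 500-kb (50-SNP) window: exactly 2/50 = 4% per
  # window, under the bound
  A_4 <- A; A_4[1, seq(25L, n, by = 25L)] <- 2L
  params4 <- scan_params(window_kb = 500, step_kb = 500, tolerance = 0.05,
                         min_snps = 20)
  segs <- scan_chromosome(ahapset_from_matrix(A_4), map, params4, "1")
  expect_equal(nrow(segs), 1L)
})

test_that("scan at tolerance 0 agrees with the exhaustive maximal-consistent-run oracle", {
  params <- scan_params(window_kb = 500, step_kb = 50, tolerance = 0,
                        min_snps = 20)
  window_bp <- params$window_kb * 1000
  set.seed(314)
  for (rep in 1:12) {
    n <- sample(1000:2000, 1)
    with_block <- rep %% 3 != 0
    block <- if (with_block) {
      b1 <- sample(seq_len(n - 300), 1); c(b1, b1 + sample(200:299, 1))
    } else NULL
    rc <- random_ahap_chromosome(sample(3:6, 1), n, block)
    segs <- scan_chromosome(ahapset_from_matrix(rc$A), rc$map, params, "1")
    oracle <- oracle_consistent_runs(rc$A, rc$pos)
    # every reported bound is within one window of an oracle run bound
    for (i in seq_len(nrow(segs))) {
      d <- abs(oracle$start_bp - segs$start_bp[i]) +
        abs(oracle$end_bp - segs$end_bp[i])
      j <- which.min(d)
      expect_lte(abs(segs$start_bp[i] - oracle$start_bp[j]), window_bp)
      expect_lte(abs(segs$end_bp[i] - oracle$end_bp[j]), window_bp)
    }
    # every long oracle run is found
    long <- oracle[oracle$end_bp - oracle$start_bp >= 2 * window_bp &
                     oracle$n_snps >= params$min_snps, , drop = FALSE]
    for (j in seq_len(nrow(long))) {
      hit <- any(segs$start_bp <= long$start_bp[j] + window_bp &
                   segs$end_bp >= long$end_bp[j] - window_bp)
      expect_true(hit, label = sprintf("rep %d: oracle run %d recovered", rep, j))
    }
    # independent random aHaps share nothing detectable
    if (!with_block) expect_equal(nrow(segs), 0L)
  }
})

test_that("lowering the tolerance never enlarges a segment", {
  set.seed(99)
  rc <- random_ahap_chromosome(4, 1500, block = c(400, 900), na_rate = 0.02)
  # sprinkle 2% discordant calls inside the block
  inside <- 400:900
  noisy <- sample(inside, length(inside) * 0.02)
  flip <- cbind(sample(1:4, length(noisy), TRUE), noisy)
  rc$A[flip] <- ifelse(is.na(rc$A[flip]), NA_integer_, 3L - rc$A[flip])
  loose <- scan_chromosome(ahapset_from_matrix(rc$A), rc$map,
                           scan_params(tolerance = 0.05), "1")
  tight <- scan_chromosome(ahapset_from_matrix(rc$A), rc$map,
                           scan_params(tolerance = 0.01), "1")
  for (i in seq_len(nrow(tight))) {
    covered <- any(loose$start_bp <= tight$start_bp[i] &
                     loose$end_bp >= tight$end_bp[i])
    expect_true(covered)
  }
})

test_that("single assured aHap warns and reports nothing unless overridden", {
  rc <- random_ahap_chromosome(1, 600)
  expect_warning(
    segs <- scan_chromosome(ahapset_from_matrix(rc$A), rc$map,
                            scan_params(), "1"),
    "W_UNPOWERED")
  expect_equal(nrow(segs), 0L)
  segs <- scan_chromosome(ahapset_from_matrix(rc$A), rc$map, scan_params(),
                          "1", allow_single_ahap = TRUE)
  expect_gt(nrow(segs), 0L)
})

test_that("paired aHaps trim segments where neither member carries the consensus", {
  set.seed(7)
  n <- 1200L
  pos <- seq(5e3, by = 5e3, length.out = n)
  map <- marker_map("1", sprintf("s%d", 1:n), pos)
  consensus <- sample(1:2, n, replace = TRUE)
  A <- rbind(consensus, consensus, consensus)
  ahs <- ahapset_from_matrix(A)
  seg <- scan_chromosome(ahs, map, scan_params(), "1")
  expect_equal(nrow(seg), 1L)

  make_pair <- function(trans, untrans, child = "kid") {
    pid <- paste0("pair_p_", child)
    list(transmitted = structure(list(alleles = trans, child = child,
                                      parent = "p", which = "transmitted",
                                      status = "paired", pair_id = pid,
                                      child_affection = "unknown"), class = "AHap"),
         untransmitted = structure(list(alleles = untrans, child = child,
                                        parent = "p", which = "untransmitted",
                                        status = "paired", pair_id = pid,
                                        child_affection = "unknown"), class = "AHap"),
         pair_id = pid, child = child, child_affection = "unknown")
  }
  # transmitted member equals consensus everywhere: segment unchanged,
  # child called a carrier
  ahs$paired <- list(make_pair(consensus, 3L - consensus))
  out <- refine_with_paired(seg[1, ], ahs, map, scan_params())
  expect_equal(out$segments$start_bp, seg$start_bp[1])
  expect_equal(out$segments$end_bp, seg$end_bp[1])
  expect_equal(out$pair_calls$carrier, "transmitted")

  # both members diverge beyond the midpoint: segment trimmed to the left
  breakpoint <- 600L
  trans <- consensus; untrans <- 3L - consensus
  trans[breakpoint:n] <- 3L - consensus[breakpoint:n]
  ahs$paired <- list(make_pair(trans, untrans))
  out <- refine_with_paired(seg[1, ], ahs, map, scan_params())
  expect_equal(nrow(out$segments), 1L)
  expect_lt(out$segments$end_bp, pos[breakpoint] + 500e3)
  expect_gt(out$segments$end_bp, pos[breakpoint] - 500e3)
  expect_equal(out$segments$start_bp, seg$start_bp[1])

  # no pairs: identity
  ahs$paired <- list()
  out <- refine_with_paired(seg[1, ], ahs, map, scan_params())
  expect_equal(out$segments$end_bp, seg$end_bp[1])
})
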
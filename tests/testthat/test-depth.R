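test_that("window layout follows floor((G - window) / step) + 1", {
  track <- data.frame(chrom = "chr1", start = 0, end = 1e6, depth = 10)
  prof <- compute_window_ratios(track, genome = c(chr1 = 1e6))
  expect_equal(nrow(prof$windows), 91)
  expect_equal(prof$windows$start[1], 0)
  expect_equal(prof$windows$end[91], 1e6)
  expect_equal(prof$genome_avg, 10)
  expect_true(all(prof$windows$ratio == 1))
})

test_that("uncovered gaps count as zero depth in window means", {
  track <- data.frame(chrom = "chr1",
                      start = c(0, 6e5), end = c(5e5, 1e6),
                      depth = 10)
  prof <- compute_window_ratios(track, genome = c(chr1 = 1e6))
  w <- prof$windows
  expect_equal(w$depth[w$start == 4.5e5], 5)   # half covered, half gap
  expect_equal(w$depth[w$start == 5e5], 0)
  expect_error(compute_window_ratios(track[0, ]), "empty")
  zero <- data.frame(chrom = "chr1", start = 0, end = 1e6, depth = 0)
  expect_error(compute_window_ratios(zero, genome = c(chr1 = 1e6)), "zero")
})

test_that("deletion calls use a strict below-half-average rule", {
  win <- data.frame(chrom = "chr1", start = seq(0, 40) * 1e4,
                    end = seq(0, 40) * 1e4 + 1e5, depth = 10,
                    stringsAsFactors = FALSE)
  win$ratio <- 1
  win$ratio[10:15] <- 0.5          # exactly the cutoff: not a deletion
  prof <- structure(list(sample = "s", windows = win, genome_avg = 10),
                    class = "depth_profile")
  expect_equal(nrow(call_depth_deletions(prof)), 0)
  win$ratio[10:15] <- 0.499
  prof$windows <- win
  calls <- call_depth_deletions(prof)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$n_windows, 6)
  expect_equal(calls$start, win$start[10])
  expect_equal(calls$end, win$end[15])
})

test_that("refined boundaries invert the edge-window response exactly", {
  # noise-free homozygous deletion not aligned to the window grid
  a <- 501234; b <- 801234
  track <- data.frame(chrom = "chr1",
                      start = c(0, a, b), end = c(a, b, 2e6),
                      depth = c(20, 0, 20))
  prof <- compute_window_ratios(track, genome = c(chr1 = 2e6))
  calls <- call_depth_deletions(prof)
  expect_equal(nrow(calls), 1)
  step <- sv_config()$depth_step
  # union span overshoots by design; refined edges land within step/2
  expect_true(calls$start < a && calls$end > b)
  expect_lt(abs(calls$refined_start - a), step / 2 + 1e-6)
  expect_lt(abs(calls$refined_end - b), step / 2 + 1e-6)
})

test_that("carrier tables apply the 50% reciprocal-overlap rule", {
  calls <- data.frame(sample = c("s1", "s2", "s3"),
                      chrom = "chr1",
                      start = c(1500, 1501, 1000),
                      end = c(2500, 2501, 2000),
                      stringsAsFactors = FALSE)
  region <- list(chrom = "chr1", start = 1000, end = 2000)
  classes <- setNames(c("high", "low", "high", "low"),
                      c("s1", "s2", "s3", "s4"))
  tab <- deletion_carrier_table(calls, region, classes,
                                profiled = names(classes))
  # s1 overlap 500/1000 = exactly 0.5 both ways: carrier
  # s2 overlap 499: not a carrier; s3 identical: carrier; s4 no call
  expect_equal(tab["high", "carrier"], 2L)
  expect_equal(tab["high", "non_carrier"], 0L)
  expect_equal(tab["low", "carrier"], 0L)
  expect_equal(tab["low", "non_carrier"], 2L)
  expect_warning(
    deletion_carrier_table(calls, region, classes, profiled = c("s1", "s2")),
    "without depth profile")
  expect_error(
    deletion_carrier_table(calls, region, setNames("high", "s1"),
                           profiled = "s1"),
    "two phenotype classes")
})
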
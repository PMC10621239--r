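test_that("the cohort generator is deterministic given its seed", {
  t1 <- simulate_cohort(seed = 9, n_per_group = c(5, 5), n_svs = 50)
  t2 <- simulate_cohort(seed = 9, n_per_group = c(5, 5), n_svs = 50)
  expect_identical(t1$svs, t2$svs)
  expect_identical(t1$geno, t2$geno)
  c1 <- simulate_caller_outputs(t1, seed = 9)
  c2 <- simulate_caller_outputs(t2, seed = 9)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("zero divergence means identical group frequency targets", {
  t0 <- simulate_cohort(seed = 10, n_per_group = c(5, 5), n_svs = 50,
                        divergence = 0)
  expect_equal(t0$svs$freq_a, t0$svs$freq_b)
  expect_true(all(diff(t0$svs$start[t0$svs$chrom == "chr1"]) >= 2000))
})

test_that("noise-free caller outputs reproduce carried SVs per caller", {
  truth <- simulate_cohort(seed = 12, n_per_group = c(4, 4), n_svs = 60)
  cp <- default_caller_params()
  cp$sensitivity <- 1; cp$jitter <- 0; cp$fcr <- 0
  calls <- simulate_caller_outputs(truth, seed = 12, caller_params = cp)
  n_carried <- sum(truth$geno > 0)
  expect_equal(nrow(calls), n_carried * nrow(cp))
  one <- calls[calls$caller == "manta", ]
  key_truth <- paste(truth$svs$chrom, truth$svs$start, truth$svs$svtype)
  expect_true(all(paste(one$chrom, one$start, one$svtype) %in% key_truth))
})

test_that("correlated false calls are duplicated across all callers", {
  truth <- simulate_cohort(seed = 13, n_per_group = c(2, 2), n_svs = 40)
  calls <- simulate_caller_outputs(truth, seed = 13, correlated_false = TRUE)
  key_truth <- paste(truth$svs$chrom, truth$svs$start, truth$svs$svtype)
  is_false <- !paste(calls$chrom, calls$start, calls$svtype) %in% key_truth
  fc <- calls[is_false, ]
  # jitter-displaced true calls also fail the exact-key match; false calls
  # are identified as those with an identical copy from every caller
  if (nrow(fc)) {
    key <- paste(fc$sample, fc$chrom, fc$start, fc$end, fc$svtype)
    n_callers <- table(key)
    expect_true(any(n_callers == 3))
  }
  expect_gt(nrow(fc), 0)
})

test_that("written per-sample VCFs read back to the same calls", {
  truth <- simulate_cohort(seed = 14, n_per_group = c(2, 2), n_svs = 30)
  dir <- tempfile()
  calls <- simulate_caller_outputs(truth, seed = 14, write_dir = dir)
  files <- attr(calls, "files")
  expect_true(length(files) > 0)
  f <- files[1]
  parts <- strsplit(basename(f), ".", fixed = TRUE)[[1]]
  back <- read_caller_vcf(f, caller = parts[2], sample = parts[1])
  orig <- calls[calls$sample == parts[1] & calls$caller == parts[2], ]
  orig <- orig[order(orig$chrom, orig$start, orig$svtype), ]
  back <- back[order(back$chrom, back$start, back$svtype), ]
  expect_equal(back$start, orig$start)
  expect_equal(back$end, orig$end)
  expect_equal(back$svtype, orig$svtype)
  expect_equal(back$genotype, orig$genotype)
})

test_that("depth tracks carry the embedded deletion for carriers", {
  truth <- simulate_cohort(seed = 15, n_per_group = c(10, 10), n_svs = 30)
  copies <- truth$deletion$copies
  hom <- names(copies)[copies == 2][1]
  non <- names(copies)[copies == 0][1]
  skip_if(is.na(hom) || is.na(non))
  tracks <- simulate_depth_tracks(truth, seed = 15, samples = c(hom, non))
  reg <- truth$deletion$region
  inside <- function(tr) tr$chrom == reg$chrom & tr$start >= reg$start &
    tr$end <= reg$end
  expect_equal(mean(tracks[[hom]]$depth[inside(tracks[[hom]])]), 0)
  expect_gt(mean(tracks[[non]]$depth[inside(tracks[[non]])]), 15)
})

test_that("phenotypes reflect the causal dosage and validate h2", {
  truth <- simulate_cohort(seed = 16, n_per_group = c(40, 40), n_svs = 100)
  y <- simulate_phenotypes(truth, h2 = 0.3, seed = 16)
  g <- truth$geno[truth$causal$id, ]
  expect_gt(cor(y, g), 0.3)
  expect_error(simulate_phenotypes(truth, h2 = 1.2), "h2")
})

test_that("penetrance classes put class1 members among carriers only", {
  carrier <- setNames(rep(c(TRUE, FALSE), each = 50), paste0("s", 1:100))
  cl <- simulate_penetrance_classes(carrier, p1_carrier = 0.4,
                                    p1_noncarrier = 0, seed = 2)
  expect_true(all(carrier[names(cl)[cl == "high"]]))
  expect_true(any(cl == "high"))
})
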
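chain_calls <- function() {
  # starts 8 bp apart: adjacent pairs link, ends chain transitively
  normalize_calls(sv_calls(
    chrom = "chr1", start = c(100, 108, 116), end = c(300, 308, 316),
    svtype = "DEL", caller = c("m", "d", "b"), sample = "s1",
    genotype = "0/1"))
}

test_that("clustering is transitive single linkage", {
  cl <- cluster_calls(chain_calls())
  expect_equal(length(unique(cl$cluster)), 1)  # 100 vs 116 linked via 108
  far <- chain_calls()
  far$start[3] <- 200; far$end[3] <- 400
  cl2 <- cluster_calls(far)
  expect_equal(length(unique(cl2$cluster)), 2)
})

test_that("clustering never links across chromosome or SV type", {
  calls <- chain_calls()
  calls$chrom[2] <- "chr2"
  calls$svtype[3] <- "DUP"
  cl <- cluster_calls(calls)
  expect_equal(length(unique(cl$cluster)), 3)
})

test_that("size tolerance separates same-position calls; TRA uses both breakends", {
  calls <- normalize_calls(sv_calls(
    chrom = "chr1", start = c(100, 100), end = c(300, 320), svtype = "DEL",
    caller = c("m", "d"), sample = "s1", genotype = "0/1"))
  expect_equal(length(unique(cluster_calls(calls)$cluster)), 2)  # len differs by 20
  tra <- normalize_calls(sv_calls(
    chrom = "chr1", start = c(100, 105, 103), end = 101, svtype = "TRA",
    caller = c("m", "d", "b"), sample = "s1", genotype = "0/1",
    mate_chrom = "chr2", mate_pos = c(5000, 5008, 5100)))
  cl <- cluster_calls(tra)
  expect_equal(cl$cluster[1], cl$cluster[2])   # both breakends within 10
  expect_false(cl$cluster[3] == cl$cluster[1]) # mate 100 bp away
})

test_that("the partition does not depend on input order", {
  set.seed(42)
  for (i in 1:25) {
    calls <- random_callset()
    cl1 <- cluster_calls(calls)
    perm <- sample(nrow(calls))
    cl2 <- cluster_calls(calls[perm, ])
    lab2 <- integer(nrow(calls))
    lab2[perm] <- cl2$cluster
    expect_identical(canonical_partition(cl1$cluster),
                     canonical_partition(lab2))
  }
})

test_that("per-sample caller consensus keeps only multi-caller evidence", {
  calls <- normalize_calls(sv_calls(
    chrom = "chr1", start = c(100, 102, 101), end = c(300, 302, 301),
    svtype = "DEL", caller = c("m", "d", "m"),
    sample = c("s1", "s1", "s2"), genotype = "0/1"))
  cl <- cluster_calls(calls)
  cons <- apply_caller_consensus(cl)
  expect_equal(sort(unique(cons$sample)), "s1")  # s2 has 1 caller only
  # cohort-wide mode keeps s2's evidence: the cluster has 2 callers overall
  cons2 <- apply_caller_consensus(cl, per_sample = FALSE)
  expect_equal(sort(unique(cons2$sample)), c("s1", "s2"))
})

test_that("merged representatives are lower medians with severity genotypes", {
  calls <- normalize_calls(sv_calls(
    chrom = "chr1", start = c(100, 104, 102, 106), end = c(300, 304, 302, 306),
    svtype = "DEL", caller = c("m", "d", "m", "d"),
    sample = c("s1", "s1", "s2", "s2"),
    genotype = c("0/1", "1/1", "0/1", NA)))
  merged <- merge_across_samples(apply_caller_consensus(cluster_calls(calls)),
                                 samples = c("s1", "s2", "s3"))
  expect_equal(nrow(merged$svs), 1)
  expect_equal(merged$svs$start, 102)  # lower of the two middle values
  expect_equal(merged$svs$end, 302)
  expect_equal(unname(merged$gt[1, ]), c(2L, 1L, 0L))  # severity; absent = 0
})

test_that("a sample with evidence but no genotype is NA, not reference", {
  calls <- normalize_calls(sv_calls(
    chrom = "chr1", start = c(100, 102), end = c(300, 302), svtype = "DEL",
    caller = c("m", "d"), sample = "s1", genotype = NA))
  merged <- merge_across_samples(apply_caller_consensus(cluster_calls(calls)),
                                 samples = c("s1", "s2"))
  expect_true(is.na(merged$gt[1, "s1"]))
  expect_equal(unname(merged$gt[1, "s2"]), 0L)
})

test_that("the size cap drops strictly larger interval SVs; TRA exempt", {
  svs <- data.frame(id = c("a", "b", "c"), chrom = "chr1",
                    start = c(0, 0, 0), end = c(1e7, 1e7 + 1, 1),
                    svtype = c("DEL", "DEL", "TRA"),
                    length = c(1e7, 1e7 + 1, NA),
                    mate_chrom = c(NA, NA, "chr2"), mate_pos = c(NA, NA, 5),
                    n_samples = 1, stringsAsFactors = FALSE)
  merged <- structure(list(svs = svs,
                           gt = matrix(1L, 3, 1, dimnames = list(NULL, "s1")),
                           support = list(1, 1, 1)),
                      class = "merged_svs")
  expect_message(out <- filter_by_size(merged), "1 merged SV")
  expect_equal(out$svs$id, c("a", "c"))  # exactly 10 Mb kept, TRA kept
})

test_that("reference calibration counts matches one-to-one and sweeps tolerance", {
  svs <- data.frame(id = c("SV1", "SV2", "SV3"), chrom = "chr1",
                    start = c(100, 505, 9000), end = c(200, 606, 9100),
                    svtype = "DEL", length = c(100, 101, 100),
                    mate_chrom = NA, mate_pos = NA, n_samples = 1,
                    stringsAsFactors = FALSE)
  merged <- structure(list(svs = svs, gt = matrix(1L, 3, 1,
                                                  dimnames = list(NULL, "s1")),
                           support = list(1, 1, 1)), class = "merged_svs")
  ref <- data.frame(chrom = "chr1", start = c(102, 500), end = c(202, 600),
                    svtype = "DEL", stringsAsFactors = FALSE)
  rep10 <- calibrate_against_reference(merged, ref, match_tolerance = 10)
  expect_equal(rep10$n_detected, 3)
  expect_equal(rep10$n_overlapped, 2)
  expect_equal(rep10$n_false, 1)   # SV3 matches nothing
  expect_equal(rep10$n_missed, 0)
  expect_equal(sort(rep10$offsets), c(2, 6))
  rep2 <- calibrate_against_reference(merged, ref, match_tolerance = 2)
  expect_equal(rep2$n_overlapped, 1)  # only the 2-bp-offset pair survives
  swept <- calibrate_against_reference(merged, ref, sweep = c(2, 6, 10, 50))
  expect_equal(swept$best_tolerance, 6)  # smallest tolerance catching both
  expect_error(calibrate_against_reference(merged, ref[0, ]),
               "empty reference")
})

test_that("genotype matrix construction fills absent samples with zero", {
  calls <- normalize_calls(sv_calls(
    chrom = "chr1", start = c(100, 101), end = c(300, 301), svtype = "DEL",
    caller = c("m", "d"), sample = "s1", genotype = "1/1"))
  merged <- merge_sv_calls(calls, samples = c("s1", "s2"))
  m <- build_genotype_matrix(merged, groups = c(s1 = "a", s2 = "b"))
  expect_s3_class(m, "sv_matrix")
  expect_equal(unname(m$dosage[1, ]), c(2L, 0L))
  expect_equal(unname(m$groups), c("a", "b"))
})
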
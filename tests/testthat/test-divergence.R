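make_matrix <- function(dosage, groups = NULL) {
  sv_matrix(dosage, data.frame(id = rownames(dosage),
                               stringsAsFactors = FALSE), groups = groups)
}

test_that("fisher_exact_p agrees with stats::fisher.test", {
  set.seed(1)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2)
    p1 <- fisher_exact_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    p2 <- stats::fisher.test(tab)$p.value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("degenerate tables and bad counts are handled explicitly", {
  expect_equal(fisher_exact_p(0, 0, 5, 7), 1)   # zero row margin
  expect_equal(fisher_exact_p(0, 5, 0, 7), 1)   # zero column margin
  expect_error(fisher_exact_p(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_p(1.5, 2, 3, 4), "integer")
})

test_that("FDR adjustment is Benjamini-Hochberg and validates its input", {
  p <- c(0.001, 0.02, 0.4, 0.9, 0.0005)
  expect_equal(adjust_fdr(p), p.adjust(p, "BH"))
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
  expect_error(adjust_fdr(c(0.5, NA)), "0, 1")
})

test_that("MAF folds allele frequency and the filter is strict", {
  d <- rbind(sv1 = c(2L, 2L, 2L, 1L),   # af 7/8 -> maf 1/8
             sv2 = c(0L, 0L, 0L, 1L),   # af 1/8 -> maf 1/8
             sv3 = c(NA, NA, NA, NA),
             sv4 = c(1L, 0L, 0L, NA))   # af 1/6 over non-missing
  colnames(d) <- paste0("s", 1:4)
  m <- make_matrix(d)
  expect_equal(unname(sv_maf(m)), c(1 / 8, 1 / 8, NA, 1 / 6))
  expect_warning(f <- maf_filter(m, sv_config(maf_min = 0.125)), "all-missing")
  expect_equal(rownames(f$dosage), c("sv1", "sv2", "sv4"))  # == 0.125 kept
  f2 <- suppressWarnings(maf_filter(m, sv_config(maf_min = 0.13)))
  expect_equal(rownames(f2$dosage), "sv4")
})

test_that("divergence classification needs both the q and fold-ratio rules", {
  nA <- 30; nB <- 30
  d <- rbind(div = c(rep(2L, nA), rep(0L, nB)),      # fixed difference
             bal = rep(1L, nA + nB),                 # identical
             hi = c(rep(2L, nA), rep(2L, nB)))       # high everywhere
  colnames(d) <- paste0("s", seq_len(nA + nB))
  groups <- setNames(rep(c("a", "b"), c(nA, nB)), colnames(d))
  m <- make_matrix(d, groups)
  res <- sv_divergence(m, groups = c("a", "b"))
  expect_equal(res$classification,
               c("A_predominant", "not_divergent", "not_divergent"))
  expect_equal(res$freq_a[1], 1)
  expect_equal(res$freq_b[1], 0)   # zero denominator: infinite ratio passes
  expect_true(res$q[1] < 1e-4)
  # carrier mode uses sample counts, not allele counts
  res_c <- sv_divergence(m, groups = c("a", "b"), mode = "carrier")
  expect_equal(res_c$freq_a[2], 1)  # every sample carries the het
})

test_that("group-specific and shared SVs partition the set", {
  d <- rbind(onlyA = c(1L, 1L, 0L, 0L),
             onlyB = c(0L, 0L, 2L, 0L),
             both = c(1L, 0L, 1L, 0L),
             nobody = c(0L, 0L, 0L, 0L))
  colnames(d) <- paste0("s", 1:4)
  groups <- setNames(c("a", "a", "b", "b"), colnames(d))
  g <- group_specific_svs(make_matrix(d, groups))
  expect_equal(unname(g$specific[c("a", "b")]), c(1L, 1L))
  expect_equal(g$shared, 1)
  expect_equal(g$absent, 1)
  expect_equal(sum(g$specific) + g$shared + g$absent, nrow(d))
})

test_that("term enrichment matches the hypergeometric upper tail", {
  background <- paste0("g", 1:20)
  foreground <- paste0("g", 1:5)
  terms <- data.frame(term = rep(c("T1", "T2"), c(8, 4)),
                      gene = c(paste0("g", 1:8), paste0("g", 13:16)),
                      stringsAsFactors = FALSE)
  res <- enrichment_test(foreground, background, terms)
  expect_equal(res$p[res$term == "T1"],
               phyper(sum(foreground %in% paste0("g", 1:8)) - 1, 8, 12, 5,
                      lower.tail = FALSE))
  expect_error(enrichment_test(c("zzz"), background, terms), "subset")
  terms2 <- rbind(terms, data.frame(term = "T3", gene = "not_in_bg"))
  expect_warning(enrichment_test(foreground, background, terms2),
                 "no background gene")
})

test_that("landscape bins respect their documented boundaries", {
  svs <- data.frame(chrom = "chr1", start = 0, end = 1,
                    svtype = "INS",
                    length = c(50, 500, 501, 1000, 1001, 1e4, 1e4 + 1, 2e5),
                    mate_chrom = NA, mate_pos = NA, stringsAsFactors = FALSE)
  s <- summarize_landscape(svs, genome = c(chr1 = 1e6))
  expect_equal(s$length_bins$count, c(2L, 2L, 2L, 1L, 1L))
  expect_equal(sum(s$length_bins$proportion), 1)
  expect_equal(unname(s$density["chr1"]), 8)
})
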
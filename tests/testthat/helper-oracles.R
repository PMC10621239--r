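# Independent oracles used by the acceptance tests. These deliberately share
# no code with the package implementations.

# Brute-force single-linkage clustering: build the full pairwise link matrix
# from the definition, then take connected components by breadth-first search.
oracle_cluster <- function(calls, cfg = sv_config()) {
  n <- nrow(calls)
  d <- cfg$max_distance
  sd_max <- cfg$max_size_difference
  len0 <- ifelse(is.na(calls$length), 0, calls$length)
  mc <- ifelse(is.na(calls$mate_chrom), "", calls$mate_chrom)
  mp <- ifelse(is.na(calls$mate_pos), 0, calls$mate_pos)
  tra <- calls$svtype == "TRA"
  same <- outer(calls$chrom, calls$chrom, "==") &
    outer(calls$svtype, calls$svtype, "==")
  near_start <- abs(outer(calls$start, calls$start, "-")) <= d
  near_end <- abs(outer(calls$end, calls$end, "-")) <= d
  near_len <- abs(outer(len0, len0, "-")) <= sd_max
  near_mate <- outer(mc, mc, "==") & abs(outer(mp, mp, "-")) <= d
  both_tra <- outer(tra, tra, "&")
  link <- same & near_start &
    ((both_tra & near_mate) | (!both_tra & near_end & near_len))
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    comp[i] <- cur
    front <- i
    while (length(front)) {
      nb <- which(comp == 0L & colSums(link[front, , drop = FALSE]) > 0)
      comp[nb] <- cur
      front <- nb
    }
  }
  comp
}

# Canonical form of a partition given as arbitrary labels: a list of sorted
# index sets, ordered by smallest member. Two labelings describe the same
# partition iff their canonical forms are identical.
canonical_partition <- function(labels) {
  parts <- lapply(split(seq_along(labels), labels), sort)
  unname(parts[order(vapply(parts, function(p) p[1], integer(1)))])
}

# Random adversarial call set: positions, lengths and mate positions jittered
# around a few anchors so that pairwise differences straddle the 10-bp
# tolerances, plus a mix of chromosomes and all five SV types.
random_callset <- function(max_n = 30) {
  n <- sample(3:max_n, 1)
  types <- c("DEL", "INS", "DUP", "INV", "TRA")
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  svtype <- sample(types, n, replace = TRUE,
                   prob = c(0.3, 0.2, 0.2, 0.15, 0.15))
  start <- sample(c(1000, 1015, 1500), n, replace = TRUE) +
    sample(-8:8, n, replace = TRUE)
  len <- sample(c(100, 111, 400), n, replace = TRUE) +
    sample(-8:8, n, replace = TRUE)
  end <- start + len
  ins <- svtype == "INS"
  end[ins] <- start[ins] + 1
  tra <- svtype == "TRA"
  mate_chrom <- ifelse(tra, sample(c("chr1", "chr3"), n, replace = TRUE),
                       NA_character_)
  mate_pos <- ifelse(tra, 5000 + sample(-12:12, n, replace = TRUE), NA_real_)
  end[tra] <- start[tra] + 1
  len[tra] <- NA_real_
  normalize_calls(sv_calls(
    chrom, start, end, svtype, len,
    caller = sample(c("m", "d", "b"), n, replace = TRUE),
    sample = sample(c("s1", "s2"), n, replace = TRUE),
    genotype = sample(c("0/1", "1/1"), n, replace = TRUE),
    mate_chrom = mate_chrom, mate_pos = mate_pos))
}

# Exhaustive enumeration of all 2x2 tables with both row margins <= max_margin,
# with the two-sided Fisher p computed directly from binomial coefficients
# (a code path independent of fisher_exact_p's dhyper summation).
enumerate_fisher_tables <- function(max_margin = 30) {
  A <- list(); B <- list(); C <- list(); D <- list(); P <- list()
  idx <- 0L
  for (m1 in 0:max_margin) for (m2 in 0:max_margin) for (k in 0:(m1 + m2)) {
    lo <- max(0, k - m2); hi <- min(k, m1)
    x <- lo:hi
    dens <- exp(lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k))
    p <- vapply(dens, function(dobs) {
      min(1, sum(dens[dens <= dobs * (1 + 1e-7)]))
    }, numeric(1))
    if (m1 == 0 || m2 == 0 || k == 0 || k == m1 + m2) p[] <- 1
    idx <- idx + 1L
    A[[idx]] <- x; B[[idx]] <- m1 - x
    C[[idx]] <- k - x; D[[idx]] <- m2 - (k - x)
    P[[idx]] <- p
  }
  data.frame(a = unlist(A), b = unlist(B), c = unlist(C), d = unlist(D),
             p = unlist(P))
}

# Match merged SVs back to simulated truth: truth SVs sit on a 2-kb grid and
# caller jitter is bounded well under 100 bp, so a 100-bp window identifies
# the generating truth SV unambiguously (NA = matches no truth SV).
match_to_truth <- function(merged_svs, truth_svs, tolerance = 100) {
  midx <- rep(NA_integer_, nrow(merged_svs))
  for (i in seq_len(nrow(merged_svs))) {
    cand <- which(truth_svs$chrom == merged_svs$chrom[i] &
                    truth_svs$svtype == merged_svs$svtype[i] &
                    abs(truth_svs$start - merged_svs$start[i]) <= tolerance)
    if (length(cand) == 1) midx[i] <- cand
  }
  midx
}
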
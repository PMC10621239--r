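#' Per-SV minor allele frequency
#'
#' Alt-allele frequency is Sum(dosage) / (2 x non-missing samples); the MAF
#' folds it onto [0, 0.5].
#'
#' @param m An \code{sv_matrix}.
#' @return Numeric vector of MAFs (NA for all-missing rows).
#' @export
sv_maf <- function(m) {
  d <- m$dosage
  nm <- rowSums(!is.na(d))
  af <- rowSums(d, na.rm = TRUE) / (2 * nm)
  af[nm == 0] <- NA
  pmin(af, 1 - af)
}

#' Filter SVs by minor allele frequency
#'
#' Removes SVs whose overall MAF is strictly below \code{cfg$maf_min}
#' (missing dosages are excluded from the denominators); rows that are
#' entirely missing are removed with a warning.
#'
#' @param m An \code{sv_matrix}.
#' @param cfg An \code{\link{sv_config}}.
#' @return The filtered \code{sv_matrix}.
#' @export
maf_filter <- function(m, cfg = sv_config()) {
  cfg <- as_sv_config(cfg)
  maf <- sv_maf(m)
  if (anyNA(maf)) warning(sum(is.na(maf)), " all-missing SV row(s) removed")
  keep <- !is.na(maf) & maf >= cfg$maf_min
  m[keep, ]
}

#' Alt-allele frequency per SV within one group
#'
#' @param m An \code{sv_matrix} with group labels.
#' @param group Group label.
#' @return Numeric vector: Sum(dosage) / (2 x non-missing samples in group).
#' @export
group_allele_frequency <- function(m, group) {
  if (is.null(m$groups)) stop("sv_matrix has no group labels")
  sel <- which(m$groups == group)
  if (!length(sel)) stop("empty group: ", group)
  d <- m$dosage[, sel, drop = FALSE]
  nm <- rowSums(!is.na(d))
  f <- rowSums(d, na.rm = TRUE) / (2 * nm)
  f[nm == 0] <- NA
  f
}

#' Two-sided Fisher exact p-value for 2x2 tables
#'
#' Computes the two-sided p-value by summing hypergeometric point
#' probabilities not exceeding that of the observed table (with the
#' conventional relative tolerance 1 + 1e-7). Tables with a zero margin carry
#' no information and return p = 1. Vectorised over table entries.
#'
#' @param a,b,c,d Cell counts: rows are groups, columns allele (or carrier)
#'   states, i.e. table rbind(c(a, b), c(c, d)).
#' @return Numeric vector of p-values.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != floor(c(a, b, c, d)))) {
    stop("cell counts must be non-negative integers")
  }
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]; m2 <- c[i] + d[i]; k <- a[i] + c[i]
    if (m1 == 0 || m2 == 0 || k == 0 || (b[i] + d[i]) == 0) {
      p[i] <- 1
      next
    }
    lo <- max(0, k - m2); hi <- min(k, m1)
    x <- lo:hi
    dens <- stats::dhyper(x, m1, m2, k)
    obs <- dens[a[i] - lo + 1]
    p[i] <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p Vector of p-values in [0, 1].
#' @return q-values (BH step-up), preserving the rank order of \code{p}.
#' @export
adjust_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Between-group SV frequency divergence
#'
#' For each SV, builds the 2x2 allele-count table (alt/ref x group) from
#' dosages, computes the two-sided Fisher exact p, BH-adjusts, and classifies
#' an SV as divergent toward the higher-frequency group when q <
#' \code{cfg$fdr_alpha} and the frequency fold-ratio exceeds
#' \code{cfg$freq_ratio_min} (a zero denominator counts as infinite ratio).
#'
#' @param m An \code{sv_matrix} with exactly two group labels (or
#'   \code{groups} given explicitly).
#' @param groups Optional character(2): the two group labels to compare.
#' @param cfg An \code{\link{sv_config}}.
#' @param mode "allele" (2n allele counts, default) or "carrier"
#'   (samples with dosage > 0 vs not).
#' @return Data.frame: id, freq_a, freq_b, p, q, classification
#'   (A_predominant / B_predominant / not_divergent).
#' @export
sv_divergence <- function(m, groups = NULL, cfg = sv_config(),
                          mode = c("allele", "carrier")) {
  cfg <- as_sv_config(cfg)
  mode <- match.arg(mode)
  if (is.null(m$groups)) stop("sv_matrix has no group labels")
  if (is.null(groups)) groups <- unique(m$groups)
  if (length(groups) != 2) stop("exactly two groups required")
  da <- m$dosage[, m$groups == groups[1], drop = FALSE]
  db <- m$dosage[, m$groups == groups[2], drop = FALSE]
  if (mode == "allele") {
    alt_a <- rowSums(da, na.rm = TRUE)
    tot_a <- 2 * rowSums(!is.na(da))
    alt_b <- rowSums(db, na.rm = TRUE)
    tot_b <- 2 * rowSums(!is.na(db))
  } else {
    alt_a <- rowSums(da > 0, na.rm = TRUE)
    tot_a <- rowSums(!is.na(da))
    alt_b <- rowSums(db > 0, na.rm = TRUE)
    tot_b <- rowSums(!is.na(db))
  }
  freq_a <- ifelse(tot_a > 0, alt_a / tot_a, NA)
  freq_b <- ifelse(tot_b > 0, alt_b / tot_b, NA)
  p <- fisher_exact_p(alt_a, tot_a - alt_a, alt_b, tot_b - alt_b)
  q <- adjust_fdr(p)
  ratio <- pmax(freq_a, freq_b) / pmin(freq_a, freq_b)
  ratio[pmin(freq_a, freq_b) == 0 & pmax(freq_a, freq_b) > 0] <- Inf
  ratio[pmax(freq_a, freq_b) == 0] <- 1
  divergent <- !is.na(q) & q < cfg$fdr_alpha & ratio > cfg$freq_ratio_min
  classification <- ifelse(!divergent, "not_divergent",
                           ifelse(freq_a > freq_b, "A_predominant",
                                  "B_predominant"))
  data.frame(id = m$info$id, freq_a = freq_a, freq_b = freq_b,
             p = p, q = q, classification = classification,
             stringsAsFactors = FALSE)
}

#' Group-specific and shared SV counts
#'
#' An SV is specific to a group when its alt frequency is positive there and
#' zero in every other group; shared when positive in at least two groups.
#' Together with SVs absent everywhere these categories partition the SV set.
#'
#' @param m An \code{sv_matrix} with group labels (>= 2 groups).
#' @return List: \code{specific} (named count per group), \code{shared},
#'   \code{absent}, and the per-SV \code{presence} logical matrix.
#' @export
group_specific_svs <- function(m) {
  if (is.null(m$groups)) stop("sv_matrix has no group labels")
  gl <- unique(m$groups)
  if (length(gl) < 2) stop("need at least two groups")
  pres <- vapply(gl, function(g) {
    rowSums(m$dosage[, m$groups == g, drop = FALSE], na.rm = TRUE) > 0
  }, logical(nrow(m$dosage)))
  colnames(pres) <- gl
  npres <- rowSums(pres)
  specific <- vapply(gl, function(g) sum(pres[, g] & npres == 1), integer(1))
  list(specific = specific, shared = sum(npres >= 2), absent = sum(npres == 0),
       presence = pres)
}

#' Hypergeometric term over-representation test
#'
#' One-sided (upper tail) hypergeometric test per term, BH-adjusted. Terms
#' with no background gene are skipped with a warning.
#'
#' @param foreground Character vector of genes of interest (must be a subset
#'   of \code{background}).
#' @param background Character vector: the gene universe.
#' @param terms Data.frame with columns \code{term}, \code{gene}.
#' @return Data.frame: term, n_fg, n_term, p, q, ordered by p.
#' @export
enrichment_test <- function(foreground, background, terms) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    stop("foreground genes must be a subset of the background")
  }
  all_terms <- unique(terms$term)
  terms <- terms[terms$gene %in% background, , drop = FALSE]
  empty <- setdiff(all_terms, unique(terms$term))
  if (length(empty)) {
    warning("term(s) with no background gene skipped: ",
            paste(empty, collapse = ", "))
  }
  tl <- split(terms$gene, terms$term)
  if (!length(tl)) {
    warning("no non-empty terms after restricting to background")
    return(data.frame(term = character(), n_fg = integer(),
                      n_term = integer(), p = numeric(), q = numeric()))
  }
  N <- length(background)
  K <- length(foreground)
  res <- lapply(names(tl), function(t) {
    tg <- unique(tl[[t]])
    x <- sum(foreground %in% tg)
    p <- stats::phyper(x - 1, length(tg), N - length(tg), K,
                       lower.tail = FALSE)
    data.frame(term = t, n_fg = x, n_term = length(tg), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- adjust_fdr(res$p)
  res[order(res$p), , drop = FALSE]
}

#' Summarize the SV landscape
#'
#' Length-bin counts and proportions over the bins [50, 500], (500, 1000],
#' (1000, 1e4], (1e4, 1e5], (1e5, Inf) bp, counts per SV type, and SV density
#' (count per Mb) per chromosome. TRA records have no length and are excluded
#' from the bins by default.
#'
#' @param svs SV data.frame (\code{merged$svs}).
#' @param genome Named numeric vector of chromosome lengths (bp).
#' @param include_tra Bin TRA records by inter-breakpoint span (same
#'   chromosome only).
#' @return List: \code{length_bins} (count and proportion per bin),
#'   \code{by_type}, \code{density} (per chromosome, count/Mb).
#' @export
summarize_landscape <- function(svs, genome = NULL, include_tra = FALSE) {
  len <- svs$length
  if (include_tra) {
    tra <- svs$svtype == "TRA" & svs$chrom == svs$mate_chrom
    len[tra] <- abs(svs$mate_pos[tra] - svs$start[tra])
  }
  len <- len[!is.na(len)]
  breaks <- c(50, 500, 1000, 1e4, 1e5, Inf)
  labs <- c("50-500", "500-1k", "1k-10k", "10k-100k", ">100k")
  bins <- table(cut(len, breaks, labels = labs, include.lowest = TRUE))
  by_type <- table(factor(svs$svtype, levels = SV_TYPES))
  density <- NULL
  if (!is.null(genome)) {
    cnt <- table(factor(svs$chrom, levels = names(genome)))
    density <- as.numeric(cnt) / (genome / 1e6)
    names(density) <- names(genome)
  }
  list(length_bins = data.frame(bin = labs, count = as.integer(bins),
                                proportion = if (sum(bins)) as.integer(bins) / sum(bins) else rep(0, length(labs))),
       by_type = by_type, density = density)
}
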
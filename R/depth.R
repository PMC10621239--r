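#' Windowed depth ratios for one sample
#'
#' Computes mean sequencing depth in sliding windows (default 100 kb with a
#' 10-kb step) from a bedGraph-like track and divides by the sample's
#' genome-average depth. A chromosome of length G yields
#' floor((G - window) / step) + 1 windows.
#'
#' @param track Data.frame with columns chrom, start, end, depth (0-based
#'   half-open intervals, bedGraph convention); positions not covered by any
#'   interval count as depth 0.
#' @param cfg An \code{\link{sv_config}}.
#' @param genome Named numeric vector of chromosome lengths; defaults to the
#'   maximum end per chromosome in the track.
#' @param sample Sample id to stamp on the profile.
#' @param average "mean" (default) or "median" of the window depths as the
#'   genome-average depth.
#' @return A \code{depth_profile}: list with \code{sample}, \code{windows}
#'   (chrom, start, end, depth, ratio) and \code{genome_avg}.
#' @export
compute_window_ratios <- function(track, cfg = sv_config(), genome = NULL,
                                  sample = "sample",
                                  average = c("mean", "median")) {
  cfg <- as_sv_config(cfg)
  average <- match.arg(average)
  if (is.null(track) || nrow(track) == 0) stop("empty depth track")
  if (is.null(genome)) {
    genome <- tapply(track$end, track$chrom, max)
    genome <- stats::setNames(as.numeric(genome), names(genome))
  }
  win <- cfg$depth_window; step <- cfg$depth_step
  out <- list()
  for (ch in names(genome)) {
    G <- genome[[ch]]
    if (G < win) next
    starts <- seq(0, G - win, by = step)
    tr <- track[track$chrom == ch, , drop = FALSE]
    cov <- S4Vectors::Rle(0, G)
    if (nrow(tr)) {
      o <- order(tr$start)
      tr <- tr[o, , drop = FALSE]
      vals <- numeric(0); lens <- numeric(0)
      pos <- 0
      for (i in seq_len(nrow(tr))) {
        if (tr$start[i] > pos) {
          vals <- c(vals, 0); lens <- c(lens, tr$start[i] - pos)
        }
        vals <- c(vals, tr$depth[i]); lens <- c(lens, tr$end[i] - tr$start[i])
        pos <- tr$end[i]
      }
      if (pos < G) { vals <- c(vals, 0); lens <- c(lens, G - pos) }
      cov <- S4Vectors::Rle(vals, lens)
    }
    v <- IRanges::Views(cov, start = starts + 1, width = win)
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = starts + win,
                            depth = IRanges::viewMeans(v),
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no chromosome long enough for one window")
  windows <- do.call(rbind, out)
  rownames(windows) <- NULL
  avg <- if (average == "mean") mean(windows$depth) else
    stats::median(windows$depth)
  if (avg <= 0) stop("genome-average depth is zero")
  windows$ratio <- windows$depth / avg
  structure(list(sample = sample, windows = windows, genome_avg = avg),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("Depth profile for %s: %d windows, genome-average depth %.2f\n",
              x$sample, nrow(x$windows), x$genome_avg))
  invisible(x)
}

#' Call deletions from windowed depth ratios
#'
#' A deletion is a maximal run of consecutive windows whose depth ratio is
#' strictly below \code{cfg$depth_del_ratio} (half the genome average by
#' default). The call spans the union of the run's windows; runs separated by
#' at least one non-qualifying window stay separate calls.
#'
#' Because each window is much wider than the step, the union span
#' systematically overshoots the true deletion edges: an edge window's ratio
#' falls linearly from the background ratio b to the plateau ratio c as its
#' deleted fraction f grows, so it qualifies once b - (b - c) f < t
#' (threshold t). The reported \code{refined_start}/\code{refined_end} invert
#' that relation using the run's plateau estimate and the chromosome's median
#' window ratio as the background, which places the edges to within about one
#' window step. (The background is not exactly 1 because the genome-average
#' depth itself includes any deleted regions.)
#'
#' @param profile A \code{depth_profile}.
#' @param cfg An \code{\link{sv_config}}.
#' @return Data.frame: sample, chrom, start, end (union of qualifying
#'   windows), refined_start, refined_end (edge-model estimates), n_windows,
#'   mean_ratio.
#' @export
call_depth_deletions <- function(profile, cfg = sv_config()) {
  cfg <- as_sv_config(cfg)
  w <- profile$windows
  out <- list()
  for (ch in unique(w$chrom)) {
    ww <- w[w$chrom == ch, , drop = FALSE]
    low <- ww$ratio < cfg$depth_del_ratio
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    win <- cfg$depth_window; step <- cfg$depth_step
    core_k <- ceiling(win / step) - 1           # windows clipped at each edge
    bg <- max(stats::median(ww$ratio), cfg$depth_del_ratio + 1e-6)
    for (k in which(r$values)) {
      i <- starts[k]; j <- ends[k]
      run_ratio <- ww$ratio[i:j]
      # plateau depth ratio: interior windows if the run is long enough
      chat <- if (length(run_ratio) > 2 * core_k) {
        mean(run_ratio[(core_k + 1):(length(run_ratio) - core_k)])
      } else {
        min(run_ratio)
      }
      chat <- min(max(chat, 0), cfg$depth_del_ratio)
      phi <- (bg - cfg$depth_del_ratio) / (bg - chat)
      out[[length(out) + 1]] <- data.frame(
        sample = profile$sample, chrom = ch,
        start = ww$start[i], end = ww$end[j],
        refined_start = ww$start[i] + win * (1 - phi) - step / 2,
        refined_end = ww$start[j] + win * phi + step / 2,
        n_windows = j - i + 1,
        mean_ratio = mean(run_ratio),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_windows = integer(), mean_ratio = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Carrier table for a deletion region by phenotype class
#'
#' A sample carries the deletion when one of its depth-derived calls
#' reciprocally overlaps the region by at least \code{min_reciprocal}.
#' Returns class x carrier/non-carrier counts ready for
#' \code{\link{fisher_exact_p}} in carrier mode.
#'
#' @param calls Data.frame of deletion calls (pooled over samples, as from
#'   \code{\link{call_depth_deletions}}).
#' @param region List or data.frame with chrom, start, end.
#' @param classes Named vector: sample -> phenotype class (two classes).
#' @param profiled Character vector of samples that have depth profiles;
#'   phenotyped samples without a profile are excluded with a warning.
#' @param min_reciprocal Minimum reciprocal overlap fraction (default 0.5).
#' @return A 2x2 integer matrix (rows: classes; cols: carrier, non_carrier).
#' @export
deletion_carrier_table <- function(calls, region, classes,
                                   profiled = unique(calls$sample),
                                   min_reciprocal = 0.5) {
  samples <- names(classes)
  no_profile <- setdiff(samples, profiled)
  if (length(no_profile)) {
    warning(length(no_profile),
            " phenotyped sample(s) without depth profile excluded")
    samples <- setdiff(samples, no_profile)
  }
  reg_len <- region$end - region$start
  in_reg <- calls$chrom == region$chrom
  ov <- pmin(calls$end, region$end) - pmax(calls$start, region$start)
  recip <- in_reg & ov > 0 &
    ov / (calls$end - calls$start) >= min_reciprocal &
    ov / reg_len >= min_reciprocal
  carriers <- unique(calls$sample[recip])
  cls <- sort(unique(as.character(classes[samples])))
  if (length(cls) != 2) stop("exactly two phenotype classes required")
  tab <- matrix(0L, 2, 2, dimnames = list(cls, c("carrier", "non_carrier")))
  for (cl in cls) {
    s <- samples[classes[samples] == cl]
    tab[cl, "carrier"] <- sum(s %in% carriers)
    tab[cl, "non_carrier"] <- sum(!s %in% carriers)
  }
  tab
}
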
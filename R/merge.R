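# lower median: middle value, or the lower of the two middle values
median_low <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else x[n / 2]
}

#' Cluster caller-level SV calls under breakpoint/size tolerances
#'
#' Single-linkage transitive clustering, performed independently per
#' (chromosome, SV type). Two interval calls link iff their starts differ by
#' at most \code{max_distance}, their ends by at most \code{max_distance},
#' and their lengths by at most \code{max_size_difference}. TRA calls link
#' when both breakend pairs are within \code{max_distance}; the size test is
#' skipped. Clusters form a partition of the input and do not depend on input
#' order.
#'
#' @param calls Normalized \code{sv_calls}.
#' @param cfg An \code{\link{sv_config}}.
#' @return \code{calls} with an integer \code{cluster} column; cluster ids are
#'   globally unique. \code{split(calls, calls$cluster)} is the partition.
#' @export
cluster_calls <- function(calls, cfg = sv_config()) {
  cfg <- as_sv_config(cfg)
  calls <- as.data.frame(calls)
  n <- nrow(calls)
  calls$cluster <- integer(n)
  if (n == 0) {
    class(calls) <- c("sv_calls", "data.frame")
    return(calls)
  }
  grp <- paste(calls$chrom, calls$svtype, sep = "\r")
  mate_key <- as.integer(factor(ifelse(is.na(calls$mate_chrom), "",
                                       calls$mate_chrom)))
  offset <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    o <- idx[order(calls$start[idx])]
    lab <- .cluster_group(calls$start[o], calls$end[o],
                          ifelse(is.na(calls$length[o]), 0, calls$length[o]),
                          mate_key[o],
                          ifelse(is.na(calls$mate_pos[o]), 0, calls$mate_pos[o]),
                          calls$svtype[o[1]] == "TRA",
                          cfg$max_distance, cfg$max_size_difference)
    calls$cluster[o] <- lab + offset
    offset <- offset + max(lab)
  }
  class(calls) <- c("sv_calls", "data.frame")
  calls
}

#' Enforce per-sample caller consensus within clusters
#'
#' Within each cluster, a sample's calls are kept only if at least
#' \code{min_caller_support} distinct callers contributed a call for that
#' sample (the 2-of-3 rule by default). Clusters left with no supported
#' sample are dropped. With \code{per_sample = FALSE} the caller count is
#' taken over the whole cluster instead (cohort-wide consensus).
#'
#' @param clustered Output of \code{\link{cluster_calls}}.
#' @param cfg An \code{\link{sv_config}}.
#' @param per_sample Count distinct callers per (cluster, sample) rather than
#'   per cluster.
#' @return The surviving calls, cluster column preserved.
#' @export
apply_caller_consensus <- function(clustered, cfg = sv_config(),
                                   per_sample = TRUE) {
  cfg <- as_sv_config(cfg)
  if (cfg$min_caller_support < 1) stop("min_caller_support must be >= 1")
  if (nrow(clustered) == 0) return(clustered)
  if (per_sample) {
    key <- paste(clustered$cluster, clustered$sample, sep = "\r")
  } else {
    key <- as.character(clustered$cluster)
  }
  ncall <- vapply(split(clustered$caller, key),
                  function(cl) length(unique(cl)), integer(1))
  keep <- ncall[key] >= cfg$min_caller_support
  out <- clustered[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge consensus calls across samples into representative SVs
#'
#' Collapses each cross-sample cluster into one merged SV. When the input
#' carries the \code{cluster} column from \code{\link{cluster_calls}} that
#' partition is reused (dropping unsupported evidence does not re-evaluate
#' linkage); otherwise the linkage rule is applied first. Representative
#' coordinates and length are the per-field lower medians of the member
#' values; each sample's genotype is the most severe genotype among that
#' sample's member calls (1/1 > 0/1 > 0/0).
#'
#' @param consensus Calls surviving \code{\link{apply_caller_consensus}}.
#' @param cfg An \code{\link{sv_config}}.
#' @param samples Sample universe for the genotype matrix; defaults to the
#'   samples observed in \code{consensus}.
#' @param recluster Re-apply the linkage rule even when a \code{cluster}
#'   column is present.
#' @return A \code{merged_svs} object: list with \code{svs} (data.frame: id,
#'   chrom, start, end, svtype, length, mate_chrom, mate_pos, n_samples),
#'   \code{gt} (SV x sample dosage matrix; NA where a sample has evidence but
#'   no genotype, 0 where it has no evidence), and \code{support} (per SV, a
#'   named integer vector sample -> number of supporting callers).
#' @export
merge_across_samples <- function(consensus, cfg = sv_config(), samples = NULL,
                                 recluster = FALSE) {
  cfg <- as_sv_config(cfg)
  if (is.null(samples)) samples <- sort(unique(consensus$sample))
  clustered <- if (!recluster && !is.null(consensus$cluster)) consensus else
    cluster_calls(consensus, cfg)
  cl_ids <- sort(unique(clustered$cluster))
  n_sv <- length(cl_ids)
  svs <- data.frame(id = character(n_sv), chrom = character(n_sv),
                    start = numeric(n_sv), end = numeric(n_sv),
                    svtype = character(n_sv), length = numeric(n_sv),
                    mate_chrom = NA_character_, mate_pos = NA_real_,
                    n_samples = integer(n_sv), stringsAsFactors = FALSE)
  gt <- matrix(0L, nrow = n_sv, ncol = length(samples),
               dimnames = list(NULL, samples))
  support <- vector("list", n_sv)
  parts <- split(seq_len(nrow(clustered)), clustered$cluster)
  for (k in seq_len(n_sv)) {
    rows <- clustered[parts[[as.character(cl_ids[k])]], , drop = FALSE]
    tra <- rows$svtype[1] == "TRA"
    svs$chrom[k] <- rows$chrom[1]
    svs$svtype[k] <- rows$svtype[1]
    svs$start[k] <- median_low(rows$start)
    svs$end[k] <- if (rows$svtype[1] == "INS") svs$start[k] + 1 else median_low(rows$end)
    svs$length[k] <- if (tra) NA_real_ else median_low(rows$length)
    if (tra) {
      svs$mate_chrom[k] <- rows$mate_chrom[1]
      svs$mate_pos[k] <- median_low(rows$mate_pos)
    }
    d <- gt_dosage(rows$genotype)
    by_sample <- split(d, rows$sample)
    gsam <- vapply(by_sample, function(z) {
      if (all(is.na(z))) NA_integer_ else max(z, na.rm = TRUE)
    }, integer(1))
    gsam <- gsam[names(gsam) %in% samples]
    gt[k, names(gsam)] <- gsam
    svs$n_samples[k] <- length(gsam)
    support[[k]] <- vapply(split(rows$caller, rows$sample),
                           function(cl) length(unique(cl)), integer(1))
  }
  o <- order(svs$chrom, svs$start, svs$end)
  svs <- svs[o, , drop = FALSE]
  gt <- gt[o, , drop = FALSE]
  support <- support[o]
  svs$id <- sprintf("SV%05d", seq_len(n_sv))
  rownames(svs) <- NULL
  structure(list(svs = svs, gt = gt, support = support),
            class = "merged_svs")
}

#' @export
print.merged_svs <- function(x, ...) {
  cat(sprintf("Merged SV set: %d SVs x %d samples\n",
              nrow(x$svs), ncol(x$gt)))
  if (nrow(x$svs)) print(table(x$svs$svtype))
  invisible(x)
}

#' Drop merged SVs above the maximum size
#'
#' Interval SVs with length strictly greater than \code{max_sv_length}
#' (default 10 Mb) are removed; TRA records, which have no length, are exempt.
#'
#' @param merged A \code{merged_svs} object.
#' @param cfg An \code{\link{sv_config}}.
#' @return The filtered \code{merged_svs}; the number removed is reported via
#'   \code{message()}.
#' @export
filter_by_size <- function(merged, cfg = sv_config()) {
  cfg <- as_sv_config(cfg)
  drop <- !is.na(merged$svs$length) & merged$svs$length > cfg$max_sv_length &
    merged$svs$svtype != "TRA"
  if (any(drop)) {
    message(sum(drop), " merged SV(s) above ", cfg$max_sv_length,
            " bp removed")
  }
  merged$svs <- merged$svs[!drop, , drop = FALSE]
  rownames(merged$svs) <- NULL
  merged$gt <- merged$gt[!drop, , drop = FALSE]
  merged$support <- merged$support[!drop]
  merged
}

#' Merge caller-level calls end to end
#'
#' Convenience wrapper: cluster, apply caller consensus, merge across samples
#' and apply the size cap.
#'
#' @inheritParams cluster_calls
#' @param samples Sample universe (see \code{\link{merge_across_samples}}).
#' @param per_sample See \code{\link{apply_caller_consensus}}.
#' @return A \code{merged_svs} object.
#' @export
merge_sv_calls <- function(calls, cfg = sv_config(), samples = NULL,
                           per_sample = TRUE) {
  cfg <- as_sv_config(cfg)
  clustered <- cluster_calls(normalize_calls(calls), cfg)
  consensus <- apply_caller_consensus(clustered, cfg, per_sample = per_sample)
  merged <- merge_across_samples(consensus, cfg, samples = samples)
  filter_by_size(merged, cfg)
}

#' Score merged SVs against a curated reference set
#'
#' Matches merged SVs to reference SVs of the same type whose start and end
#' breakpoints are both within \code{match_tolerance} bp, using greedy
#' one-to-one matching in increasing breakpoint-offset order. Optionally
#' restricted to one region, and optionally swept over a tolerance grid.
#'
#' @param merged A \code{merged_svs} object.
#' @param reference Data.frame from \code{\link{read_reference_table}}.
#' @param match_tolerance Breakpoint tolerance in bp (default
#'   \code{cfg$max_distance}).
#' @param cfg An \code{\link{sv_config}}.
#' @param region Optional list(chrom, start, end) restricting both sets.
#' @param sweep Optional numeric vector of tolerances; when given, the report
#'   gains a \code{sweep} data.frame and \code{best_tolerance}, the smallest
#'   tolerance maximizing \code{n_overlapped - n_false}.
#' @return A \code{concordance_report}: n_detected, n_overlapped, n_false,
#'   n_missed, and the matched pairs' breakpoint offsets (bp).
#' @export
calibrate_against_reference <- function(merged, reference,
                                        match_tolerance = NULL,
                                        cfg = sv_config(), region = NULL,
                                        sweep = NULL) {
  cfg <- as_sv_config(cfg)
  if (is.null(match_tolerance)) match_tolerance <- cfg$max_distance
  if (nrow(reference) == 0) stop("empty reference set: nothing to calibrate against")
  det <- merged$svs
  if (!is.null(region)) {
    inreg <- function(df) df$chrom == region$chrom &
      df$start < region$end & df$end > region$start
    det <- det[inreg(det), , drop = FALSE]
    reference <- reference[inreg(reference), , drop = FALSE]
    if (nrow(reference) == 0) stop("empty reference set in region")
  }
  score <- function(tol) {
    matched_det <- rep(FALSE, nrow(det))
    matched_ref <- rep(FALSE, nrow(reference))
    offs <- numeric(0)
    if (nrow(det) && nrow(reference)) {
      pairs <- list()
      for (i in seq_len(nrow(det))) {
        cand <- which(reference$svtype == det$svtype[i] &
                        reference$chrom == det$chrom[i] &
                        abs(reference$start - det$start[i]) <= tol &
                        abs(reference$end - det$end[i]) <= tol)
        for (j in cand) {
          pairs[[length(pairs) + 1]] <- c(i, j, max(
            abs(reference$start[j] - det$start[i]),
            abs(reference$end[j] - det$end[i])))
        }
      }
      if (length(pairs)) {
        pm <- do.call(rbind, pairs)
        pm <- pm[order(pm[, 3], pm[, 1], pm[, 2]), , drop = FALSE]
        for (r in seq_len(nrow(pm))) {
          i <- pm[r, 1]; j <- pm[r, 2]
          if (!matched_det[i] && !matched_ref[j]) {
            matched_det[i] <- TRUE
            matched_ref[j] <- TRUE
            offs <- c(offs, pm[r, 3])
          }
        }
      }
    }
    list(n_detected = nrow(det),
         n_overlapped = sum(matched_det),
         n_false = nrow(det) - sum(matched_det),
         n_missed = sum(!matched_ref),
         offsets = offs)
  }
  rep0 <- score(match_tolerance)
  rep0$tolerance <- match_tolerance
  if (!is.null(sweep)) {
    grid <- lapply(sweep, function(t) {
      s <- score(t)
      data.frame(tolerance = t, n_overlapped = s$n_overlapped,
                 n_false = s$n_false)
    })
    grid <- do.call(rbind, grid)
    obj <- grid$n_overlapped - grid$n_false
    rep0$sweep <- grid
    rep0$best_tolerance <- min(grid$tolerance[obj == max(obj)])
  }
  structure(rep0, class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(paste0("Concordance vs curated reference (tolerance %g bp):\n",
                     "  detected %d, overlapped %d, false %d, missed %d\n"),
              x$tolerance, x$n_detected, x$n_overlapped, x$n_false, x$n_missed))
  if (!is.null(x$best_tolerance)) {
    cat(sprintf("  sweep best tolerance: %g bp\n", x$best_tolerance))
  }
  invisible(x)
}

#' Build the SV genotype (dosage) matrix
#'
#' Assembles the merged-SV x sample diploid dosage matrix (entries 0, 1, 2 or
#' NA). A sample absent from an SV's evidence receives dosage 0 — absence of
#' a consensus call is treated as the reference genotype, not as missing.
#'
#' @param merged A \code{merged_svs} object.
#' @param samples Ordered sample universe; defaults to the matrix columns.
#' @param groups Optional named vector/factor: sample -> population label.
#' @return An \code{sv_matrix}: list with \code{dosage} (SV x sample matrix),
#'   \code{info} (SV metadata), \code{samples}, \code{groups}.
#' @export
build_genotype_matrix <- function(merged, samples = NULL, groups = NULL) {
  if (is.null(samples)) samples <- colnames(merged$gt)
  if (anyDuplicated(merged$svs$id)) stop("duplicate SV identifiers")
  dos <- matrix(0L, nrow(merged$svs), length(samples),
                dimnames = list(merged$svs$id, samples))
  common <- intersect(samples, colnames(merged$gt))
  dos[, common] <- merged$gt[, common]
  sv_matrix(dos, merged$svs, groups = groups)
}

#' Construct an SV dosage matrix object
#'
#' @param dosage SV x sample matrix with entries 0/1/2/NA.
#' @param info Data.frame of SV metadata (id, chrom, start, end, svtype,
#'   length) with one row per matrix row.
#' @param groups Optional named vector: sample -> group label.
#' @return An object of class \code{sv_matrix}.
#' @export
sv_matrix <- function(dosage, info, groups = NULL) {
  stopifnot(nrow(dosage) == nrow(info))
  if (anyDuplicated(info$id)) stop("duplicate SV identifiers")
  rownames(dosage) <- info$id
  if (!is.null(groups)) {
    groups <- groups[colnames(dosage)]
    if (any(is.na(groups))) stop("every sample needs a group label")
  }
  structure(list(dosage = dosage, info = info,
                 samples = colnames(dosage), groups = groups),
            class = "sv_matrix")
}

#' @export
print.sv_matrix <- function(x, ...) {
  cat(sprintf("SV dosage matrix: %d SVs x %d samples\n",
              nrow(x$dosage), ncol(x$dosage)))
  if (!is.null(x$groups)) print(table(x$groups))
  invisible(x)
}

#' @export
`[.sv_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  sv_matrix(x$dosage[i, j, drop = FALSE], x$info[i, , drop = FALSE],
            groups = if (!is.null(x$groups)) x$groups[j])
}
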
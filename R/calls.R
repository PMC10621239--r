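SV_TYPES <- c("DEL", "INS", "DUP", "INV", "TRA")
INTERVAL_TYPES <- c("DEL", "DUP", "INV")
GT_TOKENS <- c("0/0", "0/1", "1/1")

#' Construct a table of caller-level SV calls
#'
#' Internal coordinates are 0-based half-open; \code{start < end} for
#' DEL/DUP/INV with \code{length == end - start}. Insertions are anchored as a
#' 1-bp interval at the insertion point and carry the inserted length.
#' Translocations (TRA) hold both breakends in one record
#' (\code{chrom:start} and \code{mate_chrom:mate_pos}) and have no length.
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive start breakpoints.
#' @param end 0-based exclusive end breakpoints.
#' @param svtype One of DEL, INS, DUP, INV, TRA.
#' @param length SV length in bp (inserted length for INS; NA for TRA).
#' @param caller,sample Caller and sample identifiers.
#' @param genotype Genotype tokens "0/0", "0/1", "1/1"; NA for missing.
#' @param mate_chrom,mate_pos Second breakend, TRA only.
#' @return A \code{data.frame} of class \code{sv_calls}.
#' @export
sv_calls <- function(chrom = character(), start = integer(), end = integer(),
                     svtype = character(), length = NA_real_,
                     caller = NA_character_, sample = NA_character_,
                     genotype = NA_character_,
                     mate_chrom = NA_character_, mate_pos = NA_real_) {
  n <- max(length(chrom), length(start), length(end), length(svtype))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    svtype = rep_len(toupper(as.character(svtype)), n),
    length = rep_len(as.numeric(length), n),
    mate_chrom = rep_len(as.character(mate_chrom), n),
    mate_pos = rep_len(as.numeric(mate_pos), n),
    caller = rep_len(as.character(caller), n),
    sample = rep_len(as.character(sample), n),
    genotype = rep_len(as.character(genotype), n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("sv_calls", "data.frame")
  df
}

#' Normalize raw SV calls
#'
#' Recomputes lengths for interval types (DEL/DUP/INV), canonicalizes the SV
#' type to uppercase, anchors INS records as 1-bp intervals, and maps missing
#' genotype tokens ("./.", ".") to NA. Errors on interval records with
#' \code{end <= start} or unknown SV types.
#'
#' @param calls An \code{sv_calls} data.frame (or compatible data.frame).
#' @return Normalized \code{sv_calls}.
#' @export
normalize_calls <- function(calls) {
  calls <- as.data.frame(calls)
  calls$svtype <- toupper(calls$svtype)
  bad_type <- setdiff(unique(calls$svtype), SV_TYPES)
  if (length(bad_type)) {
    stop("unknown svtype token(s): ", paste(bad_type, collapse = ", "),
         "; allowed: ", paste(SV_TYPES, collapse = ", "))
  }
  iv <- calls$svtype %in% INTERVAL_TYPES
  if (any(iv & calls$end <= calls$start)) {
    i <- which(iv & calls$end <= calls$start)[1]
    stop(sprintf("interval SV with end <= start (record %d: %s:%g-%g)",
                 i, calls$chrom[i], calls$start[i], calls$end[i]))
  }
  calls$length[iv] <- calls$end[iv] - calls$start[iv]
  ins <- calls$svtype == "INS"
  calls$end[ins] <- calls$start[ins] + 1
  calls$length[calls$svtype == "TRA"] <- NA_real_
  gt <- calls$genotype
  gt[gt %in% c("./.", ".", "")] <- NA_character_
  gt <- sub("\\|", "/", gt)
  gt[gt == "1/0"] <- "0/1"
  bad_gt <- !is.na(gt) & !gt %in% GT_TOKENS
  if (any(bad_gt)) {
    stop("unrecognized genotype token(s): ",
         paste(unique(gt[bad_gt]), collapse = ", "))
  }
  calls$genotype <- gt
  tra <- calls$svtype == "TRA"
  if (any(tra & (is.na(calls$mate_chrom) | is.na(calls$mate_pos)))) {
    stop("TRA records must carry mate_chrom and mate_pos")
  }
  class(calls) <- c("sv_calls", "data.frame")
  calls
}

# genotype token -> alt dosage {0,1,2}; NA for missing
gt_dosage <- function(gt) {
  d <- rep(NA_integer_, length(gt))
  d[gt == "0/0"] <- 0L
  d[gt == "0/1"] <- 1L
  d[gt == "1/1"] <- 2L
  d
}

dosage_gt <- function(d) {
  g <- rep(NA_character_, length(d))
  g[!is.na(d) & d == 0] <- "0/0"
  g[!is.na(d) & d == 1] <- "0/1"
  g[!is.na(d) & d == 2] <- "1/1"
  g
}
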
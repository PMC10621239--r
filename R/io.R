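#' Read caller SV output (VCF with symbolic ALT / BND records)
#'
#' Parses a VCF 4.x file as emitted by short-read SV callers: symbolic ALT
#' alleles (\code{<DEL>}, \code{<INS>}, \code{<DUP>}, \code{<INV>}) with
#' \code{END}/\code{SVLEN} INFO keys, and breakend (BND) record pairs which
#' are collapsed into single TRA records (the lower-coordinate breakend is the
#' primary locus). VCF 1-based coordinates are converted to the internal
#' 0-based half-open convention.
#'
#' @param path VCF file path.
#' @param caller Caller identifier stamped on every call.
#' @param sample Sample identifier. If \code{NULL} and the VCF has genotype
#'   columns, one call row is emitted per sample per record using the VCF
#'   sample names.
#' @return An \code{sv_calls} data.frame.
#' @details A symbolic non-INS ALT without an \code{END} key is a record-level
#'   error reporting the offending line number. An unpaired BND record is
#'   skipped with a warning.
#' @export
read_caller_vcf <- function(path, caller = "caller", sample = NULL) {
  lines <- readLines(path)
  hdr <- grepl("^##", lines)
  col_line <- which(grepl("^#CHROM", lines))
  if (length(col_line) != 1) stop("not a VCF: missing #CHROM header line in ", path)
  cols <- strsplit(sub("^#", "", lines[col_line]), "\t", fixed = TRUE)[[1]]
  vcf_samples <- if (length(cols) > 9) cols[10:length(cols)] else character()
  body_idx <- which(!hdr & !grepl("^#", lines) & nzchar(lines))
  body_idx <- body_idx[body_idx > col_line]
  if (!length(body_idx)) return(sv_calls())

  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  n <- length(fields)
  get <- function(i) vapply(fields, function(f) f[i], character(1))
  chrom <- get(1); pos <- as.numeric(get(2)); id <- get(3)
  alt <- get(5); info <- get(8)

  info_key <- function(key) {
    vapply(regmatches(info, gregexpr(paste0("(^|;)", key, "=[^;]+"), info)),
           function(x) if (length(x)) sub(paste0(".*", key, "="), "", x[1]) else NA_character_,
           character(1))
  }
  end_i <- suppressWarnings(as.numeric(info_key("END")))
  svlen <- suppressWarnings(as.numeric(info_key("SVLEN")))
  svtype_i <- info_key("SVTYPE")
  mateid <- info_key("MATEID")

  # genotypes: first FORMAT field must be GT when genotype columns exist
  gt_for <- function(sample_col) {
    if (length(fields[[1]]) < sample_col) return(rep(NA_character_, n))
    vapply(fields, function(f) strsplit(f[sample_col], ":", fixed = TRUE)[[1]][1],
           character(1))
  }

  symbolic <- grepl("^<(DEL|INS|DUP|INV)>$", alt)
  bnd <- grepl("\\[|\\]", alt) | (!is.na(svtype_i) & svtype_i == "BND" & !symbolic)

  build_rows <- function(sel, sample_id, gt) {
    out <- list()
    sym <- sel & symbolic
    if (any(sym)) {
      st <- sub("^<|>$", "", alt[sym]); st <- gsub("[<>]", "", st)
      miss_end <- st != "INS" & is.na(end_i[sym])
      if (any(miss_end)) {
        ln <- body_idx[which(sym)[miss_end][1]]
        stop(sprintf("VCF line %d: symbolic ALT <%s> without END INFO key",
                     ln, st[miss_end][1]))
      }
      start0 <- pos[sym] - 1
      end0 <- end_i[sym]                       # 1-based inclusive == 0-based exclusive
      len <- ifelse(st == "INS", abs(svlen[sym]), end0 - start0)
      end0[st == "INS"] <- start0[st == "INS"] + 1
      out$sym <- sv_calls(chrom[sym], start0, end0, st, len,
                          caller = caller, sample = sample_id, genotype = gt[sym])
    }
    bsel <- sel & bnd
    if (any(bsel)) {
      out$tra <- pair_bnd(chrom[bsel], pos[bsel], alt[bsel], id[bsel],
                          mateid[bsel], gt[bsel], body_idx[bsel],
                          caller, sample_id)
    }
    do.call(rbind, out)
  }

  if (is.null(sample) && length(vcf_samples)) {
    res <- lapply(seq_along(vcf_samples), function(k) {
      build_rows(rep(TRUE, n), vcf_samples[k], gt_for(9 + k))
    })
    calls <- do.call(rbind, res)
  } else {
    if (is.null(sample)) sample <- "sample"
    gt <- if (length(vcf_samples)) gt_for(10) else rep(NA_character_, n)
    calls <- build_rows(rep(TRUE, n), sample, gt)
  }
  if (is.null(calls)) return(sv_calls())
  normalize_calls(calls)
}

# pair BND records into single TRA calls; lower (chrom, pos) breakend primary
pair_bnd <- function(chrom, pos, alt, id, mateid, gt, line_no, caller, sample_id) {
  mate_loc <- vapply(
    regmatches(alt, gregexpr("[\\[\\]]([^\\[\\]:]+):([0-9]+)[\\[\\]]", alt,
                             perl = TRUE)),
    function(x) if (length(x)) gsub("[][]", "", x[1]) else NA_character_,
    character(1))
  mate_chrom <- sub(":.*", "", mate_loc)
  mate_pos <- as.numeric(sub(".*:", "", mate_loc))
  used <- rep(FALSE, length(chrom))
  rows <- list()
  key <- paste(chrom, pos, sep = ":")
  for (i in seq_along(chrom)) {
    if (used[i] || is.na(mate_chrom[i])) next
    # mate: by MATEID if available, else by reciprocal coordinates
    j <- NA_integer_
    if (!is.na(mateid[i])) {
      cand <- which(!used & id == mateid[i])
      if (length(cand)) j <- cand[1]
    }
    if (is.na(j)) {
      cand <- which(!used & chrom == mate_chrom[i] & pos == mate_pos[i] &
                      mate_chrom == chrom[i] & mate_pos == pos[i] &
                      seq_along(chrom) != i)
      if (length(cand)) j <- cand[1]
    }
    if (is.na(j)) {
      warning(sprintf("VCF line %d: unpaired BND record %s skipped",
                      line_no[i], id[i]))
      used[i] <- TRUE
      next
    }
    used[c(i, j)] <- TRUE
    prim <- if (chrom[i] < chrom[j] || (chrom[i] == chrom[j] && pos[i] <= pos[j])) i else j
    sec <- if (prim == i) j else i
    rows[[length(rows) + 1]] <- sv_calls(
      chrom[prim], pos[prim] - 1, pos[prim], "TRA", NA_real_,
      caller = caller, sample = sample_id, genotype = gt[prim],
      mate_chrom = chrom[sec], mate_pos = pos[sec] - 1)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Read SV calls from a generic tab-separated breakpoint table
#'
#' Accepts the simple dialect used for callers without native VCF output:
#' header columns \code{chrom}, \code{start}, \code{end}, \code{svtype} and
#' optionally \code{length}, \code{genotype}, \code{mate_chrom},
#' \code{mate_pos}. Coordinates in the file are 1-based inclusive.
#'
#' @inheritParams read_caller_vcf
#' @return An \code{sv_calls} data.frame.
#' @export
read_caller_table <- function(path, caller = "caller", sample = "sample") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "svtype")
  if (!all(need %in% names(df))) {
    stop("breakpoint table must have columns: ", paste(need, collapse = ", "))
  }
  normalize_calls(sv_calls(
    df$chrom, df$start - 1, df$end, df$svtype,
    length = if ("length" %in% names(df)) df$length else NA_real_,
    caller = caller, sample = sample,
    genotype = if ("genotype" %in% names(df)) df$genotype else NA_character_,
    mate_chrom = if ("mate_chrom" %in% names(df)) df$mate_chrom else NA_character_,
    mate_pos = if ("mate_pos" %in% names(df)) df$mate_pos - 1 else NA_real_))
}

#' Read a curated reference SV table
#'
#' Tab-separated with header columns \code{chrom}, \code{start}, \code{end},
#' \code{svtype}; 1-based inclusive coordinates in the file, converted to the
#' internal 0-based half-open convention and sorted by (chrom, start).
#'
#' @param path File path.
#' @return A data.frame with columns chrom, start, end, svtype, source.
#' @export
read_reference_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("reference SV table is empty: ", path)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      svtype = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  need <- c("chrom", "start", "end", "svtype")
  if (!all(need %in% names(df))) {
    stop("reference table must have columns: ", paste(need, collapse = ", "))
  }
  df$svtype <- toupper(df$svtype)
  bad <- setdiff(unique(df$svtype), SV_TYPES)
  if (length(bad)) {
    stop("unknown svtype token(s) in reference table: ",
         paste(bad, collapse = ", "),
         "; allowed: ", paste(SV_TYPES, collapse = ", "))
  }
  out <- data.frame(chrom = as.character(df$chrom),
                    start = df$start - 1, end = as.numeric(df$end),
                    svtype = df$svtype,
                    source = if ("source" %in% names(df)) df$source else NA_character_,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write merged SVs as a multi-sample VCF
#'
#' Emits symbolic-ALT records with SVTYPE/END/SVLEN INFO keys and per-sample
#' GT fields; TRA records are written as mated BND pairs. Reading the file
#' back with \code{\link{read_caller_vcf}} recovers coordinates, types and
#' genotypes exactly for interval SV types.
#'
#' @param merged A \code{merged_svs} object (see
#'   \code{\link{merge_across_samples}}) or a list with elements \code{svs}
#'   (data.frame chrom/start/end/svtype/length) and \code{gt} (SV x sample
#'   dosage matrix, entries 0/1/2/NA).
#' @param path Output path.
#' @param samples Ordered sample ids; defaults to the matrix column names.
#' @return \code{path}, invisibly.
#' @export
write_merged_vcf <- function(merged, path, samples = colnames(merged$gt)) {
  svs <- merged$svs
  gt <- merged$gt
  if (anyDuplicated(samples)) stop("duplicate sample id in sample list")
  o <- order(svs$chrom, svs$start)
  if (!identical(o, seq_len(nrow(svs)))) {
    stop("merged SVs must be sorted by (chrom, start)")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=svpopkit",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend id\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  lines <- character()
  if (nrow(svs)) {
    gts <- apply(gt, 1, function(d) {
      g <- dosage_gt(d); g[is.na(g)] <- "./."
      paste(g, collapse = "\t")
    })
    ids <- if (!is.null(svs$id)) svs$id else sprintf("SV%05d", seq_len(nrow(svs)))
    for (i in seq_len(nrow(svs))) {
      if (svs$svtype[i] == "TRA") {
        id_a <- paste0(ids[i], "_1"); id_b <- paste0(ids[i], "_2")
        alt_a <- sprintf("N[%s:%d[", svs$mate_chrom[i], svs$mate_pos[i] + 1)
        alt_b <- sprintf("N[%s:%d[", svs$chrom[i], svs$start[i] + 1)
        lines <- c(lines,
          paste(c(svs$chrom[i], svs$start[i] + 1, id_a, "N", alt_a, ".", "PASS",
                  sprintf("SVTYPE=BND;MATEID=%s", id_b), "GT", strsplit(gts[i], "\t")[[1]]),
                collapse = "\t"),
          paste(c(svs$mate_chrom[i], svs$mate_pos[i] + 1, id_b, "N", alt_b, ".", "PASS",
                  sprintf("SVTYPE=BND;MATEID=%s", id_a), "GT", strsplit(gts[i], "\t")[[1]]),
                collapse = "\t"))
      } else {
        slen <- if (svs$svtype[i] == "DEL") -svs$length[i] else svs$length[i]
        info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d",
                        svs$svtype[i], as.integer(svs$end[i]), as.integer(slen))
        lines <- c(lines, paste(c(
          svs$chrom[i], svs$start[i] + 1, ids[i], "N",
          paste0("<", svs$svtype[i], ">"), ".", "PASS", info, "GT",
          strsplit(gts[i], "\t")[[1]]), collapse = "\t"))
      }
    }
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
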
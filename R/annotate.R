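IMPACT_LEVELS <- c("MODIFIER", "LOW", "MODERATE", "HIGH")
CONTEXT_LEVELS <- c("intergenic", "downstream_1kb", "upstream_1kb",
                    "intronic", "exonic")

#' Construct a gene-model set
#'
#' @param genes Data.frame: gene_id, chrom, strand ("+"/"-"), start, end
#'   (0-based half-open transcript span).
#' @param exons Data.frame: gene_id, chrom, start, end (0-based half-open);
#'   per gene, exons must be sorted, non-overlapping, and within the span.
#' @return An object of class \code{gene_models}.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)),
            all(genes$strand %in% c("+", "-")))
  for (g in split(exons, exons$gene_id)) {
    o <- order(g$start)
    if (any(g$start[o][-1] < g$end[o][-nrow(g)])) {
      stop("overlapping exons in gene ", g$gene_id[1])
    }
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Read gene models from a GFF3 file
#'
#' Uses \code{rtracklayer} to import the annotation and extracts gene spans
#' and exon intervals (exons are attached to their gene via the Parent chain
#' or gene_id-style attributes). Coordinates are converted to the internal
#' 0-based half-open convention.
#'
#' @param path GFF3 file path.
#' @return A \code{gene_models} object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  gid <- as.character(md$ID)
  genes <- data.frame(
    gene_id = gid[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene] - 1,
    end = GenomicRanges::end(gr)[is_gene],
    stringsAsFactors = FALSE)
  # map transcripts (mRNA etc.) to genes, then exons to genes via Parent
  parent <- vapply(md$Parent, function(p) if (length(p)) p[1] else NA_character_,
                   character(1))
  tx2gene <- stats::setNames(parent[!is_gene & !is.na(gid)],
                             gid[!is_gene & !is.na(gid)])
  is_exon <- md$type == "exon"
  ex_parent <- parent[is_exon]
  ex_gene <- ifelse(ex_parent %in% genes$gene_id, ex_parent,
                    unname(tx2gene[ex_parent]))
  exons <- data.frame(
    gene_id = ex_gene,
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon] - 1,
    end = GenomicRanges::end(gr)[is_exon],
    stringsAsFactors = FALSE)
  exons <- exons[!is.na(exons$gene_id), , drop = FALSE]
  # collapse duplicate exons from multiple isoforms
  exons <- unique(exons)
  gene_models(genes, exons)
}

# half-open [start, end) -> GRanges (1-based inclusive)
.gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
}

#' Classify the genic context of merged SVs
#'
#' Assigns each SV one category with precedence
#' exonic > intronic > upstream_1kb > downstream_1kb > intergenic, using
#' strand-aware flanks of width \code{cfg$flank} beyond the transcript span
#' (the SnpEff-style "-ud" window). Overlap is any >= 1 bp intersection in
#' half-open arithmetic. TRA records are evaluated at each breakend and the
#' most severe context is kept. Every (SV, gene) contact is also reported so
#' multi-gene SVs record each affected gene.
#'
#' @param svs Data.frame of SVs (\code{merged$svs}): id, chrom, start, end,
#'   svtype, length, and mate fields for TRA.
#' @param genes A \code{gene_models} object.
#' @param cfg An \code{\link{sv_config}}.
#' @return List with \code{sv_table} (id, category, genes) and \code{pairs}
#'   (sv id, gene_id, category per pair).
#' @export
classify_genic_context <- function(svs, genes, cfg = sv_config()) {
  cfg <- as_sv_config(cfg)
  g <- genes$genes
  missing_chrom <- setdiff(unique(svs$chrom), unique(g$chrom))
  if (length(missing_chrom) && nrow(svs)) {
    warning("chromosome(s) absent from annotation, SVs there are intergenic: ",
            paste(missing_chrom, collapse = ", "))
  }
  # evaluation intervals: span for interval SVs, both breakends for TRA
  tra <- svs$svtype == "TRA"
  ev_idx <- c(seq_len(nrow(svs)), which(tra))
  ev_chrom <- c(svs$chrom, svs$mate_chrom[tra])
  ev_start <- c(svs$start, svs$mate_pos[tra])
  ev_end <- c(svs$end, svs$mate_pos[tra] + 1)
  svgr <- .gr(ev_chrom, ev_start, ev_end)

  up_start <- ifelse(g$strand == "+", g$start - cfg$flank, g$end)
  up_end <- ifelse(g$strand == "+", g$start, g$end + cfg$flank)
  dn_start <- ifelse(g$strand == "+", g$end, g$start - cfg$flank)
  dn_end <- ifelse(g$strand == "+", g$end + cfg$flank, g$start)
  layers <- list(
    exonic = .gr(genes$exons$chrom, genes$exons$start, genes$exons$end),
    intronic = .gr(g$chrom, g$start, g$end),
    upstream_1kb = .gr(g$chrom, pmax(up_start, 0), pmax(up_end, 0)),
    downstream_1kb = .gr(g$chrom, pmax(dn_start, 0), pmax(dn_end, 0))
  )
  layer_gene <- list(exonic = genes$exons$gene_id, intronic = g$gene_id,
                     upstream_1kb = g$gene_id, downstream_1kb = g$gene_id)
  pairs <- list()
  for (lay in names(layers)) {
    # suppress the seqlevel-mismatch note when SV and annotation chromosome
    # sets differ (already surfaced as the warning above)
    fo <- suppressWarnings(GenomicRanges::findOverlaps(svgr, layers[[lay]]))
    if (length(fo)) {
      pairs[[lay]] <- data.frame(
        sv = ev_idx[S4Vectors::queryHits(fo)],
        gene_id = layer_gene[[lay]][S4Vectors::subjectHits(fo)],
        category = lay, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(sv = integer(), gene_id = character(), category = character(),
               stringsAsFactors = FALSE)
  # per (sv, gene): keep the most severe category
  if (nrow(pairs)) {
    sev <- match(pairs$category, CONTEXT_LEVELS)
    o <- order(-sev)
    pairs <- pairs[o, , drop = FALSE]
    key <- paste(pairs$sv, pairs$gene_id, sep = "\r")
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  cat_per_sv <- rep("intergenic", nrow(svs))
  genes_per_sv <- rep("", nrow(svs))
  if (nrow(pairs)) {
    sev <- match(pairs$category, CONTEXT_LEVELS)
    best <- tapply(sev, pairs$sv, max)
    cat_per_sv[as.integer(names(best))] <- CONTEXT_LEVELS[best]
    gl <- tapply(pairs$gene_id, pairs$sv, function(x) paste(sort(unique(x)), collapse = ","))
    genes_per_sv[as.integer(names(gl))] <- gl
  }
  ids <- if (!is.null(svs$id)) svs$id else as.character(seq_len(nrow(svs)))
  pairs$sv_id <- ids[pairs$sv]
  list(sv_table = data.frame(id = ids, category = cat_per_sv,
                             genes = genes_per_sv, stringsAsFactors = FALSE),
       pairs = pairs)
}

# impact for one (svtype, category, length) combination
impact_for <- function(svtype, category, length) {
  ifelse(category == "exonic",
         ifelse(svtype == "INS" & !is.na(length) & length %% 3 == 0,
                "MODERATE", "HIGH"),
         ifelse(category == "intronic", "LOW", "MODIFIER"))
}

#' Assign simplified impact classes to annotated SVs
#'
#' Four-level mapping: exonic DEL/DUP/INV/TRA (and frameshift-length exonic
#' INS) are HIGH; in-frame exonic INS (length divisible by 3) are MODERATE;
#' fully intronic SVs are LOW; upstream/downstream/intergenic SVs are
#' MODIFIER. Impact is assigned per (SV, gene) pair; the SV-level class is
#' the maximum over genes.
#'
#' @param svs SV data.frame (as in \code{\link{classify_genic_context}}).
#' @param context Output of \code{\link{classify_genic_context}}.
#' @return \code{context} with an \code{impact} column added to both
#'   \code{sv_table} and \code{pairs}.
#' @export
assign_impact <- function(svs, context) {
  ids <- if (!is.null(svs$id)) svs$id else as.character(seq_len(nrow(svs)))
  st <- svs$svtype[match(context$sv_table$id, ids)]
  ln <- svs$length[match(context$sv_table$id, ids)]
  context$sv_table$impact <- impact_for(st, context$sv_table$category, ln)
  if (nrow(context$pairs)) {
    st_p <- svs$svtype[context$pairs$sv]
    ln_p <- svs$length[context$pairs$sv]
    context$pairs$impact <- impact_for(st_p, context$pairs$category, ln_p)
    # SV-level impact = max severity over its gene pairs
    sev <- match(context$pairs$impact, IMPACT_LEVELS)
    best <- tapply(sev, context$pairs$sv, max)
    idx <- match(ids[as.integer(names(best))], context$sv_table$id)
    context$sv_table$impact[idx] <- IMPACT_LEVELS[best]
  }
  context
}

#' Annotate merged SVs with genic context and impact
#'
#' @param merged A \code{merged_svs} object.
#' @param genes A \code{gene_models} object.
#' @param cfg An \code{\link{sv_config}}.
#' @return List: \code{sv_table} (id, category, impact, genes) and
#'   \code{pairs} (per SV-gene contact).
#' @export
annotate_svs <- function(merged, genes, cfg = sv_config()) {
  ctx <- classify_genic_context(merged$svs, genes, cfg)
  assign_impact(merged$svs, ctx)
}

#' Summarize gene-level and class-level SV impact
#'
#' @param annotation Output of \code{\link{annotate_svs}}.
#' @param genes A \code{gene_models} object.
#' @param svs Optional SV data.frame for per-type counts.
#' @return List: \code{per_gene} (gene x impact count table including
#'   all-zero rows for untouched genes), \code{by_class} (SV counts per
#'   impact class), \code{by_category} (per genic context),
#'   \code{n_genes_affected}.
#' @export
summarize_gene_impacts <- function(annotation, genes, svs = NULL) {
  all_genes <- genes$genes$gene_id
  per_gene <- matrix(0L, length(all_genes), length(IMPACT_LEVELS),
                     dimnames = list(all_genes, IMPACT_LEVELS))
  p <- annotation$pairs
  if (nrow(p)) {
    tab <- table(factor(p$gene_id, levels = all_genes),
                 factor(p$impact, levels = IMPACT_LEVELS))
    per_gene[] <- as.integer(tab)
  }
  by_class <- table(factor(annotation$sv_table$impact, levels = IMPACT_LEVELS))
  by_category <- table(factor(annotation$sv_table$category,
                              levels = CONTEXT_LEVELS))
  list(per_gene = per_gene,
       by_class = by_class,
       by_category = by_category,
       n_genes_affected = sum(rowSums(per_gene) > 0))
}
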
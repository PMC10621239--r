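toy_genes <- function() {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = c("+", "-"),
                      start = c(10000, 20000), end = c(13000, 23000),
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("g1", "g1", "g2"), chrom = "chr1",
                      start = c(10000, 11200, 20000),
                      end = c(10600, 11800, 20500),
                      stringsAsFactors = FALSE)
  gene_models(genes, exons)
}

toy_svs <- function() {
  data.frame(
    id = paste0("SV", 1:7),
    chrom = "chr1",
    start = c(10100, 10700, 9500, 13100, 50000, 10100, 23100),
    end = c(10200, 10800, 9600, 13200, 50100, 10101, 23200),
    svtype = c("DEL", "DEL", "DEL", "DEL", "DEL", "INS", "DEL"),
    length = c(100, 100, 100, 100, 100, 300, 100),
    mate_chrom = NA_character_, mate_pos = NA_real_,
    stringsAsFactors = FALSE)
}

test_that("genic context follows the exonic > intronic > flank precedence", {
  ctx <- classify_genic_context(toy_svs(), toy_genes())
  expect_equal(ctx$sv_table$category,
               c("exonic",        # inside exon 1 of g1
                 "intronic",      # between g1's exons
                 "upstream_1kb",  # 1 kb before the + strand TSS
                 "downstream_1kb",
                 "intergenic",
                 "exonic",
                 "upstream_1kb")) # g2 is - strand: upstream lies after end
  expect_equal(ctx$sv_table$genes[1], "g1")
  expect_equal(ctx$sv_table$genes[7], "g2")
  expect_equal(ctx$sv_table$genes[5], "")
})

test_that("impact classes map from type, context and frame", {
  svs <- toy_svs()
  ann <- assign_impact(svs, classify_genic_context(svs, toy_genes()))
  expect_equal(ann$sv_table$impact,
               c("HIGH", "LOW", "MODIFIER", "MODIFIER", "MODIFIER",
                 "MODERATE",   # exonic in-frame INS (300 %% 3 == 0)
                 "MODIFIER"))
  svs$length[6] <- 301          # frameshift insertion
  ann2 <- assign_impact(svs, classify_genic_context(svs, toy_genes()))
  expect_equal(ann2$sv_table$impact[6], "HIGH")
})

test_that("an SV spanning two genes records both and takes the worst impact", {
  svs <- data.frame(id = "SVx", chrom = "chr1", start = 10000, end = 21000,
                    svtype = "DEL", length = 11000,
                    mate_chrom = NA_character_, mate_pos = NA_real_,
                    stringsAsFactors = FALSE)
  ann <- assign_impact(svs, classify_genic_context(svs, toy_genes()))
  expect_equal(ann$sv_table$genes, "g1,g2")
  expect_equal(ann$sv_table$category, "exonic")
  expect_equal(ann$sv_table$impact, "HIGH")
  expect_equal(sort(ann$pairs$gene_id), c("g1", "g2"))
})

test_that("TRA records are evaluated at both breakends", {
  svs <- data.frame(id = "T1", chrom = "chr1", start = 50000, end = 50001,
                    svtype = "TRA", length = NA_real_,
                    mate_chrom = "chr1", mate_pos = 10100,
                    stringsAsFactors = FALSE)
  ann <- assign_impact(svs, classify_genic_context(svs, toy_genes()))
  expect_equal(ann$sv_table$category, "exonic")  # mate breakend is exonic
  expect_equal(ann$sv_table$impact, "HIGH")
})

test_that("SVs on unannotated chromosomes warn and fall back to intergenic", {
  svs <- toy_svs()[1, ]
  svs$chrom <- "chrZ"
  expect_warning(ctx <- classify_genic_context(svs, toy_genes()), "chrZ")
  expect_equal(ctx$sv_table$category, "intergenic")
})

test_that("gene-level summaries include untouched genes as zero rows", {
  svs <- toy_svs()
  ann <- assign_impact(svs, classify_genic_context(svs, toy_genes()))
  s <- summarize_gene_impacts(ann, toy_genes(), svs)
  expect_equal(rownames(s$per_gene), c("g1", "g2"))
  expect_equal(s$n_genes_affected, 2)
  expect_equal(sum(s$by_class), nrow(svs))
  expect_equal(unname(s$by_category["intergenic"]), 1L)
})

test_that("overlapping exons are rejected at construction", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 0, end = 1000, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = c(0, 100), end = c(200, 300),
                      stringsAsFactors = FALSE)
  expect_error(gene_models(genes, exons), "overlapping exons")
})

test_that("GFF3 gene models round-trip through rtracklayer", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t10001\t13000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t10001\t13000\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t10001\t10600\t.\t+\t.\tID=e1;Parent=t1",
    "chr1\tsrc\texon\t11201\t11800\t.\t+\t.\tID=e2;Parent=t1"), gff)
  gm <- read_gene_models(gff)
  expect_equal(gm$genes$gene_id, "g1")
  expect_equal(gm$genes$start, 10000)   # converted to 0-based
  expect_equal(gm$genes$end, 13000)
  expect_equal(nrow(gm$exons), 2)
  expect_equal(gm$exons$start, c(10000, 11200))
})
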
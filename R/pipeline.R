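#' Run the SV population pipeline end to end
#'
#' Orchestrates the stages ingest/merge -> annotate -> divergence ->
#' structure -> association -> depth-PAV on either supplied inputs or a
#' synthetic cohort, with one configuration object and a fixed seed. Outputs
#' are pure functions of (inputs, config, seed): rerunning with the same
#' arguments reproduces identical tables.
#'
#' @param config Either an \code{\link{sv_config}}, a list of its fields, or
#'   a path to a YAML-like "key = value" text file with those fields
#'   (unknown keys are an error).
#' @param calls Caller-level \code{sv_calls}; if NULL a synthetic cohort is
#'   generated and its caller outputs used.
#' @param groups Named vector sample -> group (required with \code{calls}).
#' @param genes Optional \code{gene_models} for annotation.
#' @param depth_tracks Optional named list of per-sample depth tracks.
#' @param phenotype Optional named trait vector for association.
#' @param seed Seed for the synthetic stages.
#' @param sim Arguments passed to \code{\link{simulate_cohort}} when no calls
#'   are supplied.
#' @param stages Character vector of stages to run (subset of merge,
#'   annotate, divergence, structure, gwas, pav).
#' @param out_dir If non-NULL, result tables are written there as
#'   tab-separated files with a config header comment.
#' @return List: \code{manifest} (config snapshot, seed, stages, versions)
#'   and one element per executed stage.
#' @export
run_pipeline <- function(config = sv_config(), calls = NULL, groups = NULL,
                         genes = NULL, depth_tracks = NULL, phenotype = NULL,
                         seed = 1, sim = list(),
                         stages = c("merge", "annotate", "divergence",
                                    "structure", "gwas", "pav"),
                         out_dir = NULL) {
  if (is.character(config) && length(config) == 1) config <- read_config_file(config)
  cfg <- as_sv_config(config)
  known <- c("merge", "annotate", "divergence", "structure", "gwas", "pav")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))

  truth <- NULL
  if (is.null(calls)) {
    truth <- do.call(simulate_cohort, c(list(seed = seed), sim))
    calls <- simulate_caller_outputs(truth, seed = seed)
    groups <- truth$groups
    if (is.null(genes)) genes <- truth$genes
    if (is.null(depth_tracks) && "pav" %in% stages) {
      depth_tracks <- simulate_depth_tracks(truth, seed = seed)
    }
    if (is.null(phenotype) && "gwas" %in% stages) {
      phenotype <- simulate_phenotypes(truth, seed = seed)
    }
  }
  res <- list(manifest = list(config = unclass(cfg), seed = seed,
                              stages = stages,
                              version = as.character(utils::packageVersion("svpopkit"))),
              truth = truth)

  merged <- merge_sv_calls(calls, cfg, samples = names(groups))
  m <- build_genotype_matrix(merged, groups = groups)
  res$merge <- list(merged = merged, matrix = m)

  if ("annotate" %in% stages) {
    if (is.null(genes)) stop("stage annotate: gene models missing")
    res$annotate <- annotate_svs(merged, genes, cfg)
  }
  filt <- maf_filter(m, cfg)
  if ("divergence" %in% stages) {
    res$divergence <- sv_divergence(filt, cfg = cfg)
  }
  if ("structure" %in% stages || "gwas" %in% stages) {
    K <- suppressWarnings(bn_kinship(filt))
    pca <- pca_from_kinship(K, min(cfg$n_pcs, ncol(filt$dosage)))
    res$structure <- list(kinship = K, pca = pca)
  }
  if ("gwas" %in% stages) {
    if (is.null(phenotype)) stop("stage gwas: phenotype missing")
    res$gwas <- sv_gwas(filt, phenotype, cfg, K = res$structure$kinship)
  }
  if ("pav" %in% stages) {
    if (is.null(depth_tracks)) stop("stage pav: depth tracks missing")
    profs <- lapply(names(depth_tracks), function(s) {
      compute_window_ratios(depth_tracks[[s]], cfg, sample = s)
    })
    names(profs) <- names(depth_tracks)
    dels <- do.call(rbind, lapply(profs, call_depth_deletions, cfg = cfg))
    rownames(dels) <- NULL
    res$pav <- list(profiles = profs, deletions = dels)
  }
  if (!is.null(out_dir)) write_pipeline_tables(res, out_dir, cfg)
  res
}

# "key = value" flat config file
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=")
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2)))
  stats::setNames(as.list(vals), keys)
}

write_pipeline_tables <- function(res, out_dir, cfg) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- paste0("# svpopkit config: ",
                paste(names(cfg), unlist(cfg), sep = "=", collapse = " "))
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  emit(res$merge$merged$svs, "merged_svs")
  if (!is.null(res$annotate)) emit(res$annotate$sv_table, "annotation")
  if (!is.null(res$divergence)) emit(res$divergence, "divergence")
  if (!is.null(res$gwas)) emit(res$gwas$results, "gwas")
  if (!is.null(res$pav)) emit(res$pav$deletions, "pav_deletions")
  invisible(out_dir)
}
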
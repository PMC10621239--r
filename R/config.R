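#' Pipeline configuration
#'
#' Collects every numeric threshold the pipeline uses in one validated list.
#' Defaults are the constants of the published lettuce SV pipeline: 10-bp
#' breakpoint and size tolerances for merging, 2-of-3 caller support, a 10-Mb
#' size cap, 1-kb genic flanks, MAF 0.05, FDR 1e-4 with a 2-fold frequency
#' ratio, 100-kb/10-kb depth windows with a 0.5 depth-ratio cutoff, five
#' principal components, 10-kb/1-marker/r2 0.5 LD pruning, and Bonferroni
#' alpha 0.05.
#'
#' @param max_distance Maximum breakpoint distance (bp) for two calls to link.
#' @param max_size_difference Maximum SV length difference (bp) for linkage.
#' @param min_caller_support Distinct callers required per sample (consensus).
#' @param max_sv_length Interval SVs longer than this (bp) are discarded.
#' @param flank Upstream/downstream genic flank width (bp).
#' @param min_sv_length Minimum SV size (bp); variants below are not SVs.
#' @param maf_min SVs with minor allele frequency below this are filtered out.
#' @param fdr_alpha FDR cutoff for divergence classification.
#' @param freq_ratio_min Minimum between-group allele-frequency fold ratio.
#' @param depth_window Depth window size (bp).
#' @param depth_step Depth window step (bp).
#' @param depth_del_ratio Windows with depth ratio strictly below this are
#'   deletion candidates.
#' @param n_pcs Number of principal components used as GWAS covariates.
#' @param prune_window LD-pruning window (bp).
#' @param prune_step LD-pruning step (markers).
#' @param prune_r2 r-squared threshold above which the later marker is pruned.
#' @param bonferroni_alpha Family-wise error rate for the Bonferroni threshold.
#' @return A list of class \code{sv_config}.
#' @examples
#' cfg <- sv_config()
#' cfg$max_distance
#' @export
sv_config <- function(max_distance = 10,
                      max_size_difference = 10,
                      min_caller_support = 2,
                      max_sv_length = 1e7,
                      flank = 1000,
                      min_sv_length = 50,
                      maf_min = 0.05,
                      fdr_alpha = 1e-4,
                      freq_ratio_min = 2,
                      depth_window = 1e5,
                      depth_step = 1e4,
                      depth_del_ratio = 0.5,
                      n_pcs = 5,
                      prune_window = 1e4,
                      prune_step = 1,
                      prune_r2 = 0.5,
                      bonferroni_alpha = 0.05) {
  cfg <- list(
    max_distance = max_distance,
    max_size_difference = max_size_difference,
    min_caller_support = min_caller_support,
    max_sv_length = max_sv_length,
    flank = flank,
    min_sv_length = min_sv_length,
    maf_min = maf_min,
    fdr_alpha = fdr_alpha,
    freq_ratio_min = freq_ratio_min,
    depth_window = depth_window,
    depth_step = depth_step,
    depth_del_ratio = depth_del_ratio,
    n_pcs = n_pcs,
    prune_window = prune_window,
    prune_step = prune_step,
    prune_r2 = prune_r2,
    bonferroni_alpha = bonferroni_alpha
  )
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) stop("all configuration values must be numeric")
  if (any(unlist(cfg) <= 0)) {
    bad <- names(cfg)[unlist(cfg) <= 0]
    stop("configuration values must be positive: ", paste(bad, collapse = ", "))
  }
  if (cfg$min_caller_support < 1) stop("min_caller_support must be >= 1")
  if (cfg$depth_step > cfg$depth_window) stop("depth_step must be <= depth_window")
  if (cfg$maf_min >= 0.5) stop("maf_min must be in (0, 0.5)")
  structure(cfg, class = "sv_config")
}

#' @export
print.sv_config <- function(x, ...) {
  cat("SV pipeline configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}

# validate a user-supplied config (e.g. from run_pipeline); unknown keys error
as_sv_config <- function(cfg) {
  if (inherits(cfg, "sv_config")) return(cfg)
  if (is.null(cfg)) return(sv_config())
  stopifnot(is.list(cfg))
  known <- names(formals(sv_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(sv_config, cfg)
}
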
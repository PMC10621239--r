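#' Standardized (Balding-Nichols style) kinship matrix
#'
#' K[i,j] = (1/L) * Sum_l (g_il - 2 p_l)(g_jl - 2 p_l) / (2 p_l (1 - p_l))
#' over the L polymorphic SVs, where p_l is the alt-allele frequency.
#' Missing dosages are mean-imputed per SV for this computation only;
#' monomorphic SVs are excluded with a warning.
#'
#' @param m An \code{sv_matrix} (ideally MAF-filtered).
#' @return An n x n symmetric matrix with sample ids as dimnames.
#' @export
bn_kinship <- function(m) {
  d <- t(m$dosage)                      # samples x SVs
  p <- colMeans(d, na.rm = TRUE) / 2
  # mean-impute missing dosages per SV
  if (anyNA(d)) {
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- 2 * p[idx[, 2]]
  }
  # polymorphic = non-constant dosage (p in {0, 1} is constant, but so is an
  # all-heterozygous column with p = 0.5)
  poly <- p > 0 & p < 1 & (colMeans(d^2) - colMeans(d)^2) > 0
  if (any(!poly)) warning(sum(!poly), " monomorphic SV(s) excluded from kinship")
  if (!any(poly)) stop("no polymorphic SVs: cannot compute kinship")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(d, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(z) / ncol(z)
  dimnames(K) <- list(m$samples, m$samples)
  K
}

#' Principal components from a kinship matrix
#'
#' Returns the top eigenvectors of K (descending eigenvalue), each scaled by
#' the square root of its eigenvalue. For reproducibility across numeric
#' backends, each component's sign is fixed so that its largest-magnitude
#' loading is positive.
#'
#' @param K Symmetric kinship matrix.
#' @param n_pcs Number of components (must not exceed nrow(K)).
#' @return List: \code{scores} (n x n_pcs matrix, columns PC1..),
#'   \code{values} (all eigenvalues), \code{vectors} (unscaled eigenvectors
#'   for the kept components).
#' @export
pca_from_kinship <- function(K, n_pcs = 5) {
  n <- nrow(K)
  if (n_pcs > n) stop("n_pcs exceeds the number of samples")
  e <- eigen(K, symmetric = TRUE)
  vec <- e$vectors[, seq_len(n_pcs), drop = FALSE]
  val <- e$values[seq_len(n_pcs)]
  for (k in seq_len(n_pcs)) {
    i <- which.max(abs(vec[, k]))
    if (vec[i, k] < 0) vec[, k] <- -vec[, k]
  }
  scores <- sweep(vec, 2, sqrt(pmax(val, 0)), "*")
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  rownames(scores) <- rownames(K)
  list(scores = scores, values = e$values, vectors = vec)
}

#' Pairwise r-squared between markers
#'
#' Squared Pearson correlation of dosages (complete pairwise observations).
#'
#' @param m An \code{sv_matrix} or dosage matrix (markers x samples).
#' @return Marker x marker r-squared matrix.
#' @export
ld_r2 <- function(m) {
  d <- if (inherits(m, "sv_matrix")) m$dosage else m
  r <- stats::cor(t(d), use = "pairwise.complete.obs")
  r^2
}

#' Window-based LD pruning
#'
#' Markers are scanned in position order; a marker is removed when its
#' dosage r-squared with any retained marker within \code{prune_window} bp
#' upstream exceeds \code{prune_r2} (the later marker of each offending pair
#' is dropped). The window advances one marker at a time.
#'
#' @param m An \code{sv_matrix}; \code{info} must carry chrom and start, and
#'   markers must be position-sorted within chromosome.
#' @param cfg An \code{\link{sv_config}}.
#' @return Character vector of retained marker ids, in input order.
#' @export
ld_prune <- function(m, cfg = sv_config()) {
  cfg <- as_sv_config(cfg)
  info <- m$info
  for (ch in unique(info$chrom)) {
    if (is.unsorted(info$start[info$chrom == ch])) {
      stop("markers must be sorted by position within chromosome")
    }
  }
  d <- m$dosage
  keep <- logical(nrow(d))
  for (ch in unique(info$chrom)) {
    idx <- which(info$chrom == ch)
    kept <- integer(0)
    for (i in idx) {
      win <- kept[info$start[kept] >= info$start[i] - cfg$prune_window]
      drop_i <- FALSE
      if (length(win)) {
        v <- suppressWarnings(
          stats::cor(d[i, ], t(d[win, , drop = FALSE]),
                     use = "pairwise.complete.obs"))
        drop_i <- any(!is.na(v) & v^2 > cfg$prune_r2)
      }
      if (!drop_i) {
        kept <- c(kept, i)
        keep[i] <- TRUE
      }
    }
  }
  m$info$id[keep]
}
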
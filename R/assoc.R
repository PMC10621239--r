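#' Fit the null mixed model (variance components) for association
#'
#' Restricted maximum likelihood for y = X b + u + e with u ~ (0, sg2 K) and
#' e ~ (0, se2 I), profiled over the variance ratio delta = se2/sg2 via the
#' eigendecomposition of K projected off the fixed effects, with a log-grid
#' search over delta in [1e-5, 1e5] refined by local optimization. The fit is
#' deterministic given its inputs and caches the eigendecomposition of K for
#' the genome scan.
#'
#' @param y Trait values (numeric; NAs dropped as complete cases).
#' @param X Covariate matrix including the intercept column (and PCs);
#'   defaults to an intercept-only model.
#' @param K Kinship matrix (samples in the same order as y).
#' @param ridge Small value added to the diagonal if K has eigenvalues below
#'   -1e-8.
#' @return An object of class \code{emmax_null}: delta, h2, sigma_g2,
#'   sigma_e2, beta, the retained sample index, the eigendecomposition of K,
#'   and \code{degenerate} (TRUE when the restricted likelihood is flat in
#'   delta, e.g. K proportional to the identity; the scan then reduces to
#'   ordinary least squares).
#' @export
fit_null_model <- function(y, X = NULL, K, ridge = 1e-6) {
  keep <- which(!is.na(y))
  if (is.null(X)) X <- matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  keep <- keep[stats::complete.cases(X[keep, , drop = FALSE])]
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  K <- K[keep, keep]
  n <- length(y); q <- ncol(X)
  if (stats::var(y) == 0) stop("constant trait: nothing to fit")
  qrX <- qr(X)
  if (qrX$rank < q) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):q]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  eK <- eigen(K, symmetric = TRUE)
  if (min(eK$values) < -1e-8) {
    K <- K + diag(ridge - min(eK$values), n)
    eK <- eigen(K, symmetric = TRUE)
  }
  # eigenvalues/vectors of K projected off X
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  eS <- eigen(S %*% K %*% S, symmetric = TRUE)
  xi <- eS$values[seq_len(n - q)]
  xi[xi < 1e-10] <- 1e-10
  eta <- drop(crossprod(eS$vectors[, seq_len(n - q), drop = FALSE], y))
  restll <- function(log_delta) {
    delta <- exp(log_delta)
    ss <- sum(eta^2 / (xi + delta))
    0.5 * ((n - q) * (log((n - q) / (2 * pi)) - 1 - log(ss)) -
             sum(log(xi + delta)))
  }
  grid <- log(10) * seq(-5, 5, by = 0.1)
  ll <- vapply(grid, restll, numeric(1))
  degenerate <- (max(ll) - min(ll)) < 1e-6
  if (degenerate) {
    delta <- exp(max(grid))
  } else {
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(restll, c(lo, hi), maximum = TRUE, tol = 1e-8)
    delta <- exp(opt$maximum)
  }
  sigma_g2 <- sum(eta^2 / (xi + delta)) / (n - q)
  sigma_e2 <- delta * sigma_g2
  h2 <- 1 / (1 + delta)
  # GLS fixed effects under the fitted V = sigma_g2 (K + delta I)
  w <- 1 / (eK$values + delta)
  Ut <- t(eK$vectors)
  Xs <- Ut %*% X; ys <- drop(Ut %*% y)
  XtVX <- crossprod(Xs, Xs * w)
  beta <- drop(solve(XtVX, crossprod(Xs, ys * w)))
  names(beta) <- colnames(X)
  structure(list(delta = delta, h2 = if (degenerate) 0 else h2,
                 sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, beta = beta,
                 samples = keep, eK = eK, X = X, y = y,
                 degenerate = degenerate),
            class = "emmax_null")
}

#' @export
print.emmax_null <- function(x, ...) {
  cat(sprintf("Mixed-model null fit: n = %d, delta = %.4g, h2 = %.3f%s\n",
              length(x$y), x$delta, x$h2,
              if (x$degenerate) " (flat likelihood: reduces to OLS)" else ""))
  invisible(x)
}

#' @export
#' @method summary emmax_null
summary.emmax_null <- function(object, ...) {
  print(object)
  cat("Fixed effects:\n")
  print(object$beta)
  invisible(object)
}

#' Genome scan with fixed variance components (EMMAX approximation)
#'
#' Tests each marker by generalized least squares of the trait on
#' [covariates, marker] under V = sg2 K + se2 I with the variance components
#' held at their null-model estimates; p-values come from the marker
#' coefficient's F test on (1, n - q - 1) degrees of freedom. Monomorphic
#' markers get a missing p-value.
#'
#' @param m An \code{sv_matrix} (or dosage matrix markers x samples) aligned
#'   to the samples the null model was fitted on (before complete-case
#'   subsetting; the fit's retained index is applied here).
#' @param fit An \code{emmax_null} object.
#' @return Data.frame: id, effect, se, p.
#' @export
emmax_scan <- function(m, fit) {
  G <- if (inherits(m, "sv_matrix")) m$dosage else m
  ids <- if (inherits(m, "sv_matrix")) m$info$id else
    (if (!is.null(rownames(G))) rownames(G) else as.character(seq_len(nrow(G))))
  G <- G[, fit$samples, drop = FALSE]
  G[is.na(G)] <- 0
  n <- length(fit$y); q <- ncol(fit$X)
  w <- 1 / (fit$eK$values + fit$delta)
  sw <- sqrt(w)
  Ut <- t(fit$eK$vectors)
  ys <- drop(Ut %*% fit$y) * sw
  Xs <- (Ut %*% fit$X) * sw
  Gs <- (Ut %*% t(G)) * sw                      # n x markers
  # residualize off the covariates
  qrX <- qr(Xs)
  yr <- qr.resid(qrX, ys)
  Gr <- qr.resid(qrX, Gs)
  gss <- colSums(Gr^2)
  mono <- gss < 1e-12 | apply(G, 1, function(g) stats::var(g) == 0)
  beta <- colSums(Gr * yr) / gss
  rss <- sum(yr^2) - beta^2 * gss
  df2 <- n - q - 1
  fstat <- beta^2 * gss / (rss / df2)
  p <- stats::pf(fstat, 1, df2, lower.tail = FALSE)
  se <- sqrt(rss / df2 / gss)
  beta[mono] <- NA; p[mono] <- NA; se[mono] <- NA
  data.frame(id = ids, effect = beta, se = se, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bonferroni significance threshold
#'
#' @param n_tested Number of markers tested (>= 1).
#' @param cfg An \code{\link{sv_config}} (uses \code{bonferroni_alpha}).
#' @param alpha Family-wise error rate; overrides the config value.
#' @return alpha / n_tested.
#' @export
significance_threshold <- function(n_tested, cfg = sv_config(),
                                   alpha = NULL) {
  cfg <- as_sv_config(cfg)
  if (is.null(alpha)) alpha <- cfg$bonferroni_alpha
  if (alpha <= 0) stop("alpha must be positive")
  if (length(n_tested) != 1 || n_tested < 1) stop("n_tested must be >= 1")
  alpha / n_tested
}

#' Run a mixed-model association study on an SV matrix
#'
#' Convenience wrapper: builds kinship and principal-component covariates,
#' fits the null model, scans all markers, and flags Bonferroni-significant
#' ones. Significant markers within \code{signal_gap} bp on a chromosome are
#' grouped into signals.
#'
#' @param m An \code{sv_matrix}.
#' @param y Named trait vector (sample -> value).
#' @param cfg An \code{\link{sv_config}}.
#' @param K Optional precomputed kinship; defaults to \code{bn_kinship(m)}.
#' @param signal_gap Distance (bp) within which significant SVs merge into
#'   one signal.
#' @return List: \code{results} (scan table with chrom/pos/significant),
#'   \code{fit}, \code{threshold}, \code{signals} (one row per merged signal).
#' @export
sv_gwas <- function(m, y, cfg = sv_config(), K = NULL, signal_gap = 1e6) {
  cfg <- as_sv_config(cfg)
  y <- y[m$samples]
  if (is.null(K)) K <- bn_kinship(m)
  pcs <- pca_from_kinship(K, cfg$n_pcs)$scores
  X <- cbind(intercept = 1, pcs)
  fit <- fit_null_model(y, X, K)
  res <- emmax_scan(m, fit)
  res$chrom <- m$info$chrom
  res$pos <- m$info$start
  thr <- significance_threshold(sum(!is.na(res$p)), cfg)
  res$significant <- !is.na(res$p) & res$p < thr
  sig <- res[res$significant, , drop = FALSE]
  signals <- NULL
  if (nrow(sig)) {
    sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
    new_sig <- c(TRUE, diff(sig$pos) > signal_gap |
                   sig$chrom[-1] != sig$chrom[-nrow(sig)])
    gid <- cumsum(new_sig)
    signals <- do.call(rbind, lapply(split(sig, gid), function(s) {
      data.frame(chrom = s$chrom[1], start = min(s$pos), end = max(s$pos),
                 n_svs = nrow(s), top_id = s$id[which.min(s$p)],
                 top_p = min(s$p), stringsAsFactors = FALSE)
    }))
    rownames(signals) <- NULL
  }
  list(results = res, fit = fit, threshold = thr, signals = signals)
}
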
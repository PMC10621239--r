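#' Default emulated caller noise parameters
#'
#' Three short-read callers with per-caller detection sensitivity, breakpoint
#' jitter (SD of the rounded-Gaussian offset, bp) and false-call rate
#' (expected false calls per true SV per sample). Jitter SDs of 2/3/5 bp keep
#' almost all cross-caller breakpoint offsets within 10 bp, the scale at
#' which concordant multi-caller calls are observed to agree.
#'
#' @return Data.frame: caller, sensitivity, jitter, fcr.
#' @export
default_caller_params <- function() {
  data.frame(caller = c("manta", "delly", "breakdancer"),
             sensitivity = c(0.9, 0.9, 0.9),
             jitter = c(2, 3, 5),
             fcr = c(0.05, 0.05, 0.05),
             stringsAsFactors = FALSE)
}

# non-overlapping synthetic gene models on a grid
simulate_gene_models <- function(genome, gene_every = 2e4, gene_len = 3000,
                                 n_exons = 3) {
  genes <- list(); exons <- list()
  k <- 0
  for (ch in names(genome)) {
    starts <- seq(5000, genome[[ch]] - gene_len - 5000, by = gene_every)
    for (s in starts) {
      k <- k + 1
      gid <- sprintf("gene%05d", k)
      strand <- if (k %% 2 == 0) "+" else "-"
      genes[[k]] <- data.frame(gene_id = gid, chrom = ch, strand = strand,
                               start = s, end = s + gene_len,
                               stringsAsFactors = FALSE)
      ex_w <- floor(gene_len / (2 * n_exons - 1))
      ex_s <- s + (seq_len(n_exons) - 1) * 2 * ex_w
      exons[[k]] <- data.frame(gene_id = gid, chrom = ch,
                               start = ex_s, end = ex_s + ex_w,
                               stringsAsFactors = FALSE)
    }
  }
  gene_models(do.call(rbind, genes), do.call(rbind, exons))
}

#' Simulate a two-population SV cohort with known truth
#'
#' Generates a small diploid cohort emulating a cultivated/wild population
#' pair: per-SV base allele frequencies, a per-SV logit-scale frequency shift
#' of SD \code{divergence} applied with opposite sign in the two groups, and
#' binomial(2, freq) genotypes. SV breakpoints are laid out on a spaced grid
#' so distinct true SVs can never collide under the merge tolerances. A large
#' deletion region (default 600 kb) with group-structured carriers is
#' embedded for the depth stage, and one mid-frequency SV is marked causal
#' for the association stage.
#'
#' @param seed Integer seed; the truth is deterministic given the seed.
#' @param n_per_group Samples per group (length-2 integer).
#' @param n_svs Number of true SVs (> 0).
#' @param divergence SD of the per-SV logit-frequency half-shift between the
#'   groups (0 = identical frequencies).
#' @param genome Named chromosome lengths (bp).
#' @param caller_params See \code{\link{default_caller_params}}.
#' @param group_names Labels for the two populations.
#' @return A \code{cohort_truth} object: genome, genes, svs (with per-group
#'   truth frequencies), geno (SV x sample dosage), samples, groups,
#'   caller_params, causal, deletion (region + per-sample deleted-copy
#'   count).
#' @export
simulate_cohort <- function(seed = 1, n_per_group = c(50, 50), n_svs = 2000,
                            divergence = 0.3,
                            genome = c(chr1 = 5e6, chr2 = 5e6),
                            caller_params = default_caller_params(),
                            group_names = c("sativa", "serriola")) {
  if (n_svs <= 0) stop("n_svs must be positive")
  set.seed(seed)
  samples <- c(sprintf("%s_%03d", group_names[1], seq_len(n_per_group[1])),
               sprintf("%s_%03d", group_names[2], seq_len(n_per_group[2])))
  groups <- stats::setNames(rep(group_names, n_per_group), samples)

  # spaced SV grid: slots far enough apart that tolerances cannot chain
  slot_gap <- 2000
  slots_per_chr <- floor((genome - 2e4) / slot_gap)
  total_slots <- sum(slots_per_chr)
  if (n_svs > total_slots) stop("genome too small for n_svs spaced SVs")
  chr_of <- rep(names(genome), slots_per_chr)
  pos_of <- unlist(lapply(slots_per_chr, function(k) 1e4 + seq_len(k) * slot_gap),
                   use.names = FALSE)
  pick <- sort(sample(total_slots, n_svs))
  svtype <- sample(SV_TYPES, n_svs, replace = TRUE,
                   prob = c(0.5, 0.15, 0.15, 0.1, 0.1))
  len <- round(exp(stats::runif(n_svs, log(50), log(1500))))
  start <- pos_of[pick]
  chrom <- chr_of[pick]
  end <- start + len
  end[svtype == "INS"] <- start[svtype == "INS"] + 1
  mate_chrom <- rep(NA_character_, n_svs)
  mate_pos <- rep(NA_real_, n_svs)
  tra <- svtype == "TRA"
  if (any(tra)) {
    other <- vapply(chrom[tra], function(ch) {
      cand <- setdiff(names(genome), ch)
      if (length(cand)) cand[1] else ch
    }, character(1))
    mate_chrom[tra] <- other
    mate_pos[tra] <- round(stats::runif(sum(tra), 2e4, genome[other] - 2e4))
    end[tra] <- start[tra] + 1
    len[tra] <- NA_real_
  }

  base <- stats::rbeta(n_svs, 0.8, 0.8)
  base <- pmin(pmax(base, 0.02), 0.98)
  shift <- stats::rnorm(n_svs, 0, divergence)
  freq_a <- stats::plogis(stats::qlogis(base) + shift)
  freq_b <- stats::plogis(stats::qlogis(base) - shift)

  geno <- matrix(0L, n_svs, length(samples),
                 dimnames = list(sprintf("TRUE%05d", seq_len(n_svs)), samples))
  ga <- groups == group_names[1]
  geno[, ga] <- stats::rbinom(n_svs * sum(ga), 2, rep(freq_a, sum(ga)))
  geno[, !ga] <- stats::rbinom(n_svs * sum(!ga), 2, rep(freq_b, sum(!ga)))

  svs <- data.frame(id = rownames(geno), chrom = chrom, start = start,
                    end = end, svtype = svtype, length = len,
                    mate_chrom = mate_chrom, mate_pos = mate_pos,
                    freq_a = freq_a, freq_b = freq_b,
                    stringsAsFactors = FALSE)

  # causal SV for association: a mid-frequency non-TRA SV
  maf_true <- pmin(rowMeans(geno) / 2, 1 - rowMeans(geno) / 2)
  cand <- which(!tra & maf_true > 0.2 & maf_true < 0.4)
  causal_id <- if (length(cand)) svs$id[sample(cand, 1)] else svs$id[1]
  causal <- data.frame(id = causal_id, effect = 1, stringsAsFactors = FALSE)

  # embedded 600-kb deletion with group-structured carriers for depth stage
  del_region <- data.frame(chrom = names(genome)[1], start = 2e6, end = 2.6e6,
                           stringsAsFactors = FALSE)
  p_del <- ifelse(ga, 0.4, 0.1)
  del_copies <- stats::rbinom(length(samples), 2, p_del)   # deleted copies
  names(del_copies) <- samples

  genes <- simulate_gene_models(genome)
  structure(list(genome = genome, genes = genes, svs = svs, geno = geno,
                 samples = samples, groups = groups,
                 caller_params = caller_params, causal = causal,
                 deletion = list(region = del_region, copies = del_copies),
                 seed = seed),
            class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples (%s), %d true SVs, seed %d\n",
              length(x$samples),
              paste(table(x$groups), collapse = " + "),
              nrow(x$svs), x$seed))
  invisible(x)
}

#' Simulate per-sample, per-caller SV call sets
#'
#' Each true SV carried by a sample (dosage > 0) is observed by each caller
#' with its sensitivity; observed breakpoints receive independent
#' rounded-Gaussian jitter with the caller's SD. False calls are added per
#' sample and caller at rate \code{fcr} x (number of true SVs); by default
#' each false call is private to one caller, so 2-of-3 consensus removes it.
#'
#' @param truth A \code{cohort_truth}.
#' @param seed Integer seed.
#' @param caller_params Override \code{truth$caller_params}.
#' @param correlated_false If TRUE, false calls are duplicated across all
#'   callers (stress mode).
#' @param write_dir If non-NULL, one single-sample VCF per (sample, caller)
#'   is written there (named SAMPLE.CALLER.vcf) and paths are returned in
#'   \code{attr(, "files")}.
#' @return An \code{sv_calls} data.frame of all caller-level calls.
#' @export
simulate_caller_outputs <- function(truth, seed = 1,
                                    caller_params = truth$caller_params,
                                    correlated_false = FALSE,
                                    write_dir = NULL) {
  set.seed(seed + 1L)
  svs <- truth$svs
  n_svs <- nrow(svs)
  out <- list()
  for (s in truth$samples) {
    carried <- which(truth$geno[, s] > 0)
    sample_false <- NULL
    for (ci in seq_len(nrow(caller_params))) {
      cp <- caller_params[ci, ]
      det <- carried[stats::runif(length(carried)) < cp$sensitivity]
      if (length(det)) {
        j1 <- round(stats::rnorm(length(det), 0, cp$jitter))
        j2 <- round(stats::rnorm(length(det), 0, cp$jitter))
        st <- svs$start[det] + j1
        en <- ifelse(svs$svtype[det] == "INS", st + 1, svs$end[det] + j2)
        ln <- ifelse(svs$svtype[det] == "INS", svs$length[det] + j2, en - st)
        mp <- svs$mate_pos[det] + ifelse(svs$svtype[det] == "TRA", j2, NA)
        tra_d <- svs$svtype[det] == "TRA"
        en[tra_d] <- st[tra_d] + 1
        ln[tra_d] <- NA
        out[[length(out) + 1]] <- sv_calls(
          svs$chrom[det], st, en, svs$svtype[det], ln,
          caller = cp$caller, sample = s,
          genotype = dosage_gt(truth$geno[det, s]),
          mate_chrom = svs$mate_chrom[det], mate_pos = mp)
      }
      n_false <- stats::rpois(1, cp$fcr * n_svs)
      if (n_false > 0) {
        fc <- make_false_calls(truth, n_false, cp$caller, s)
        if (correlated_false) {
          if (is.null(sample_false)) sample_false <- fc
        } else {
          out[[length(out) + 1]] <- fc
        }
      }
    }
    if (correlated_false && !is.null(sample_false)) {
      for (cl in caller_params$caller) {
        dup <- sample_false
        dup$caller <- cl
        out[[length(out) + 1]] <- dup
      }
    }
  }
  calls <- if (length(out)) normalize_calls(do.call(rbind, out)) else sv_calls()
  if (!is.null(write_dir)) {
    dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    for (s in unique(calls$sample)) {
      for (cl in unique(calls$caller)) {
        sub <- calls[calls$sample == s & calls$caller == cl, , drop = FALSE]
        if (!nrow(sub)) next
        sub <- sub[order(sub$chrom, sub$start), , drop = FALSE]
        gt <- matrix(gt_dosage(sub$genotype), ncol = 1,
                     dimnames = list(NULL, s))
        path <- file.path(write_dir, paste0(s, ".", cl, ".vcf"))
        write_merged_vcf(list(svs = sub, gt = gt), path)
        files <- c(files, path)
      }
    }
    attr(calls, "files") <- files
  }
  calls
}

# random false calls avoiding nothing in particular: uniform positions
make_false_calls <- function(truth, n, caller, sample) {
  chrom <- sample(names(truth$genome), n, replace = TRUE)
  st <- floor(stats::runif(n, 1e4, truth$genome[chrom] - 2e4))
  ty <- sample(c("DEL", "INS", "DUP", "INV"), n, replace = TRUE)
  ln <- round(exp(stats::runif(n, log(50), log(1500))))
  en <- ifelse(ty == "INS", st + 1, st + ln)
  sv_calls(chrom, st, en, ty, ln, caller = caller, sample = sample,
           genotype = sample(c("0/1", "1/1"), n, replace = TRUE))
}

#' Simulate per-sample windowed depth tracks
#'
#' Per-sample binned depth (bin = \code{cfg$depth_step}) drawn as
#' Poisson(coverage x bin x copy/2) / bin, where copy number is 2 outside
#' deletions and 2 - deleted copies inside the cohort's embedded deletion
#' region for carrier samples.
#'
#' @param truth A \code{cohort_truth}.
#' @param seed Integer seed.
#' @param coverage Mean sequencing depth.
#' @param cfg An \code{\link{sv_config}} (bin size = depth_step).
#' @param samples Samples to simulate (default all).
#' @return Named list of bedGraph-like data.frames (chrom, start, end, depth).
#' @export
simulate_depth_tracks <- function(truth, seed = 1, coverage = 20,
                                  cfg = sv_config(),
                                  samples = truth$samples) {
  if (coverage <= 0) stop("coverage must be positive")
  cfg <- as_sv_config(cfg)
  set.seed(seed + 2L)
  bin <- cfg$depth_step
  reg <- truth$deletion$region
  tracks <- list()
  for (s in samples) {
    parts <- list()
    for (ch in names(truth$genome)) {
      G <- floor(truth$genome[[ch]] / bin) * bin
      starts <- seq(0, G - bin, by = bin)
      copy <- rep(2, length(starts))
      if (ch == reg$chrom) {
        inside <- starts >= reg$start & starts < reg$end
        copy[inside] <- 2 - truth$deletion$copies[s]
      }
      depth <- stats::rpois(length(starts), coverage * bin * copy / 2) / bin
      parts[[ch]] <- data.frame(chrom = ch, start = starts, end = starts + bin,
                                depth = depth, stringsAsFactors = FALSE)
    }
    tracks[[s]] <- do.call(rbind, parts)
  }
  tracks
}

#' Simulate phenotypes from the cohort truth
#'
#' Quantitative trait y = sum(effect x causal dosage) + u + e with polygenic
#' u ~ MVN(0, h2 K) built from the truth genotypes and e ~ N(0, (1 - h2));
#' the causal effects are in residual-SD units.
#'
#' @param truth A \code{cohort_truth}.
#' @param h2 Polygenic variance fraction in [0, 1].
#' @param causal Data.frame (id, effect); NULL for no causal SV.
#' @param seed Integer seed.
#' @return Named numeric vector of trait values.
#' @export
simulate_phenotypes <- function(truth, h2 = 0.5, causal = truth$causal,
                                seed = 1) {
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  set.seed(seed + 3L)
  n <- length(truth$samples)
  y <- rep(0, n)
  if (!is.null(causal) && nrow(causal)) {
    for (i in seq_len(nrow(causal))) {
      g <- truth$geno[causal$id[i], ]
      y <- y + causal$effect[i] * g
    }
  }
  if (h2 > 0) {
    K <- suppressWarnings(
      bn_kinship(sv_matrix(truth$geno,
                           data.frame(id = rownames(truth$geno)))))
    eK <- eigen(K, symmetric = TRUE)
    u <- eK$vectors %*% (sqrt(pmax(eK$values, 0)) * stats::rnorm(n))
    y <- y + sqrt(h2) * drop(u)
  }
  y <- y + stats::rnorm(n, 0, sqrt(1 - h2))
  stats::setNames(y, truth$samples)
}

#' Assign two phenotype classes from carrier status with penetrance
#'
#' Emulates an incomplete-penetrance pattern: carriers fall in class
#' \code{class1} with probability \code{p1_carrier}, non-carriers with
#' probability \code{p1_noncarrier} (default 0, so class1 contains carriers
#' only).
#'
#' @param carrier Named logical vector: sample -> carrier status.
#' @param p1_carrier P(class1 | carrier).
#' @param p1_noncarrier P(class1 | non-carrier).
#' @param classes Labels (class1, class2).
#' @param seed Integer seed.
#' @return Named character vector of class labels.
#' @export
simulate_penetrance_classes <- function(carrier, p1_carrier = 0.3,
                                        p1_noncarrier = 0,
                                        classes = c("high", "low"),
                                        seed = 1) {
  set.seed(seed + 4L)
  p <- ifelse(carrier, p1_carrier, p1_noncarrier)
  cl <- ifelse(stats::runif(length(carrier)) < p, classes[1], classes[2])
  stats::setNames(cl, names(carrier))
}
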
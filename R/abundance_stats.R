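#' Drop proteins missing in more than a fraction of samples
#'
#' Removes rows whose missing fraction strictly exceeds \code{max_missing}
#' (a protein absent in exactly half the samples is kept at the default).
#'
#' @param m protein x sample matrix with NA for missing.
#' @param max_missing maximum tolerated missing fraction (default 0.5).
#' @return Filtered matrix with attributes n_dropped / n_kept.
#' @export
filter_missingness <- function(m, max_missing = 0.5) {
  frac <- rowMeans(is.na(m))
  keep <- frac <= max_missing
  out <- m[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "n_kept") <- sum(keep)
  out
}

#' Probabilistic quotient normalization
#'
#' The reference profile is the per-protein median across samples (observed
#' values only). Each sample's dilution factor is the median of its
#' quotients against the reference; the sample is divided by that factor.
#' Proteins with an undefined reference are excluded from factor computation
#' but still scaled. A sample sharing no observed protein with the reference
#' gets factor 1 with a warning.
#'
#' @param m raw-scale (positive) protein x sample matrix, NA = missing.
#' @return list: \code{normalized} matrix, \code{factors} per-sample.
#' @export
pqn_normalize <- function(m) {
  stopifnot(ncol(m) >= 2)
  if (any(m[!is.na(m)] <= 0)) stop("raw intensities must be positive")
  ref <- apply(m, 1, stats::median, na.rm = TRUE)
  factors <- vapply(seq_len(ncol(m)), function(j) {
    q <- m[, j] / ref
    q <- q[!is.na(q) & is.finite(q)]
    if (length(q) == 0) {
      warning("sample ", colnames(m)[j] %||% j,
              " has no overlap with the reference; factor set to 1")
      return(1)
    }
    stats::median(q)
  }, numeric(1))
  names(factors) <- colnames(m)
  list(normalized = sweep(m, 2, factors, "/"), factors = factors)
}

#' Left-censored Gibbs imputation of log2 intensities
#'
#' Models each protein's observed log2 values as Normal(m, s^2) under a
#' conjugate normal-inverse-gamma prior (prior mean = observed mean, one
#' pseudo-observation, weakly informative shape/scale anchored at the
#' observed variance). The sampler alternates drawing (m, s^2) from the
#' conjugate posterior given the completed data with drawing each missing
#' cell from Normal(m, s^2) truncated above at its censoring limit: the
#' minimum observed log2 value of that cell's sample (values were censored
#' because they fell below the detection floor). The imputation is the
#' posterior mean over post-burn-in sweeps; the per-cell posterior SD is
#' returned. Deterministic under a fixed seed.
#'
#' @param m log2-scale protein x sample matrix, NA = censored.
#' @param n_iter,burn_in Gibbs sweeps and burn-in (defaults 1000 / 200).
#' @param seed RNG seed.
#' @return list: \code{completed} matrix, \code{sd} (posterior SD of imputed
#'   cells, NA elsewhere), \code{skipped} (rows with < 2 observed values,
#'   left unimputed).
#' @export
impute_left_censored <- function(m, n_iter = 1000L, burn_in = 200L,
                                 seed = 1L) {
  stopifnot(burn_in < n_iter)
  completed <- m
  sdm <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  limits <- apply(m, 2, function(col) {
    if (all(is.na(col))) NA_real_ else min(col, na.rm = TRUE)
  })
  skipped <- character(0)
  with_substream(seed, "impute", {
    for (i in seq_len(nrow(m))) {
      obs <- !is.na(m[i, ])
      miss <- which(!obs)
      if (length(miss) == 0) next
      if (sum(obs) < 2) {
        skipped <- c(skipped, rownames(m)[i] %||% as.character(i))
        next
      }
      yobs <- m[i, obs]
      m0 <- mean(yobs); k0 <- 1; a0 <- 1
      v0 <- stats::var(yobs); if (v0 <= 0) v0 <- 1e-4
      b0 <- v0
      lim <- limits[miss]
      z <- pmin(lim, m0)                     # initial completion
      draws <- matrix(0, n_iter - burn_in, length(miss))
      for (it in seq_len(n_iter)) {
        yy <- c(yobs, z)
        nn <- length(yy)
        ybar <- mean(yy)
        kn <- k0 + nn
        mn <- (k0 * m0 + nn * ybar) / kn
        an <- a0 + nn / 2
        bn <- b0 + 0.5 * sum((yy - ybar)^2) +
          k0 * nn * (ybar - m0)^2 / (2 * kn)
        s2 <- 1 / stats::rgamma(1, an, rate = bn)
        mu <- stats::rnorm(1, mn, sqrt(s2 / kn))
        # truncated-normal draws below each cell's limit
        p_up <- stats::pnorm(lim, mu, sqrt(s2))
        u <- stats::runif(length(miss), 0, pmax(p_up, 1e-12))
        z <- stats::qnorm(pmin(u, 1 - 1e-12), mu, sqrt(s2))
        z <- pmin(z, lim)                    # numeric guard
        if (it > burn_in) draws[it - burn_in, ] <- z
      }
      completed[i, miss] <- colMeans(draws)
      sdm[i, miss] <- apply(draws, 2, stats::sd)
    }
  })
  list(completed = completed, sd = sdm, skipped = skipped)
}

#' Differential abundance between tumor and normal samples
#'
#' Unpaired mode uses a Welch two-sample t statistic on log2 values; paired
#' mode a one-sample t test on within-pair (tumor - normal) differences.
#' The log2 fold change is the tumor mean minus the normal mean (paired:
#' mean pair difference). P values are two-sided and adjusted across all
#' tested proteins by Benjamini-Hochberg. Proteins constant across all
#' samples get p = 1 and are flagged.
#'
#' @param m completed log2 protein x sample matrix.
#' @param design data.frame: sample, condition ("normal"/"tumor"), pair_id.
#' @param paired use the paired contrast (requires complete pairs).
#' @return data.frame: protein_id, log2_fold_change, p_value, q_value,
#'   n_used, flagged_constant.
#' @export
differential_expression <- function(m, design, paired = FALSE) {
  stopifnot(all(design$sample %in% colnames(m)),
            all(c("normal", "tumor") %in% design$condition))
  m <- m[, design$sample, drop = FALSE]
  tum <- design$condition == "tumor"
  if (paired) {
    if (anyNA(design$pair_id)) stop("paired mode requires pair_id")
    pt <- design$pair_id[tum]; pn <- design$pair_id[!tum]
    if (!setequal(pt, pn) || anyDuplicated(pt) || anyDuplicated(pn))
      stop("paired mode requires complete 1:1 pairs")
    ord_n <- match(pt, pn)
  }
  res <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    yt <- m[i, tum]; yn <- m[i, !tum]
    flag <- FALSE
    if (paired) {
      d <- yt - yn[ord_n]
      lfc <- mean(d)
      if (stats::sd(d) == 0) {
        p <- 1; flag <- TRUE
      } else p <- stats::t.test(d)$p.value
      n_used <- length(d)
    } else {
      lfc <- mean(yt) - mean(yn)
      if (stats::sd(c(yt, yn)) == 0) {
        p <- 1; flag <- TRUE
      } else p <- stats::t.test(yt, yn, var.equal = FALSE)$p.value
      n_used <- length(yt) + length(yn)
    }
    data.frame(protein_id = rownames(m)[i] %||% as.character(i),
               log2_fold_change = lfc, p_value = p, n_used = n_used,
               flagged_constant = flag, stringsAsFactors = FALSE)
  }))
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res[, c("protein_id", "log2_fold_change", "p_value", "q_value", "n_used",
          "flagged_constant")]
}

#' Full differential-abundance pipeline
#'
#' filter (> \code{max_missing} missing) -> PQN -> log2 -> left-censored
#' Gibbs imputation -> t contrast -> BH.
#'
#' @param intensities raw protein x sample matrix, NA = missing.
#' @param design sample/condition/pair_id data.frame.
#' @param paired paired contrast flag.
#' @param max_missing missingness filter threshold.
#' @param n_iter,burn_in,seed Gibbs settings.
#' @return list: de (result table), normalized, completed, factors.
#' @export
run_differential_abundance <- function(intensities, design, paired = FALSE,
                                       max_missing = 0.5, n_iter = 1000L,
                                       burn_in = 200L, seed = 1L) {
  filt <- filter_missingness(intensities, max_missing)
  pqn <- pqn_normalize(filt)
  lg <- log2(pqn$normalized)
  imp <- impute_left_censored(lg, n_iter = n_iter, burn_in = burn_in,
                              seed = seed)
  de <- differential_expression(imp$completed, design, paired = paired)
  list(de = de, normalized = pqn$normalized, completed = imp$completed,
       factors = pqn$factors, imputation_sd = imp$sd)
}
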
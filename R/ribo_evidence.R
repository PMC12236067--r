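#' Convert ORF x sample RPF counts to ORF-length TPM
#'
#' Per sample: rate r_ij = c_ij / L_i (ORF length, nt); TPM_ij = 1e6 * r_ij /
#' sum_i r_ij. A sample with no counts yields an all-zero column (flagged in
#' the \code{zero_columns} attribute). The denominator sums over all ORFs in
#' the supplied matrix.
#'
#' @param counts ORF x sample non-negative matrix.
#' @param orf_lengths named vector of ORF lengths (nt), aligned to rows.
#' @return TPM matrix of the same shape.
#' @export
counts_to_tpm <- function(counts, orf_lengths) {
  lens <- orf_lengths[rownames(counts)]
  if (any(is.na(lens)) || any(lens <= 0))
    stop("every ORF needs a positive length")
  if (any(counts < 0)) stop("negative counts")
  r <- counts / lens
  denom <- colSums(r)
  zero <- denom == 0
  denom[zero] <- 1
  tpm <- sweep(r, 2, denom, "/") * 1e6
  attr(tpm, "zero_columns") <- colnames(counts)[zero]
  tpm
}

#' Classify ribosome-occupancy confidence tiers
#'
#' Detection per (ORF, sample) defaults to a nonzero count; an optional
#' logical \code{detection} matrix (e.g. external per-sample translation
#' calls) overrides it. Tier \code{high} requires detection in at least
#' \code{high_min_samples} samples across at least \code{high_min_datasets}
#' datasets with median TPM over detected samples of at least
#' \code{high_min_median_tpm}; otherwise \code{low} requires at least
#' \code{low_min_samples} detections; otherwise \code{none}.
#'
#' @param counts ORF x sample count matrix.
#' @param tpm matching TPM matrix from \code{\link{counts_to_tpm}}.
#' @param sample_to_dataset named character vector (or data.frame with
#'   sample/dataset columns) mapping samples to datasets.
#' @param low_min_samples,high_min_samples,high_min_datasets,high_min_median_tpm
#'   tier thresholds (defaults 20 / 40 / 4 / 1).
#' @param detection optional logical matrix overriding count > 0.
#' @param median_over "detected" (default) or "all" samples.
#' @return data.frame: orf_id, n_detected_samples, n_detected_datasets,
#'   median_detected_tpm, tier.
#' @export
classify_confidence <- function(counts, tpm, sample_to_dataset,
                                low_min_samples = 20L,
                                high_min_samples = 40L,
                                high_min_datasets = 4L,
                                high_min_median_tpm = 1,
                                detection = NULL,
                                median_over = c("detected", "all")) {
  median_over <- match.arg(median_over)
  if (is.data.frame(sample_to_dataset))
    sample_to_dataset <- stats::setNames(sample_to_dataset$dataset,
                                         sample_to_dataset$sample)
  ds <- sample_to_dataset[colnames(counts)]
  if (anyNA(ds)) stop("every sample must map to exactly one dataset")
  if (length(unique(ds)) < high_min_datasets)
    warning("fewer datasets than 'high_min_datasets'; high tier unreachable")
  det <- if (is.null(detection)) counts > 0 else detection
  stopifnot(identical(dim(det), dim(counts)))
  out <- data.frame(orf_id = rownames(counts),
                    n_detected_samples = as.integer(rowSums(det)),
                    n_detected_datasets = vapply(seq_len(nrow(det)), function(i)
                      length(unique(ds[det[i, ]])), integer(1)),
                    stringsAsFactors = FALSE)
  out$median_detected_tpm <- vapply(seq_len(nrow(det)), function(i) {
    sel <- if (median_over == "detected") det[i, ] else rep(TRUE, ncol(det))
    if (!any(sel)) return(NA_real_)
    stats::median(tpm[i, sel])
  }, numeric(1))
  high <- out$n_detected_samples >= high_min_samples &
    out$n_detected_datasets >= high_min_datasets &
    !is.na(out$median_detected_tpm) &
    out$median_detected_tpm >= high_min_median_tpm
  low <- !high & out$n_detected_samples >= low_min_samples
  out$tier <- ifelse(high, "high", ifelse(low, "low", "none"))
  out
}

#' Fit a per-ORF NB2 dispersion model with a library-size offset
#'
#' Maximizes the NB2 likelihood (variance mu(1 + alpha mu)) for one ORF's
#' counts across samples with mean mu_j = rate * T_j, i.e. a log link with
#' offset log(T_j), over (log rate, log alpha). Initialization is by method
#' of moments; when the moment variance does not exceed the mean the
#' dispersion is floored at 1e-8 (Poisson-like). Convergence uses a gradient
#' tolerance of 1e-8 with at most 200 iterations.
#'
#' @param y integer counts across samples.
#' @param library_totals per-sample totals T_j (> 0).
#' @return list of class \code{nb_fit}: rate, alpha, log_likelihood,
#'   converged, zero_fraction, fitted (logical; FALSE for all-zero rows).
#' @export
fit_nb_dispersion <- function(y, library_totals) {
  stopifnot(length(y) == length(library_totals), all(library_totals > 0))
  if (length(y) < 5) stop("need at least 5 samples")
  zf <- mean(y == 0)
  if (all(y == 0))
    return(structure(list(rate = 0, alpha = NA_real_,
                          log_likelihood = NA_real_, converged = NA,
                          zero_fraction = zf, fitted = FALSE),
                     class = "nb_fit"))
  rate0 <- sum(y) / sum(library_totals)
  mu0 <- rate0 * library_totals
  # moment estimate of alpha from the Pearson-type relation
  num <- sum((y - mu0)^2 - mu0)
  den <- sum(mu0^2)
  alpha0 <- if (num > 0) num / den else 1e-8
  alpha0 <- min(max(alpha0, 1e-8), 1e4)
  nll <- function(par) {
    mu <- exp(par[1]) * library_totals
    a <- exp(par[2])
    -sum(stats::dnbinom(y, mu = mu, size = 1 / a, log = TRUE))
  }
  start <- c(log(rate0), log(alpha0))
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(log(rate0) - 20, log(1e-8)),
                      upper = c(log(rate0) + 20, log(1e6)),
                      control = list(maxit = 200, pgtol = 1e-8,
                                     factr = 10))
  structure(list(rate = exp(opt$par[1]), alpha = exp(opt$par[2]),
                 log_likelihood = -opt$value,
                 log_likelihood_start = -nll(start),
                 converged = opt$convergence == 0,
                 zero_fraction = zf, fitted = TRUE),
            class = "nb_fit")
}

#' Fit NB2 dispersion for every ORF in an evidence matrix
#'
#' @param counts ORF x sample count matrix.
#' @param library_totals per-sample totals; column sums when NULL.
#' @return data.frame: orf_id, rate, alpha, log_likelihood, converged,
#'   zero_fraction, fitted.
#' @export
fit_nb_dispersion_all <- function(counts, library_totals = NULL) {
  if (is.null(library_totals)) library_totals <- colSums(counts)
  do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    f <- fit_nb_dispersion(counts[i, ], library_totals)
    data.frame(orf_id = rownames(counts)[i], rate = f$rate, alpha = f$alpha,
               log_likelihood = f$log_likelihood,
               converged = isTRUE(f$converged),
               zero_fraction = f$zero_fraction, fitted = f$fitted,
               stringsAsFactors = FALSE)
  }))
}

#' Summarize dispersion fits by ORF class
#'
#' Quartiles (25/50/75\%) of the fitted dispersion, rate and zero fraction
#' per class (e.g. canonical / high tier / low tier / none), suitable for
#' plotting; empty classes give NA rows.
#'
#' @param fits data.frame from \code{\link{fit_nb_dispersion_all}}.
#' @param classes character vector of class labels aligned to fits rows.
#' @return data.frame with one row per class.
#' @export
summarize_dispersion <- function(fits, classes) {
  stopifnot(nrow(fits) == length(classes))
  qs <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(c(NA_real_, NA_real_, NA_real_))
    unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
  }
  if (length(classes) == 0)
    return(data.frame(class = character(0), n = integer(0)))
  do.call(rbind, lapply(sort(unique(classes)), function(cl) {
    f <- fits[classes == cl & fits$fitted, , drop = FALSE]
    a <- qs(f$alpha); r <- qs(f$rate); z <- qs(f$zero_fraction)
    data.frame(class = cl, n = nrow(f),
               alpha_q1 = a[1], alpha_median = a[2], alpha_q3 = a[3],
               rate_q1 = r[1], rate_median = r[2], rate_q3 = r[3],
               zero_q1 = z[1], zero_median = z[2], zero_q3 = z[3],
               stringsAsFactors = FALSE)
  }))
}
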
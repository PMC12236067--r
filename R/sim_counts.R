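#' Simulate ribosome-footprint count matrices with planted NB structure
#'
#' For each sample j a library total T_j is drawn uniformly from
#' \code{library_size_range}; each ORF i then receives a count from
#' NB2(mean = true_rate_i * length_i * T_j, dispersion = true_alpha_i), i.e.
#' variance mu(1 + alpha * mu). Noise ORFs (is_translated = FALSE) are
#' additionally zeroed with probability \code{zero_inflation_noise},
#' emulating stochastic footprint dropout.
#'
#' @param truth truth table from \code{\link{generate_toy_annotation}}.
#' @param config a \code{\link{sim_config}}.
#' @return A list: \code{counts} (ORF x sample integer matrix),
#'   \code{orf_lengths} (named, nt), \code{samples} (data.frame with sample,
#'   dataset, library_total).
#' @export
simulate_rpf_counts <- function(truth, config) {
  with_substream(config$seed, "rpf_counts", {
    n_samp <- config$n_datasets * config$samples_per_dataset
    samples <- data.frame(
      sample = sprintf("s%03d", seq_len(n_samp)),
      dataset = sprintf("ds%02d", rep(seq_len(config$n_datasets),
                                      each = config$samples_per_dataset)),
      library_total = round(stats::runif(n_samp, config$library_size_range[1],
                                         config$library_size_range[2])),
      stringsAsFactors = FALSE)
    counts <- matrix(0L, nrow(truth), n_samp,
                     dimnames = list(truth$orf_id, samples$sample))
    for (j in seq_len(n_samp)) {
      mu <- truth$true_rate * truth$length_nt * samples$library_total[j]
      counts[, j] <- as.integer(stats::rnbinom(nrow(truth), mu = mu,
                                               size = 1 / truth$true_alpha))
    }
    noise <- !truth$is_translated
    if (any(noise) && config$zero_inflation_noise > 0) {
      drop <- matrix(stats::runif(sum(noise) * n_samp) <
                       config$zero_inflation_noise, sum(noise), n_samp)
      counts[noise, ][drop] <- 0L
    }
    list(counts = counts,
         orf_lengths = stats::setNames(truth$length_nt, truth$orf_id),
         samples = samples)
  })
}

#' Write / read an RPF evidence matrix
#'
#' \code{counts.tsv} has ORF rows and sample columns (first column
#' \code{orf_id}, second \code{length_nt}); \code{samples.tsv} maps samples
#' to datasets and library totals.
#'
#' @param rpf result of \code{\link{simulate_rpf_counts}}.
#' @param dir output directory.
#' @return Paths written (write) / the evidence list (read).
#' @export
write_rpf_counts <- function(rpf, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cp <- file.path(dir, "counts.tsv")
  sp <- file.path(dir, "samples.tsv")
  df <- data.frame(orf_id = rownames(rpf$counts),
                   length_nt = rpf$orf_lengths[rownames(rpf$counts)],
                   rpf$counts, check.names = FALSE)
  write_tsv(df, cp)
  write_tsv(rpf$samples, sp)
  invisible(c(counts = cp, samples = sp))
}

#' @rdname write_rpf_counts
#' @param counts_path,samples_path files written by \code{write_rpf_counts}.
#' @export
read_rpf_counts <- function(counts_path, samples_path) {
  df <- read_tsv(counts_path)
  samples <- read_tsv(samples_path)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$orf_id
  storage.mode(counts) <- "integer"
  list(counts = counts,
       orf_lengths = stats::setNames(df$length_nt, df$orf_id),
       samples = samples)
}
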
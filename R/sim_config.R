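#' Simulation configuration for the synthetic proteogenomic world
#'
#' Bundles every tunable of the synthetic-data generator: the toy
#' transcriptome layout, the negative-binomial ribosome-footprint model, the
#' conservation track, proteomic sampling and the TMT-like intensity matrix.
#' Identical (config, seed) pairs reproduce byte-identical output files.
#'
#' @param seed master integer seed; every artifact draws from a labelled
#'   substream derived from it.
#' @param n_canonical_genes number of canonical protein-coding genes.
#' @param n_sorfs_per_biotype named integer vector over
#'   \code{c("5utr","3utr","lnc_intergenic","lnc_antisense","pseudogene","tec")}.
#' @param fraction_translated fraction of planted sORFs that are genuinely
#'   translated (ribosome-occupied, protein-producing).
#' @param fraction_conserved fraction of planted sORFs evolving under
#'   constraint (conservation track elevated as in canonical CDS).
#' @param n_datasets,samples_per_dataset ribosome-profiling study layout.
#' @param rate_translated,rate_noise expected RPF reads per nucleotide per
#'   total library read for translated and noise ORFs (mean count =
#'   rate * length * library_total).
#' @param alpha_translated,alpha_noise NB2 dispersion (variance mu(1+alpha*mu)).
#' @param zero_inflation_noise extra probability that a noise ORF's count is
#'   zeroed in a sample (stochastic footprint dropout).
#' @param cons_mu_cds,cons_mu_neutral,cons_sigma mean conservation score over
#'   constrained / neutral positions and the per-base normal noise SD
#'   (phyloP-like units).
#' @param cons_sorf_margin planted conserved sORFs are drawn at
#'   \code{cons_mu_cds + cons_sorf_margin}: the score cutoff is the median of
#'   canonical per-gene means, so elements drawn exactly at the canonical
#'   mean would straddle the cutoff; conserved sORFs emulate clearly
#'   constrained elements above the canonical median.
#' @param tmt_effect_size log2 fold-change planted on the differential subset
#'   of the intensity matrix.
#' @param de_fraction fraction of intensity-matrix proteins that are
#'   differential.
#' @param tmt_n_per_group samples per condition in the intensity matrix.
#' @param tmt_sigma residual SD of log2 intensities.
#' @param censor_quantile per-sample quantile below which log2 intensities are
#'   left-censored to missing.
#' @param library_size_range length-2 numeric; per-sample library totals are
#'   drawn uniformly from this interval.
#' @param min_codons minimum planted ORF length in codons (stop excluded).
#' @param sorf_codons_range length-2 integer range for planted sORF lengths.
#' @param n_variants,n_gwas_snps sizes of the simulated variant / GWAS tables.
#' @return An object of class \code{sorf_sim_config}.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_canonical_genes = 5)
sim_config <- function(seed = 1L,
                       n_canonical_genes = 20L,
                       n_sorfs_per_biotype = c("5utr" = 6L, "3utr" = 6L,
                                               "lnc_intergenic" = 8L,
                                               "lnc_antisense" = 6L,
                                               "pseudogene" = 4L, "tec" = 2L),
                       fraction_translated = 0.5,
                       fraction_conserved = 0.5,
                       n_datasets = 6L,
                       samples_per_dataset = 20L,
                       rate_translated = 2e-7,
                       rate_noise = 2e-9,
                       alpha_translated = 0.3,
                       alpha_noise = 2.0,
                       zero_inflation_noise = 0.7,
                       cons_mu_cds = 2.0,
                       cons_mu_neutral = -0.5,
                       cons_sigma = 0.3,
                       cons_sorf_margin = 0.5,
                       tmt_effect_size = 1.0,
                       de_fraction = 0.1,
                       tmt_n_per_group = 10L,
                       tmt_sigma = 0.5,
                       censor_quantile = 0.2,
                       library_size_range = c(5e5, 2e6),
                       min_codons = 30L,
                       sorf_codons_range = c(30L, 80L),
                       n_variants = 200L,
                       n_gwas_snps = 100L) {
  biotypes <- c("5utr", "3utr", "lnc_intergenic", "lnc_antisense",
                "pseudogene", "tec")
  full <- stats::setNames(integer(length(biotypes)), biotypes)
  full[names(n_sorfs_per_biotype)] <- as.integer(n_sorfs_per_biotype)
  cfg <- list(seed = as.integer(seed),
              n_canonical_genes = as.integer(n_canonical_genes),
              n_sorfs_per_biotype = full,
              fraction_translated = fraction_translated,
              fraction_conserved = fraction_conserved,
              n_datasets = as.integer(n_datasets),
              samples_per_dataset = as.integer(samples_per_dataset),
              rate_translated = rate_translated, rate_noise = rate_noise,
              alpha_translated = alpha_translated, alpha_noise = alpha_noise,
              zero_inflation_noise = zero_inflation_noise,
              cons_mu_cds = cons_mu_cds, cons_mu_neutral = cons_mu_neutral,
              cons_sigma = cons_sigma, cons_sorf_margin = cons_sorf_margin,
              tmt_effect_size = tmt_effect_size, de_fraction = de_fraction,
              tmt_n_per_group = as.integer(tmt_n_per_group),
              tmt_sigma = tmt_sigma,
              censor_quantile = censor_quantile,
              library_size_range = library_size_range,
              min_codons = as.integer(min_codons),
              sorf_codons_range = as.integer(sorf_codons_range),
              n_variants = as.integer(n_variants),
              n_gwas_snps = as.integer(n_gwas_snps))
  class(cfg) <- "sorf_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  props <- c("fraction_translated", "fraction_conserved",
             "zero_inflation_noise", "censor_quantile", "de_fraction")
  for (p in props)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", p))
  pos <- c("rate_translated", "rate_noise", "alpha_translated", "alpha_noise",
           "cons_sigma", "tmt_sigma")
  for (p in pos)
    if (cfg[[p]] < 0) stop(sprintf("'%s' must be >= 0", p))
  if (cfg$n_canonical_genes < 1L) stop("'n_canonical_genes' must be >= 1")
  if (any(cfg$n_sorfs_per_biotype < 0L)) stop("sORF counts must be >= 0")
  if (cfg$n_datasets < 1L || cfg$samples_per_dataset < 1L)
    stop("dataset layout counts must be >= 1")
  if (cfg$min_codons < 1L) stop("'min_codons' must be >= 1")
  if (length(cfg$library_size_range) != 2L ||
      any(cfg$library_size_range <= 0) ||
      diff(cfg$library_size_range) < 0)
    stop("'library_size_range' must be an increasing positive interval")
  if (diff(cfg$sorf_codons_range) < 0 ||
      cfg$sorf_codons_range[1] < cfg$min_codons)
    stop("'sorf_codons_range' must start at or above 'min_codons'")
  invisible(cfg)
}

#' @export
print.sorf_sim_config <- function(x, ...) {
  cat("sorfkit simulation config (seed ", x$seed, ")\n", sep = "")
  cat("  canonical genes: ", x$n_canonical_genes, "\n", sep = "")
  cat("  planted sORFs:   ",
      paste(sprintf("%s=%d", names(x$n_sorfs_per_biotype),
                    x$n_sorfs_per_biotype), collapse = ", "), "\n", sep = "")
  cat("  ribo layout:     ", x$n_datasets, " datasets x ",
      x$samples_per_dataset, " samples\n", sep = "")
  invisible(x)
}
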
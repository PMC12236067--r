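# Proteomic-side simulators: PSM tables and TMT-like intensity matrices.

# The simulated proteomic study layout (samples x datasets) for PSM sampling.
PSM_N_SAMPLES <- 20L
PSM_N_DATASETS <- 4L

#' Simulate a peptide-spectrum-match table for planted SEPs
#'
#' Digests each planted SEP in silico (trypsin: cut after K/R unless followed
#' by P), keeps peptides and, per proteomic sample, detects each peptide with
#' probability equal to the SEP's relative abundance; detected peptides get a
#' PSM count of 1 + Poisson and a cross-correlation-like search score. Decoy
#' and contaminant rows are included so downstream filters have something to
#' reject. SEPs with no tryptic peptide of 7-20 aa cannot appear and are
#' recorded in the \code{skipped} attribute.
#'
#' @param truth truth table from \code{\link{generate_toy_annotation}}.
#' @param config a \code{\link{sim_config}}.
#' @return data.frame (peptide, sep_id, sample, dataset, psm_count, score)
#'   with attribute \code{skipped}: SEP ids lacking eligible peptides.
#' @export
simulate_psm_table <- function(truth, config) {
  with_substream(config$seed, "psm", {
    seps <- truth[truth$biotype != "canonical_cds", , drop = FALSE]
    samples <- sprintf("p%02d", seq_len(PSM_N_SAMPLES))
    datasets <- sprintf("pds%02d", rep(seq_len(PSM_N_DATASETS),
                                       length.out = PSM_N_SAMPLES))
    rows <- list()
    skipped <- character(0)
    for (r in seq_len(nrow(seps))) {
      a <- seps$sep_abundance[r]
      peps <- tryptic_digest(seps$protein[r])
      peps <- peps[nchar(peps) >= 7 & nchar(peps) <= 20]
      if (length(peps) == 0) {
        skipped <- c(skipped, seps$orf_id[r])
        next
      }
      if (a <= 0) next
      for (j in seq_along(samples)) {
        hit <- stats::runif(length(peps)) < a
        if (!any(hit)) next
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = peps[hit], sep_id = seps$orf_id[r],
          sample = samples[j], dataset = datasets[j],
          psm_count = 1L + stats::rpois(sum(hit), 2 * a),
          score = round(stats::rnorm(sum(hit), 3.2, 0.5), 3),
          stringsAsFactors = FALSE)
      }
    }
    # decoys and contaminants for filter exercising
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    n_decoy <- 15L
    decoys <- vapply(seq_len(n_decoy), function(i)
      paste(sample(aa, sample(8:14, 1), replace = TRUE), collapse = ""),
      character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = decoys, sep_id = sprintf("DECOY_%03d", seq_len(n_decoy)),
      sample = sample(samples, n_decoy, replace = TRUE),
      dataset = "pds01",
      psm_count = 1L, score = round(stats::rnorm(n_decoy, 1.2, 0.4), 3),
      stringsAsFactors = FALSE)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    out
  })
}

#' Simulate a TMT-like intensity matrix with planted group effects
#'
#' Log2 intensities are Normal(baseline_i + effect, tmt_sigma) with effect
#' \code{tmt_effect_size} added in tumor samples for a designated
#' differential subset; values below each sample's \code{censor_quantile}
#' quantile are left-censored to missing. Raw-scale intensities (2^log2) are
#' returned so the standard pipeline (filter, PQN, log2, impute, test)
#' applies end to end.
#'
#' @param truth truth table; proteins are the canonical CDS entries plus
#'   translated SEPs.
#' @param config a \code{\link{sim_config}}.
#' @param paired generate pair identifiers linking tumor/normal samples.
#' @return list: \code{intensities} (raw protein x sample matrix, NA =
#'   censored), \code{log2_complete} (pre-censoring log2 matrix),
#'   \code{design} (sample, condition, pair_id), \code{de_truth}
#'   (protein_id, is_de, effect).
#' @export
simulate_tmt_matrix <- function(truth, config, paired = TRUE) {
  with_substream(config$seed, "tmt", {
    prots <- truth$orf_id[truth$biotype == "canonical_cds" | truth$is_translated]
    n <- length(prots)
    npg <- config$tmt_n_per_group
    design <- data.frame(
      sample = c(sprintf("n%02d", seq_len(npg)), sprintf("t%02d", seq_len(npg))),
      condition = rep(c("normal", "tumor"), each = npg),
      pair_id = if (paired) rep(sprintf("pair%02d", seq_len(npg)), 2)
                else NA_character_,
      stringsAsFactors = FALSE)
    is_de <- rep(FALSE, n)
    is_de[sample(n, round(config$de_fraction * n))] <- TRUE
    baseline <- stats::rnorm(n, 20, 1.5)
    pair_shift <- if (paired) stats::rnorm(npg, 0, 0.3) else rep(0, npg)
    m <- matrix(0, n, 2 * npg, dimnames = list(prots, design$sample))
    for (j in seq_len(2 * npg)) {
      eff <- if (design$condition[j] == "tumor")
        is_de * config$tmt_effect_size else 0
      m[, j] <- baseline + eff + pair_shift[(j - 1L) %% npg + 1L] +
        stats::rnorm(n, 0, config$tmt_sigma)
    }
    censored <- m
    if (config$censor_quantile > 0) {
      for (j in seq_len(ncol(m))) {
        lim <- stats::quantile(m[, j], config$censor_quantile, type = 7)
        censored[m[, j] < lim, j] <- NA
      }
    }
    list(intensities = 2^censored, log2_complete = m, design = design,
         de_truth = data.frame(protein_id = prots, is_de = is_de,
                               effect = ifelse(is_de, config$tmt_effect_size, 0),
                               stringsAsFactors = FALSE))
  })
}

#' Write simulated proteomic tables
#'
#' @param psms PSM data.frame; \code{tmt} result of
#'   \code{\link{simulate_tmt_matrix}}; \code{truth} the truth table.
#' @param dir output directory.
#' @return Paths written, invisibly.
#' @export
write_proteomics <- function(psms, tmt, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "psms.tsv")
  ip <- file.path(dir, "intensities.tsv")
  dp <- file.path(dir, "design.tsv")
  sp <- file.path(dir, "seps.faa")
  cp <- file.path(dir, "canonical.faa")
  write_tsv(psms, pp)
  idf <- data.frame(protein_id = rownames(tmt$intensities),
                    round(tmt$intensities, 4), check.names = FALSE)
  write_tsv(idf, ip)
  write_tsv(tmt$design, dp)
  seps <- truth[truth$biotype != "canonical_cds", ]
  canon <- truth[truth$biotype == "canonical_cds", ]
  write_protein_fasta(stats::setNames(seps$protein, seps$orf_id), sp)
  write_protein_fasta(stats::setNames(canon$protein, canon$orf_id), cp)
  invisible(c(psms = pp, intensities = ip, design = dp, seps = sp,
              canonical = cp))
}

write_protein_fasta <- function(proteins, path) {
  aas <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

read_protein_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aas), sub("\\s.*$", "", names(aas)))
}
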
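#' Run the full synthetic proteogenomic pipeline
#'
#' Generates every input from a \code{\link{sim_config}}, writes them under
#' \code{out_dir/inputs}, then runs ORFome construction, conservation
#' classification, ribosome-occupancy tiering with NB2 dispersion fits,
#' proteomic evidence aggregation, differential abundance and variant/GWAS
#' overlap, writing all result tables under \code{out_dir/results}. Outputs
#' are byte-deterministic for a fixed (config, seed).
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir output directory.
#' @param fit_dispersion fit the per-ORF NB2 model (the slowest step).
#' @return Invisibly, a list of the in-memory results.
#' @export
run_sorf_pipeline <- function(config = sim_config(), out_dir,
                              fit_dispersion = TRUE) {
  ind <- file.path(out_dir, "inputs")
  res <- file.path(out_dir, "results")
  dir.create(ind, showWarnings = FALSE, recursive = TRUE)
  dir.create(res, showWarnings = FALSE, recursive = TRUE)

  sim <- generate_toy_annotation(config)
  ann_paths <- write_simulated_annotation(sim, ind)
  track <- simulate_conservation_track(sim, config)
  write_track_bedgraph(track, file.path(ind, "conservation.bedgraph"))
  rpf <- simulate_rpf_counts(sim$truth, config)
  write_rpf_counts(rpf, ind)
  psms <- simulate_psm_table(sim$truth, config)
  tmt <- simulate_tmt_matrix(sim$truth, config)
  write_proteomics(psms, tmt, sim$truth, ind)
  vs <- simulate_variants(sim, config)
  write_variants(vs, ind)

  # --- ORFome ------------------------------------------------------------
  transcripts <- load_annotation(ann_paths["gtf"], ann_paths["genome"], "sim")
  ocfg <- orfome_config(min_codons = config$min_codons)
  orfome <- build_orfome(transcripts, ocfg)
  write_orfome(orfome, file.path(res, "orfome"))

  # --- conservation ------------------------------------------------------
  canon_tx <- Filter(function(t) !is.null(t$canonical_cds), transcripts)
  canonical_blocks <- lapply(canon_tx, function(t)
    tx_interval_to_genome(t, t$canonical_cds[1], t$canonical_cds[2]))
  names(canonical_blocks) <- vapply(canon_tx, function(t) t$gene_id,
                                    character(1))
  cons <- conservation_analysis(orfome$orfs, canonical_blocks, track,
                                chrom = names(sim$genome)[1])
  write_tsv(cons$stats, file.path(res, "conservation.tsv"))

  # --- ribosome evidence -------------------------------------------------
  tpm <- counts_to_tpm(rpf$counts, rpf$orf_lengths)
  tiers <- classify_confidence(rpf$counts, tpm, rpf$samples)
  write_tsv(tiers, file.path(res, "tiers.tsv"))
  fits <- NULL
  if (fit_dispersion) {
    fits <- fit_nb_dispersion_all(rpf$counts, rpf$samples$library_total)
    fits$rate <- signif(fits$rate, 8)
    fits$alpha <- signif(fits$alpha, 8)
    fits$log_likelihood <- signif(fits$log_likelihood, 8)
    write_tsv(fits, file.path(res, "nb_fits.tsv"))
    canon_ids <- sim$truth$orf_id[sim$truth$biotype == "canonical_cds"]
    classes <- ifelse(fits$orf_id %in% canon_ids, "canonical",
                      tiers$tier[match(fits$orf_id, tiers$orf_id)])
    disp <- summarize_dispersion(fits, classes)
    num <- vapply(disp, is.numeric, logical(1))
    disp[num] <- lapply(disp[num], signif, 8)
    write_tsv(disp, file.path(res, "dispersion_summary.tsv"))
  }

  # --- proteomic evidence ------------------------------------------------
  reps <- orfome$orfs[orfome$orfs$is_representative &
                        orfome$orfs$biotype != "canonical_cds", ]
  sep_proteins <- stats::setNames(reps$protein, reps$orf_id)
  canon_truth <- sim$truth[sim$truth$biotype == "canonical_cds", ]
  canonical_proteome <- stats::setNames(canon_truth$protein,
                                        canon_truth$orf_id)
  filt <- filter_and_map_peptides(psms, sep_proteins, canonical_proteome)
  evidence <- aggregate_sep_evidence(filt$accepted)
  write_tsv(evidence, file.path(res, "sep_evidence.tsv"))

  # --- differential abundance --------------------------------------------
  de <- run_differential_abundance(tmt$intensities, tmt$design,
                                   paired = TRUE,
                                   seed = substream_seed(config$seed, "de"))
  de_tab <- de$de
  de_tab$log2_fold_change <- signif(de_tab$log2_fold_change, 8)
  de_tab$p_value <- signif(de_tab$p_value, 8)
  de_tab$q_value <- signif(de_tab$q_value, 8)
  write_tsv(de_tab, file.path(res, "differential_abundance.tsv"))

  # --- variants / GWAS ---------------------------------------------------
  ov <- map_variants_to_orfs(vs$variants, orfome$orfs)
  ovf <- apply_score_filters(ov)
  write_tsv(ovf, file.path(res, "variant_overlaps.tsv"))
  gw <- map_gwas_snps(vs$gwas, orfome$orfs)
  gw$best_pvalue <- signif(gw$best_pvalue, 8)
  write_tsv(gw, file.path(res, "gwas_associations.tsv"))

  invisible(list(sim = sim, orfome = orfome, conservation = cons,
                 tpm = tpm, tiers = tiers, nb_fits = fits,
                 sep_evidence = evidence, de = de,
                 variant_overlaps = ovf, gwas = gw))
}
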
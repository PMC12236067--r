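test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(fraction_translated = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_canonical_genes = 0), ">= 1")
  expect_error(sim_config(library_size_range = c(2e6, 5e5)), "interval")
  expect_error(sim_config(sorf_codons_range = c(10, 80)), "min_codons")
})

test_that("planted ORFs round-trip through the emitted FASTA+GTF", {
  ss <- small_sim()
  sim <- ss$sim
  d <- withr::local_tempdir()
  paths <- write_simulated_annotation(sim, d)
  txs <- load_annotation(paths["gtf"], paths["genome"], "sim")
  expect_length(txs, length(sim$transcripts))
  for (r in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[r, ]
    tx <- txs[[tr$transcript_id]]
    sub <- substr(tx$sequence, tr$tx_start + 1, tr$tx_end)
    expect_identical(sub, tr$orf_seq)
    expect_identical(translate_orf(sub), tr$protein)
    gs <- extract_blocks_seq(sim$genome, tr$chrom,
                             blocks_from_string(tr$genomic_blocks),
                             tr$strand)
    expect_identical(gs, tr$orf_seq)
  }
  # every planted sORF starts ATG, ends at a stop, length >= min_codons
  expect_true(all(substr(sim$truth$orf_seq, 1, 3) == "ATG"))
  stops <- substr(sim$truth$orf_seq, sim$truth$length_nt - 2,
                  sim$truth$length_nt)
  expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
  expect_true(all(sim$truth$n_codons >= ss$cfg$min_codons))
  # canonical entries always translated; both strands used
  expect_true(all(sim$truth$is_translated[sim$truth$biotype == "canonical_cds"]))
  expect_setequal(unique(sim$truth$strand), c("+", "-"))
})

test_that("generation is byte-deterministic and empty sORF classes work", {
  cfg <- sim_config(seed = 7, n_canonical_genes = 3,
                    n_sorfs_per_biotype = c("lnc_intergenic" = 2))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_simulated_annotation(generate_toy_annotation(cfg), d1)
  p2 <- write_simulated_annotation(generate_toy_annotation(cfg), d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  cfg0 <- sim_config(seed = 7, n_canonical_genes = 3,
                     n_sorfs_per_biotype = c("lnc_intergenic" = 0))
  sim0 <- generate_toy_annotation(cfg0)
  expect_setequal(unique(sim0$truth$biotype), "canonical_cds")
  expect_equal(nrow(sim0$truth), 3)
})

test_that("a fixed contig that is too small raises a sizing error", {
  cfg <- sim_config(seed = 1, n_canonical_genes = 3,
                    n_sorfs_per_biotype = c("lnc_intergenic" = 2))
  expect_error(generate_toy_annotation(cfg, contig_length = 5000),
               "contig too small")
})

test_that("conservation track has the stated class-conditional means", {
  ss <- small_sim()
  track <- simulate_conservation_track(ss$sim, ss$cfg)
  truth <- ss$sim$truth
  canon <- truth[truth$biotype == "canonical_cds", ]
  cds_scores <- unlist(lapply(seq_len(nrow(canon)), function(r) {
    blk <- blocks_from_string(canon$genomic_blocks[r])
    unlist(lapply(seq_len(nrow(blk)), function(b)
      track[[canon$chrom[r]]][(blk[b, 1] + 1):blk[b, 2]]))
  }))
  expect_gt(length(cds_scores), 4000)
  expect_equal(mean(cds_scores), ss$cfg$cons_mu_cds, tolerance = 0.05)
  # a non-conserved sORF's mean is near the neutral level
  nc <- truth[!truth$is_conserved, ][1, ]
  blk <- blocks_from_string(nc$genomic_blocks)
  v <- unlist(lapply(seq_len(nrow(blk)), function(b)
    track[[nc$chrom]][(blk[b, 1] + 1):blk[b, 2]]))
  expect_equal(mean(v), ss$cfg$cons_mu_neutral, tolerance = 0.15)
  # bedGraph round trip preserves scores (4 dp written)
  d <- withr::local_tempdir()
  path <- write_track_bedgraph(track, file.path(d, "t.bedgraph"))
  back <- read_track_bedgraph(path)
  expect_equal(back[[1]][1:500], track[[1]][1:500], tolerance = 1e-4)
})

test_that("degenerate sigma = 0 gives a piecewise-constant track", {
  cfg <- sim_config(seed = 3, n_canonical_genes = 2,
                    n_sorfs_per_biotype = c("lnc_intergenic" = 2),
                    cons_sigma = 0, fraction_conserved = 0.5)
  sim <- generate_toy_annotation(cfg)
  track <- simulate_conservation_track(sim, cfg)
  vals <- unique(round(track[[1]], 10))
  expect_setequal(vals, c(cfg$cons_mu_neutral,
                          cfg$cons_mu_cds,
                          cfg$cons_mu_cds + cfg$cons_sorf_margin))
})

test_that("RPF counts match the stated NB moments", {
  # constructed truth rows: moment checks at >= 300 draws per cell
  mk_truth <- function(rate, alpha, translated) data.frame(
    orf_id = "o1", biotype = "lnc_intergenic", is_translated = translated,
    true_rate = rate, true_alpha = alpha, length_nt = 300,
    stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 5, n_datasets = 5, samples_per_dataset = 100,
                    library_size_range = c(1e6, 1e6),
                    zero_inflation_noise = 0)
  for (alpha in c(0.1, 1e-8)) {
    tr <- mk_truth(50 / (300 * 1e6), alpha, TRUE)
    rpf <- simulate_rpf_counts(tr, cfg)
    y <- as.numeric(rpf$counts[1, ])
    mu <- 50
    expect_equal(mean(y), mu, tolerance = 3 / mu)      # 50 +- 3
    vband <- mu * (1 + alpha * mu)
    expect_gte(stats::var(y), mu * 0.8)
    expect_lte(stats::var(y), vband * 1.5)
    if (alpha <= 1e-6)
      expect_equal(stats::var(y) / mean(y), 1, tolerance = 0.25)
  }
  # full zero inflation blanks noise ORFs
  cfg0 <- sim_config(seed = 5, n_datasets = 2, samples_per_dataset = 10,
                     zero_inflation_noise = 1)
  tr0 <- mk_truth(1e-6, 0.5, FALSE)
  rpf0 <- simulate_rpf_counts(tr0, cfg0)
  expect_true(all(rpf0$counts == 0))
})

test_that("counts TSV round-trips and samples map to datasets", {
  ss <- small_sim()
  rpf <- simulate_rpf_counts(ss$sim$truth, ss$cfg)
  expect_equal(ncol(rpf$counts), ss$cfg$n_datasets * ss$cfg$samples_per_dataset)
  expect_equal(length(unique(rpf$samples$dataset)), ss$cfg$n_datasets)
  d <- withr::local_tempdir()
  paths <- write_rpf_counts(rpf, d)
  back <- read_rpf_counts(paths["counts"], paths["samples"])
  expect_identical(back$counts, rpf$counts)
  expect_equal(back$samples, rpf$samples)
})

test_that("PSM simulation digests correctly and tracks abundance", {
  # hand-checked tryptic digestion: cut after K/R, never before P
  expect_identical(tryptic_digest("MKTAYIAKQRQISFVK"),
                   c("MK", "TAYIAK", "QR", "QISFVK"))
  expect_identical(tryptic_digest("AKPGGK"), c("AKPGGK"))
  ss <- small_sim()
  psms <- simulate_psm_table(ss$sim$truth, ss$cfg)
  truth <- ss$sim$truth
  zero <- truth$orf_id[truth$sep_abundance == 0 &
                         truth$biotype != "canonical_cds"]
  expect_false(any(psms$sep_id %in% zero))
  # every real PSM peptide is a substring of its SEP
  real <- psms[psms$sep_id %in% truth$orf_id, ]
  ok <- mapply(function(p, id)
    grepl(p, truth$protein[truth$orf_id == id], fixed = TRUE),
    real$peptide, real$sep_id)
  expect_true(all(ok))
  # detection count scales with abundance (binomial check on one SEP)
  abund <- truth[truth$sep_abundance > 0.8 &
                   truth$biotype != "canonical_cds", ]
  if (nrow(abund) > 0) {
    id <- abund$orf_id[1]
    n_det <- length(unique(psms$sample[psms$sep_id == id]))
    p <- abund$sep_abundance[1]
    expect_gte(n_det, round(20 * p) - 6)
  }
  # decoys carry low scores
  expect_lt(mean(psms$score[grepl("^DECOY", psms$sep_id)]),
            mean(psms$score[!grepl("^DECOY", psms$sep_id)]))
})

test_that("TMT matrix plants the effect and censors at the stated rate", {
  ss <- small_sim()
  cfg <- ss$cfg
  tmt <- simulate_tmt_matrix(ss$sim$truth, cfg)
  m <- tmt$log2_complete
  de <- tmt$de_truth$is_de
  tum <- tmt$design$condition == "tumor"
  if (any(de)) {
    diffs <- rowMeans(m[de, tum, drop = FALSE]) -
      rowMeans(m[de, !tum, drop = FALSE])
    expect_equal(mean(diffs), cfg$tmt_effect_size, tolerance = 0.3)
  }
  frac_missing <- mean(is.na(tmt$intensities))
  expect_lt(abs(frac_missing - cfg$censor_quantile), 0.03)
  # boundary: no censoring
  cfg0 <- sim_config(seed = 9, n_canonical_genes = 4, censor_quantile = 0,
                     n_sorfs_per_biotype = c("lnc_intergenic" = 2))
  sim0 <- generate_toy_annotation(cfg0)
  tmt0 <- simulate_tmt_matrix(sim0$truth, cfg0)
  expect_false(anyNA(tmt0$intensities))
})

test_that("variant simulation keeps an exact overlap ledger", {
  ss <- small_sim()
  vs <- simulate_variants(ss$sim, ss$cfg)
  expect_equal(nrow(vs$variants), ss$cfg$n_variants)
  # ledger agrees with direct coordinate arithmetic
  oracle <- oracle_overlaps(vs$variants$pos, ss$sim$truth)
  got <- paste(vs$overlap_truth$row, vs$overlap_truth$orf_id)
  want <- if (is.null(oracle)) character(0) else
    paste(oracle$i, oracle$orf_id)
  expect_setequal(got, want)
  # significance bookkeeping is the stated conjunction
  gt <- vs$gwas_truth
  expect_identical(gt$significant,
                   vs$gwas$study_n[gt$row] >= 10000 &
                     vs$gwas$pvalue[gt$row] <= 5e-8)
  # zero-size request gives empty tables with headers
  cfg0 <- sim_config(seed = 2, n_canonical_genes = 2, n_variants = 0,
                     n_gwas_snps = 0,
                     n_sorfs_per_biotype = c("lnc_intergenic" = 1))
  sim0 <- generate_toy_annotation(cfg0)
  vs0 <- simulate_variants(sim0, cfg0)
  expect_equal(nrow(vs0$variants), 0)
  expect_named(vs0$gwas, c("chrom", "pos", "pvalue", "trait", "study_n"))
})
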
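test_that("enumerate_orfs handles hand-checked cases", {
  cfg <- orfome_config(min_codons = 2)
  res <- enumerate_orfs(plain_tx("ATGAAATAG"), cfg)
  expect_equal(nrow(res), 1)
  expect_equal(res$protein, "MK")
  expect_equal(res$n_codons, 2)
  expect_equal(res$tx_start, 0)
  expect_equal(res$tx_end, 9)
  expect_equal(res$start_codon, "ATG")
  # ATG with no downstream in-frame stop yields nothing
  expect_equal(nrow(enumerate_orfs(plain_tx("ATGAAAAAA"), cfg)), 0)
  # N inside the span rejects the candidate
  expect_equal(nrow(enumerate_orfs(plain_tx("ATGANATAG"), cfg)), 0)
  # nested in-frame ATGs each yield a candidate
  res2 <- enumerate_orfs(plain_tx("ATGATGAAATAG"), cfg)
  expect_equal(nrow(res2), 2)
  expect_setequal(res2$protein, c("MMK", "MK"))
  # too-short sequence: empty list, not an error
  expect_equal(nrow(enumerate_orfs(plain_tx("ATGTAG"),
                                   orfome_config(min_codons = 30))), 0)
})

test_that("enumerate_orfs equals the position-scan oracle on random sequences", {
  set.seed(101)
  cfg <- orfome_config(min_codons = 10)
  for (i in 1:25) {
    seq <- random_tx_seq(600)
    got <- enumerate_orfs(plain_tx(seq), cfg)
    want <- oracle_enumerate(seq, 10)
    key <- function(d) if (is.null(d) || nrow(d) == 0) character(0) else
      paste(d$tx_start, d$tx_end)
    expect_setequal(key(got), key(want))
  }
})

test_that("the 50-nt NMD rule behaves at its boundaries", {
  cfg <- orfome_config()
  two_exon <- new_transcript("t2", "g", "chr1", "+",
                             rbind(c(0, 1000), c(2000, 3000)),
                             random_tx_seq(2000))
  nmd_at <- function(tx_end, tx = two_exon)
    apply_nmd_rule(list(tx_start = 0, tx_end = tx_end), tx, cfg)
  # penultimate exon ends at transcript coordinate 1000
  expect_true(nmd_at(951)$nmd_pass)    # stop 49 nt before the junction
  expect_equal(nmd_at(951)$reason, "near_junction")
  expect_false(nmd_at(949)$nmd_pass)   # 51 nt: NMD target
  expect_equal(nmd_at(949)$reason, "nmd_ptc")
  expect_false(nmd_at(950)$nmd_pass)   # exactly 50 nt: "< 50" is strict
  expect_true(nmd_at(1500)$nmd_pass)   # stop in last exon
  expect_equal(nmd_at(1500)$reason, "last_exon")
  # single-exon transcripts always pass
  single <- plain_tx(random_tx_seq(300))
  r <- apply_nmd_rule(list(tx_start = 0, tx_end = 150), single, cfg)
  expect_true(r$nmd_pass)
  expect_equal(r$reason, "single_exon")
  # 5' UTR exemption: stop 200 nt upstream of the penultimate exon end on an
  # mRNA with annotated CDS
  mrna <- new_transcript("t3", "g", "chr1", "+",
                         rbind(c(0, 1000), c(2000, 3000), c(4000, 5000)),
                         random_tx_seq(3000), canonical_cds = c(1200, 2400))
  ex <- apply_nmd_rule(list(tx_start = 100, tx_end = 800), mrna, cfg)
  expect_true(ex$nmd_pass)
  expect_true(ex$nmd_exempt_5utr)
  expect_equal(ex$reason, "utr5_exempt")
  # same geometry without a CDS fails
  lnc <- new_transcript("t4", "g", "chr1", "+",
                        rbind(c(0, 1000), c(2000, 3000), c(4000, 5000)),
                        random_tx_seq(3000))
  expect_false(apply_nmd_rule(list(tx_start = 100, tx_end = 800), lnc,
                              cfg)$nmd_pass)
})

test_that("NMD is monotone in the window size", {
  set.seed(7)
  tx <- new_transcript("t", "g", "chr1", "+",
                       rbind(c(0, 500), c(1000, 1500), c(2000, 2500)),
                       random_tx_seq(1500))
  for (i in 1:50) {
    tx_end <- sample(60:1500, 1)
    orf <- list(tx_start = 0, tx_end = tx_end)
    narrow <- apply_nmd_rule(orf, tx, orfome_config(nmd_window_nt = 30))
    wide <- apply_nmd_rule(orf, tx, orfome_config(nmd_window_nt = 80))
    if (narrow$nmd_pass) expect_true(wide$nmd_pass)
  }
})

test_that("biotype assignment follows the stated precedence", {
  ss <- small_sim()
  sim <- ss$sim
  ocfg <- orfome_config(min_codons = ss$cfg$min_codons)
  orfome <- build_orfome(sim$transcripts, ocfg)
  planted <- sim$truth[sim$truth$biotype != "canonical_cds", ]
  got <- orfome$orfs$biotype[match(planted$orf_id, orfome$orfs$orf_id)]
  expect_false(anyNA(got))
  expect_identical(got, planted$biotype)
  # canonical CDS ORFs are excluded as non-novel
  canon_ids <- sim$truth$orf_id[sim$truth$biotype == "canonical_cds"]
  expect_true(all(canon_ids %in% orfome$excluded$orf_id))
  expect_true(all(orfome$excluded$reason[
    orfome$excluded$orf_id %in% canon_ids] == "cds_overlap"))
})

test_that("genome projection round-trips on constructed transcripts", {
  # plus strand, single exon starting at genomic 1000
  t1 <- new_transcript("p1", "g", "chr1", "+", cbind(1000, 1600),
                       random_tx_seq(600))
  blk <- map_orf_to_genome(list(tx_start = 30, tx_end = 90), t1)
  expect_equal(unname(blk), cbind(1030, 1090), ignore_attr = TRUE)
  # minus strand single exon [1000, 1200): tx [0,30) -> genomic [1170,1200)
  t2 <- new_transcript("m1", "g", "chr1", "-", cbind(1000, 1200),
                       random_tx_seq(200))
  blk2 <- map_orf_to_genome(list(tx_start = 0, tx_end = 30), t2)
  expect_equal(unname(blk2), cbind(1170, 1200), ignore_attr = TRUE)
  # splice-junction ORF on both strands: re-extraction equals subsequence
  genome_seq <- random_tx_seq(3000)
  genome <- Biostrings::DNAStringSet(c(chr1 = genome_seq))
  for (strand in c("+", "-")) {
    exons <- rbind(c(100, 400), c(900, 1300))
    tx <- new_transcript("s", "g", "chr1", strand, exons,
                         spliced_sequence(genome, "chr1", exons, strand))
    j <- if (strand == "+") 300 else 400   # tx coordinate of the junction
    orf <- list(tx_start = j - 30, tx_end = j + 30)  # spans the junction
    blk <- map_orf_to_genome(orf, tx)
    expect_equal(nrow(blk), 2)
    expect_equal(sum(blk[, 2] - blk[, 1]), 60)
    expect_identical(extract_blocks_seq(genome, "chr1", blk, strand),
                     substr(tx$sequence, j - 29, j + 30))
  }
  expect_error(map_orf_to_genome(list(tx_start = 0, tx_end = 999), t2),
               "bounds")
})

test_that("merging collapses identical chains and drops read-throughs", {
  ss <- small_sim()
  txs <- ss$sim$transcripts
  # catalog B: same chains under different ids and source label
  catB <- lapply(txs, function(t) {
    t$transcript_id <- paste0(t$transcript_id, "_B")
    t$source_catalog <- "B"
    t
  })
  m <- merge_transcriptomes(list(txs, catB))
  expect_equal(length(m$transcripts), length(txs))
  expect_equal(m$n_merged, length(txs))
  expect_true(all(vapply(m$transcripts, function(t)
    setequal(t$source_catalog, c("sim", "B")), logical(1))))
  # a transcript differing by one junction is retained separately
  t_alt <- txs[[1]]
  t_alt$transcript_id <- "alt"
  t_alt$exons[1, 2] <- t_alt$exons[1, 2] - 3
  t_alt$sequence <- substr(t_alt$sequence, 4, nchar(t_alt$sequence))
  m2 <- merge_transcriptomes(list(txs, list(t_alt)))
  expect_equal(length(m2$transcripts), length(txs) + 1)
  # read-through: one exon spanning the CDS of two same-strand genes
  coding <- Filter(function(t) !is.null(t$canonical_cds), txs)
  plus <- Filter(function(t) t$strand == "+", coding)
  g1 <- plus[[1]]; g2 <- plus[[2]]
  lo <- min(g1$exons); hi <- max(g2$exons)
  rt <- new_transcript("readthrough", "rt", g1$chrom, "+",
                       cbind(lo, hi), random_tx_seq(hi - lo))
  m3 <- merge_transcriptomes(list(txs, list(rt)))
  expect_equal(m3$n_readthrough_removed, 1)
  expect_false("readthrough" %in% names(m3$transcripts))
  # malformed exon chain is a validation error naming the transcript
  bad <- txs[[1]]
  bad$exons <- bad$exons[c(2, 1, 3), ]
  expect_error(merge_transcriptomes(list(list(bad))), bad$transcript_id)
})

test_that("identity clustering follows the greedy longest-first contract", {
  # identical pair: one cluster
  cl <- cluster_redundant_seps(c(a = "MKTAYIAKQR", b = "MKTAYIAKQR"))
  expect_equal(sum(cl$is_representative), 1)
  # 2 of 20 mismatches = 90% identity joins at threshold 0.90; 3 of 20 does not
  base <- "MKTAYIAKQRLWSDEFGHCV"
  two <- "MKTAYIAKQRLWSDEFGHAA"    # 2 substitutions
  three <- "MKTAYIAKQRLWSDEFGAAA"  # 3 substitutions
  expect_equal(sum(cluster_redundant_seps(
    c(a = base, b = two), 0.90)$is_representative), 1)
  expect_equal(sum(cluster_redundant_seps(
    c(a = base, b = three), 0.90)$is_representative), 2)
  # unrelated random proteins each found their own cluster, confirmed by a
  # pairwise-identity oracle
  set.seed(11)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  prots <- vapply(1:20, function(i)
    paste(sample(aa, 40, replace = TRUE), collapse = ""), character(1))
  names(prots) <- sprintf("p%02d", 1:20)
  cl3 <- cluster_redundant_seps(prots, 0.90)
  expect_equal(sum(cl3$is_representative), 20)
  # representative is the longest member; every input maps to one cluster
  mix <- c(long = paste0(base, "AAAAA"), short = base)
  cl4 <- cluster_redundant_seps(mix, 0.5)
  expect_identical(cl4$cluster, rep("long", 2))
  expect_equal(nrow(cl4), 2)
  # monotonic: representative count non-increasing as threshold drops
  n_hi <- sum(cluster_redundant_seps(c(a = base, b = two), 0.95)$is_representative)
  n_lo <- sum(cluster_redundant_seps(c(a = base, b = two), 0.85)$is_representative)
  expect_gte(n_hi, n_lo)
})
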
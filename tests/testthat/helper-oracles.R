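# Independent brute-force oracles and shared fixtures. The oracles
# deliberately share no code with the implementation paths they check.

# Position-scan ORF oracle: try every position for ATG, walk codon by codon
# to the first stop.
oracle_enumerate <- function(seq, min_codons) {
  n <- nchar(seq)
  out <- NULL
  for (p in seq_len(max(n - 2, 0))) {
    if (substr(seq, p, p + 2) != "ATG") next
    q <- p
    found <- FALSE
    while (q + 2 <= n) {
      codon <- substr(seq, q, q + 2)
      if (codon %in% c("TAA", "TAG", "TGA") && q > p) {
        found <- TRUE
        break
      }
      q <- q + 3
    }
    if (!found) next
    n_codons <- (q - p) / 3
    if (n_codons < min_codons) next
    span <- substr(seq, p, q + 2)
    if (grepl("N", span, fixed = TRUE)) next
    out <- rbind(out, data.frame(tx_start = p - 1L, tx_end = q + 2L,
                                 n_codons = n_codons))
  }
  out
}

# Double-loop Hamming-window oracle.
oracle_min_mismatch <- function(pep, proteome) {
  k <- nchar(pep)
  pv <- strsplit(pep, "")[[1]]
  best <- k
  for (prot in proteome) {
    n <- nchar(prot)
    if (n < k) next
    sv <- strsplit(prot, "")[[1]]
    for (s in 0:(n - k)) {
      d <- sum(sv[(s + 1):(s + k)] != pv)
      if (d < best) best <- d
    }
  }
  best
}

# Double-loop variant-vs-blocks overlap oracle (pos is 1-based).
oracle_overlaps <- function(positions, orf_tbl) {
  hits <- NULL
  for (i in seq_along(positions)) {
    p0 <- positions[i] - 1
    for (r in seq_len(nrow(orf_tbl))) {
      blk <- blocks_from_string(orf_tbl$genomic_blocks[r])
      if (any(p0 >= blk[, 1] & p0 < blk[, 2]))
        hits <- rbind(hits, data.frame(i = i, orf_id = orf_tbl$orf_id[r],
                                       stringsAsFactors = FALSE))
    }
  }
  hits
}

random_tx_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                          replace = TRUE), collapse = "")

# Single-exon transcript wrapper for enumeration tests.
plain_tx <- function(seq, id = "t1") {
  new_transcript(id, "g1", "chr1", "+", cbind(0, nchar(seq)), seq,
                 annotation_biotype = "lncRNA")
}

# A small simulated world, built once per test run.
.sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- sim_config(seed = 42, n_canonical_genes = 8,
                      n_sorfs_per_biotype = c("5utr" = 3, "3utr" = 3,
                                              "lnc_intergenic" = 4,
                                              "lnc_antisense" = 3,
                                              "pseudogene" = 2, "tec" = 1))
    .sim_cache$cfg <- cfg
    .sim_cache$sim <- generate_toy_annotation(cfg)
  }
  list(sim = .sim_cache$sim, cfg = .sim_cache$cfg)
}
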
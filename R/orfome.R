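#' ORFome construction configuration
#'
#' @param min_codons minimum ORF length in codons, stop excluded (default 30).
#' @param require_atg only AUG-initiated ORFs (default TRUE; no alternative
#'   start codons are supported).
#' @param apply_nmd apply the 50-nt NMD rule filter (default TRUE).
#' @param nmd_window_nt stop codons within this many nt of the penultimate
#'   exon's 3' end escape NMD (default 50).
#' @param cluster_identity global-identity threshold for redundancy
#'   clustering (default 0.90).
#' @return list of class \code{orfome_config}.
#' @export
orfome_config <- function(min_codons = 30L, require_atg = TRUE,
                          apply_nmd = TRUE, nmd_window_nt = 50L,
                          cluster_identity = 0.90) {
  stopifnot(min_codons >= 1, cluster_identity > 0, cluster_identity <= 1,
            nmd_window_nt >= 0, isTRUE(require_atg))
  structure(list(min_codons = as.integer(min_codons), require_atg = TRUE,
                 apply_nmd = apply_nmd,
                 nmd_window_nt = as.integer(nmd_window_nt),
                 cluster_identity = cluster_identity),
            class = "orfome_config")
}

#' Merge transcript catalogs and remove read-through transcripts
#'
#' Transcripts identical in (chrom, strand, exon chain) across catalogs are
#' collapsed to one record keeping all source labels; the identifier from the
#' earliest catalog wins. Read-through transcripts, whose exon chain overlaps
#' the canonical CDS of two or more distinct genes on the same strand, are
#' removed (the CDS reference is taken from the merged set's own
#' CDS-annotated transcripts).
#'
#' @param catalogs list of transcript sets (each a named list of
#'   \code{sorf_transcript}); each catalog's transcripts should carry its
#'   source label.
#' @return list: \code{transcripts} (merged named list), \code{n_merged},
#'   \code{n_readthrough_removed}.
#' @export
merge_transcriptomes <- function(catalogs) {
  stopifnot(length(catalogs) >= 1)
  merged <- list()
  keys <- character(0)
  n_merged <- 0L
  for (cat_i in seq_along(catalogs)) {
    for (tx in catalogs[[cat_i]]) {
      validate_transcript(tx)
      key <- paste(tx$chrom, tx$strand,
                   paste(tx$exons[, 1], tx$exons[, 2], sep = "-",
                         collapse = ","), sep = "|")
      hit <- match(key, keys)
      if (is.na(hit)) {
        keys <- c(keys, key)
        merged[[tx$transcript_id]] <- tx
      } else {
        n_merged <- n_merged + 1L
        keep <- merged[[hit]]
        keep$source_catalog <- union(keep$source_catalog, tx$source_catalog)
        if (!is.null(tx$canonical_cds) && is.null(keep$canonical_cds))
          keep$canonical_cds <- tx$canonical_cds
        merged[[hit]] <- keep
      }
    }
  }
  # read-through: exon chain overlapping CDS blocks of >= 2 distinct genes,
  # same strand
  cds_tbl <- NULL
  for (tx in merged) {
    if (is.null(tx$canonical_cds)) next
    blk <- tx_interval_to_genome(tx, tx$canonical_cds[1], tx$canonical_cds[2])
    cds_tbl <- rbind(cds_tbl, data.frame(
      gene_id = tx$gene_id, chrom = tx$chrom, strand = tx$strand,
      start = blk[, 1], end = blk[, 2], stringsAsFactors = FALSE))
  }
  is_readthrough <- function(tx) {
    if (is.null(cds_tbl)) return(FALSE)
    cand <- cds_tbl[cds_tbl$chrom == tx$chrom & cds_tbl$strand == tx$strand, ]
    if (nrow(cand) == 0) return(FALSE)
    hit_genes <- character(0)
    for (e in seq_len(nrow(tx$exons))) {
      ov <- cand$start < tx$exons[e, 2] & cand$end > tx$exons[e, 1]
      hit_genes <- union(hit_genes, cand$gene_id[ov])
    }
    length(hit_genes) >= 2
  }
  rt <- vapply(merged, is_readthrough, logical(1))
  list(transcripts = merged[!rt], n_merged = n_merged,
       n_readthrough_removed = sum(rt))
}

#' Enumerate AUG-initiated ORFs in three reading frames
#'
#' Scans every reading frame of the spliced transcript sequence; each ATG
#' opening a run to the next in-frame stop codon yields a candidate when the
#' ORF is at least \code{min_codons} codons long (stop excluded). Nested
#' in-frame ATGs each yield their own candidate (redundancy is resolved later
#' by clustering). ORFs whose span contains an ambiguous base (N) are
#' rejected; ATGs with no downstream in-frame stop yield nothing.
#'
#' @param tx a \code{sorf_transcript}.
#' @param cfg an \code{\link{orfome_config}}.
#' @return data.frame of candidates: orf_id, transcript_id, frame, tx_start,
#'   tx_end (0-based half-open, stop codon included), n_codons, start_codon,
#'   protein.
#' @export
enumerate_orfs <- function(tx, cfg = orfome_config()) {
  s <- tx$sequence
  n <- nchar(s)
  empty <- data.frame(orf_id = character(0), transcript_id = character(0),
                      frame = integer(0), tx_start = integer(0),
                      tx_end = integer(0), n_codons = integer(0),
                      start_codon = character(0), protein = character(0),
                      stringsAsFactors = FALSE)
  if (n < 3 * (cfg$min_codons + 1L)) return(empty)
  if (!grepl("^[ACGTN]*$", s))
    stop("transcript ", tx$transcript_id, ": sequence alphabet must be ACGTN")
  out <- list()
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    atg_i <- which(codons == "ATG")
    stop_i <- which(codons %in% STOP_CODONS)
    if (length(atg_i) == 0 || length(stop_i) == 0) next
    has_n <- grepl("N", codons, fixed = TRUE)
    for (i in atg_i) {
      j <- stop_i[stop_i > i]
      if (length(j) == 0) next
      j <- j[1]
      n_codons <- j - i
      if (n_codons < cfg$min_codons) next
      if (any(has_n[i:j])) next
      tx_start <- starts[i] - 1L           # back to 0-based
      tx_end <- starts[j] + 2L
      protein <- paste(Biostrings::GENETIC_CODE[codons[i:(j - 1L)]],
                       collapse = "")
      out[[length(out) + 1L]] <- data.frame(
        orf_id = orf_identifier(tx$transcript_id, frame, tx_start),
        transcript_id = tx$transcript_id, frame = frame,
        tx_start = tx_start, tx_end = tx_end, n_codons = n_codons,
        start_codon = "ATG", protein = protein, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$tx_start, res$frame), ]
}

#' Apply the 50-nt nonsense-mediated-decay rule
#'
#' An ORF escapes NMD when its stop codon's last base lies in the transcript's
#' last exon, or in the penultimate exon within \code{nmd_window_nt} of that
#' exon's 3' end (transcript orientation), or when the ORF lies entirely
#' within the 5' UTR of a transcript with an annotated canonical CDS (the
#' upstream-ORF exemption). Single-exon transcripts always pass.
#'
#' @param orf one candidate row from \code{\link{enumerate_orfs}} (or any
#'   list with \code{tx_start}/\code{tx_end}).
#' @param tx the owning \code{sorf_transcript}.
#' @param cfg an \code{\link{orfome_config}}.
#' @return list(nmd_pass, reason, nmd_exempt_5utr). Reasons: "single_exon",
#'   "last_exon", "near_junction", "utr5_exempt", "nmd_ptc".
#' @export
apply_nmd_rule <- function(orf, tx, cfg = orfome_config()) {
  if (orf$tx_end > tx_length(tx) || orf$tx_start < 0)
    stop("ORF outside transcript bounds")
  lens <- tx_exon_lengths(tx)
  k <- length(lens)
  if (k == 1L)
    return(list(nmd_pass = TRUE, reason = "single_exon",
                nmd_exempt_5utr = FALSE))
  offs <- cumsum(lens)                  # tx coords of exon 3' ends
  stop_last <- orf$tx_end - 1           # 0-based position of stop's last base
  last_junction <- offs[k - 1L]
  if (stop_last >= last_junction)
    return(list(nmd_pass = TRUE, reason = "last_exon",
                nmd_exempt_5utr = FALSE))
  in_penultimate <- k == 2L || stop_last >= offs[k - 2L]
  d <- last_junction - orf$tx_end       # nt between stop end and junction
  if (in_penultimate && d < cfg$nmd_window_nt)
    return(list(nmd_pass = TRUE, reason = "near_junction",
                nmd_exempt_5utr = FALSE))
  if (!is.null(tx$canonical_cds) && orf$tx_end <= tx$canonical_cds[1])
    return(list(nmd_pass = TRUE, reason = "utr5_exempt",
                nmd_exempt_5utr = TRUE))
  list(nmd_pass = FALSE, reason = "nmd_ptc", nmd_exempt_5utr = FALSE)
}

#' Assign an ORF biotype from transcript annotation and genomic position
#'
#' Precedence (first match wins): (1) on an mRNA entirely 5' of the canonical
#' CDS start: \code{5utr}; (2) entirely 3' of the CDS end: \code{3utr};
#' (3) transcript annotated pseudogene; (4) transcript annotated TEC;
#' (5) non-coding transcript whose genomic span overlaps a canonical gene on
#' the opposite strand: \code{lnc_antisense}; (6) otherwise
#' \code{lnc_intergenic}. Any ORF overlapping its own transcript's canonical
#' CDS is excluded as non-novel (reason \code{cds_overlap}).
#'
#' @param orf a candidate row.
#' @param tx the owning transcript.
#' @param gene_spans data.frame of canonical genes: gene_id, chrom, strand,
#'   start, end (0-based half-open span).
#' @return list(biotype or NA, excluded, reason).
#' @export
assign_biotype <- function(orf, tx, gene_spans) {
  if (!is.null(tx$canonical_cds)) {
    cds <- tx$canonical_cds
    if (orf$tx_end <= cds[1])
      return(list(biotype = "5utr", excluded = FALSE, reason = ""))
    if (orf$tx_start >= cds[2])
      return(list(biotype = "3utr", excluded = FALSE, reason = ""))
    return(list(biotype = NA_character_, excluded = TRUE,
                reason = "cds_overlap"))
  }
  bt <- toupper(tx$annotation_biotype)
  if (grepl("PSEUDOGENE", bt))
    return(list(biotype = "pseudogene", excluded = FALSE, reason = ""))
  if (bt == "TEC")
    return(list(biotype = "tec", excluded = FALSE, reason = ""))
  span <- c(min(tx$exons[, 1]), max(tx$exons[, 2]))
  opp <- gene_spans$chrom == tx$chrom & gene_spans$strand != tx$strand &
    gene_spans$start < span[2] & gene_spans$end > span[1]
  if (any(opp))
    return(list(biotype = "lnc_antisense", excluded = FALSE, reason = ""))
  list(biotype = "lnc_intergenic", excluded = FALSE, reason = "")
}

#' Project an ORF onto genomic blocks
#'
#' Thin wrapper over \code{\link{tx_interval_to_genome}} for a candidate row.
#'
#' @param orf candidate row with tx_start/tx_end.
#' @param tx owning transcript.
#' @return genomic block matrix, 0-based half-open, sorted by start.
#' @export
map_orf_to_genome <- function(orf, tx) {
  tx_interval_to_genome(tx, orf$tx_start, orf$tx_end)
}

#' Cluster redundant SEPs by global sequence identity
#'
#' Greedy clustering in order of decreasing length (ties broken by
#' identifier): each protein joins the first existing cluster whose
#' representative aligns at or above the identity threshold, otherwise founds
#' its own cluster. Identity is matches / alignment length (gap columns
#' included) under a global alignment with unit match score, zero mismatch
#' and zero gap penalties. The representative is the longest member (the
#' founder, by construction).
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param identity threshold in (0, 1].
#' @return data.frame: id, cluster (representative's id), is_representative.
#' @export
cluster_redundant_seps <- function(proteins, identity = 0.90) {
  if (length(proteins) == 0)
    return(data.frame(id = character(0), cluster = character(0),
                      is_representative = logical(0)))
  stopifnot(!is.null(names(proteins)), identity > 0, identity <= 1)
  ord <- order(-nchar(proteins), names(proteins))
  proteins <- proteins[ord]
  reps <- character(0)
  assign_to <- character(length(proteins))
  for (i in seq_along(proteins)) {
    placed <- FALSE
    for (r in reps) {
      if (global_identity(proteins[[i]], proteins[[r]]) >= identity) {
        assign_to[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, names(proteins)[i])
      assign_to[i] <- names(proteins)[i]
    }
  }
  data.frame(id = names(proteins), cluster = assign_to,
             is_representative = names(proteins) == assign_to,
             stringsAsFactors = FALSE)
}

# Global alignment identity = matches / alignment length including gap
# columns, with match = 1 and mismatch/gap = 0 scoring.
global_identity <- function(a, b) {
  if (a == b) return(1)
  alphabet <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]], "X"))
  mat <- matrix(0L, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- 1L
  # unit match score, zero mismatch score; the infinitesimal gap cost only
  # breaks ties toward the compact alignment and cannot change the match count
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 1e-4)
  Biostrings::nmatch(al) / Biostrings::nchar(al)
}

#' Build the candidate ORFome from an annotated transcript set
#'
#' Runs enumeration, NMD filtering, biotype assignment, genome projection and
#' redundancy clustering over every transcript, returning the ORF table and
#' the representative SEP set.
#'
#' @param transcripts named list of \code{sorf_transcript}.
#' @param cfg an \code{\link{orfome_config}}.
#' @return list: \code{orfs} (data.frame with coordinates, biotype, NMD flag,
#'   genomic blocks, protein, cluster assignment), \code{excluded}
#'   (data.frame of dropped candidates with reasons), \code{clusters},
#'   \code{gene_spans}.
#' @export
build_orfome <- function(transcripts, cfg = orfome_config()) {
  gene_spans <- NULL
  for (tx in transcripts) {
    if (is.null(tx$canonical_cds)) next
    gene_spans <- rbind(gene_spans, data.frame(
      gene_id = tx$gene_id, chrom = tx$chrom, strand = tx$strand,
      start = min(tx$exons[, 1]), end = max(tx$exons[, 2]),
      stringsAsFactors = FALSE))
  }
  if (is.null(gene_spans))
    gene_spans <- data.frame(gene_id = character(0), chrom = character(0),
                             strand = character(0), start = numeric(0),
                             end = numeric(0))
  rows <- list()
  excl <- list()
  for (tx in transcripts) {
    cand <- enumerate_orfs(tx, cfg)
    for (i in seq_len(nrow(cand))) {
      orf <- cand[i, ]
      bt <- assign_biotype(orf, tx, gene_spans)
      if (bt$excluded) {
        excl[[length(excl) + 1L]] <- data.frame(
          orf_id = orf$orf_id, reason = bt$reason, stringsAsFactors = FALSE)
        next
      }
      nmd <- apply_nmd_rule(orf, tx, cfg)
      if (cfg$apply_nmd && !nmd$nmd_pass) {
        excl[[length(excl) + 1L]] <- data.frame(
          orf_id = orf$orf_id, reason = nmd$reason, stringsAsFactors = FALSE)
        next
      }
      blk <- map_orf_to_genome(orf, tx)
      orf$biotype <- bt$biotype
      orf$nmd_pass <- nmd$nmd_pass
      orf$nmd_reason <- nmd$reason
      orf$nmd_exempt_5utr <- nmd$nmd_exempt_5utr
      orf$chrom <- tx$chrom
      orf$strand <- tx$strand
      orf$genomic_blocks <- blocks_to_string(blk)
      rows[[length(rows) + 1L]] <- orf
    }
  }
  orfs <- if (length(rows)) do.call(rbind, rows) else NULL
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(orf_id = character(0), reason = character(0))
  clusters <- NULL
  if (!is.null(orfs)) {
    clusters <- cluster_redundant_seps(
      stats::setNames(orfs$protein, orfs$orf_id), cfg$cluster_identity)
    orfs$cluster <- clusters$cluster[match(orfs$orf_id, clusters$id)]
    orfs$is_representative <- clusters$is_representative[
      match(orfs$orf_id, clusters$id)]
    rownames(orfs) <- NULL
  }
  list(orfs = orfs, excluded = excluded, clusters = clusters,
       gene_spans = gene_spans)
}

#' Write ORFome outputs: ORF table, SEP FASTA and BED12
#'
#' The SEP FASTA contains representative sequences with headers
#' \code{orf_id|biotype|n_codons}; the BED12 encodes each ORF's genomic block
#' structure (0-based half-open, thickStart/thickEnd spanning the ORF).
#'
#' @param orfome result of \code{\link{build_orfome}}.
#' @param prefix output path prefix.
#' @return Paths written, invisibly.
#' @export
write_orfome <- function(orfome, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  tp <- paste0(prefix, "_orfs.tsv")
  fp <- paste0(prefix, "_seps.faa")
  bp <- paste0(prefix, "_orfs.bed")
  write_tsv(orfome$orfs, tp)
  reps <- orfome$orfs[orfome$orfs$is_representative, ]
  hdr <- sprintf("%s|%s|%d", reps$orf_id, reps$biotype, reps$n_codons)
  write_protein_fasta(stats::setNames(reps$protein, hdr), fp)
  bed <- do.call(rbind, lapply(seq_len(nrow(orfome$orfs)), function(i) {
    o <- orfome$orfs[i, ]
    blk <- blocks_from_string(o$genomic_blocks)
    data.frame(chrom = o$chrom, start = min(blk[, 1]), end = max(blk[, 2]),
               name = o$orf_id, score = 0L, strand = o$strand,
               thickStart = min(blk[, 1]), thickEnd = max(blk[, 2]),
               itemRgb = "0,0,0", blockCount = nrow(blk),
               blockSizes = paste0(paste(blk[, 2] - blk[, 1], collapse = ","), ","),
               blockStarts = paste0(paste(blk[, 1] - min(blk[, 1]), collapse = ","), ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(bed, bp, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(orfs = tp, seps = fp, bed = bp))
}
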
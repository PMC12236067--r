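# Variant positions follow VCF convention (1-based); ORF blocks are 0-based
# half-open. Conversion is centralized here.
variant_pos0 <- function(pos) pos - 1L

# ORF block table (orf_id, chrom, strand, genomic_blocks string) -> GRanges
# with one range per block.
orf_blocks_granges <- function(orfs) {
  rows <- do.call(rbind, lapply(seq_len(nrow(orfs)), function(i) {
    blk <- blocks_from_string(orfs$genomic_blocks[i])
    data.frame(chrom = orfs$chrom[i], start = blk[, 1], end = blk[, 2],
               orf_id = orfs$orf_id[i], stringsAsFactors = FALSE)
  }))
  GenomicRanges::GRanges(rows$chrom,
                         IRanges::IRanges(rows$start + 1L, rows$end),
                         orf_id = rows$orf_id)
}

#' Map single-nucleotide variants onto ORF genomic blocks
#'
#' A variant overlaps an ORF iff its 0-based position falls inside any of the
#' ORF's blocks (half-open: a variant at a block's end coordinate does not
#' overlap). All (variant, ORF) pairs are emitted; indels and multi-allelic
#' records are rejected with a counted warning.
#'
#' @param variants data.frame: chrom, pos (1-based), ref, alt, plus optional
#'   source/fathmm/cadd columns carried through.
#' @param orfs ORF table with orf_id, chrom, genomic_blocks columns.
#' @return data.frame of overlap pairs (variant columns + orf_id), with a
#'   \code{per_source_counts} attribute when a source column is present.
#' @export
map_variants_to_orfs <- function(variants, orfs) {
  keep <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    !grepl(",", variants$alt, fixed = TRUE)
  if (any(!keep))
    warning(sum(!keep), " indel/multi-allelic record(s) rejected")
  variants <- variants[keep, , drop = FALSE]
  empty <- cbind(variants[0, , drop = FALSE],
                 data.frame(orf_id = character(0)))
  if (nrow(variants) == 0 || nrow(orfs) == 0) return(empty)
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, width = 1L))
  ogr <- orf_blocks_granges(orfs)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(vgr, ogr, ignore.strand = TRUE))
  if (length(hits) == 0) return(empty)
  out <- cbind(variants[S4Vectors::queryHits(hits), , drop = FALSE],
               data.frame(orf_id =
                 S4Vectors::mcols(ogr)$orf_id[S4Vectors::subjectHits(hits)],
                 stringsAsFactors = FALSE))
  out <- unique(out)
  rownames(out) <- NULL
  if ("source" %in% names(out))
    attr(out, "per_source_counts") <-
      table(unique(out[, c("source", "orf_id")])$source)
  out
}

#' Apply pathogenicity-score filters to variant-ORF overlaps
#'
#' COSMIC records are kept only when their FATHMM-MKL functional score is
#' strictly greater than \code{fathmm_min}; records from other sources (or
#' lacking the score) pass through with a provenance note. Every retained
#' record is flagged deleterious when its CADD Phred score is strictly
#' greater than \code{cadd_min}; records without a CADD score are left
#' unflagged.
#'
#' @param overlaps data.frame from \code{\link{map_variants_to_orfs}} with
#'   source, fathmm, cadd columns.
#' @param fathmm_min,cadd_min thresholds (defaults 0.7 and 15).
#' @return Filtered data.frame with added \code{deleterious} and
#'   \code{score_note} columns.
#' @export
apply_score_filters <- function(overlaps, fathmm_min = 0.7, cadd_min = 15) {
  is_cosmic <- overlaps$source == "cosmic"
  has_fathmm <- !is.na(overlaps$fathmm)
  keep <- !is_cosmic | (has_fathmm & overlaps$fathmm > fathmm_min)
  keep[is_cosmic & !has_fathmm] <- TRUE
  out <- overlaps[keep, , drop = FALSE]
  has_cadd <- !is.na(out$cadd)
  out$deleterious <- has_cadd & out$cadd > cadd_min
  out$score_note <- ifelse(!has_cadd & !(out$source == "cosmic" &
                                           !is.na(out$fathmm)),
                           "score_missing", "")
  out$score_note[out$source == "cosmic" & is.na(out$fathmm)] <-
    "fathmm_missing"
  rownames(out) <- NULL
  out
}

#' Annotate the protein-level consequence of an SNV inside an ORF
#'
#' Projects the genomic position to the transcript coordinate (strand-aware;
#' alleles are complemented on the minus strand), substitutes the base in the
#' affected codon and translates. Consequences: synonymous, missense,
#' stop_gain, stop_loss, start_loss (codon 1 losing its ATG).
#'
#' @param variant one-row data.frame or list: chrom, pos (1-based), ref, alt.
#' @param orf candidate row: tx_start, tx_end (and transcript_id).
#' @param tx the owning \code{sorf_transcript}.
#' @return list: consequence, codon_index (1-based), ref_aa, alt_aa,
#'   ref_codon, alt_codon.
#' @export
annotate_coding_consequence <- function(variant, orf, tx) {
  p0 <- variant_pos0(variant$pos)
  txpos <- genome_pos_to_tx(tx, p0)
  if (is.na(txpos) || txpos < orf$tx_start || txpos >= orf$tx_end)
    stop("variant does not fall inside the ORF's blocks")
  ref_tx <- if (tx$strand == "+") variant$ref else comp_base(variant$ref)
  alt_tx <- if (tx$strand == "+") variant$alt else comp_base(variant$alt)
  have <- substr(tx$sequence, txpos + 1, txpos + 1)
  if (have != ref_tx)
    stop("reference mismatch: transcript has ", have, ", variant ref is ",
         ref_tx, " (transcript orientation)")
  off <- txpos - orf$tx_start
  ci <- off %/% 3L                        # 0-based codon index
  within <- off %% 3L
  cstart <- orf$tx_start + ci * 3L
  ref_codon <- substr(tx$sequence, cstart + 1, cstart + 3)
  alt_codon <- ref_codon
  substr(alt_codon, within + 1, within + 1) <- alt_tx
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  consequence <- if (ci == 0L && ref_codon == "ATG" && alt_codon != "ATG")
    "start_loss"
  else if (ref_aa != "*" && alt_aa == "*") "stop_gain"
  else if (ref_aa == "*" && alt_aa != "*") "stop_loss"
  else if (ref_aa == alt_aa) "synonymous"
  else "missense"
  list(consequence = consequence, codon_index = ci + 1L,
       ref_aa = ref_aa, alt_aa = alt_aa,
       ref_codon = ref_codon, alt_codon = alt_codon)
}

#' Map genome-wide-significant GWAS SNPs onto ORFs
#'
#' Keeps SNPs from studies of at least \code{min_n} participants with
#' association P at most \code{max_p} (boundaries inclusive, as printed) that
#' overlap an ORF block, and reports distinct (ORF, trait) pairs with each
#' pair's best (smallest-P) SNP.
#'
#' @param snps data.frame: chrom, pos (1-based), pvalue, trait, study_n.
#' @param orfs ORF table with orf_id, chrom, genomic_blocks.
#' @param min_n,max_p thresholds (defaults 10000 and 5e-8).
#' @return data.frame: orf_id, trait, best_pvalue, best_pos, n_snps.
#' @export
map_gwas_snps <- function(snps, orfs, min_n = 10000, max_p = 5e-8) {
  sig <- snps[snps$study_n >= min_n & snps$pvalue <= max_p, , drop = FALSE]
  empty <- data.frame(orf_id = character(0), trait = character(0),
                      best_pvalue = numeric(0), best_pos = integer(0),
                      n_snps = integer(0))
  if (nrow(sig) == 0) return(empty)
  ov <- map_variants_to_orfs(
    data.frame(chrom = sig$chrom, pos = sig$pos, ref = "N", alt = "A",
               pvalue = sig$pvalue, trait = sig$trait,
               study_n = sig$study_n, stringsAsFactors = FALSE), orfs)
  if (nrow(ov) == 0) return(empty)
  sp <- split(ov, paste(ov$orf_id, ov$trait, sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(d) {
    b <- which.min(d$pvalue)
    data.frame(orf_id = d$orf_id[1], trait = d$trait[1],
               best_pvalue = d$pvalue[b], best_pos = d$pos[b],
               n_snps = nrow(d), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$orf_id, out$trait), ]
  rownames(out) <- NULL
  out
}
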
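#' Construct a spliced transcript record
#'
#' The package-internal transcript representation: genomic exon blocks in
#' 0-based half-open coordinates sorted by genomic start, together with the
#' strand-corrected spliced sequence (5' to 3'). The canonical CDS, when
#' present, is a transcript-relative 0-based half-open interval.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom contig name.
#' @param strand "+" or "-".
#' @param exons two-column matrix (start, end), 0-based half-open, ascending.
#' @param sequence spliced nucleotide string, 5' to 3' on the transcript.
#' @param annotation_biotype annotation label (e.g. "protein_coding",
#'   "lncRNA", "pseudogene", "TEC").
#' @param source_catalog character vector of source catalog labels.
#' @param canonical_cds optional length-2 numeric: transcript-relative CDS
#'   interval, 0-based half-open (stop codon included).
#' @return An object of class \code{sorf_transcript}.
#' @export
new_transcript <- function(transcript_id, gene_id, chrom, strand, exons,
                           sequence, annotation_biotype = "lncRNA",
                           source_catalog = "default", canonical_cds = NULL) {
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  tx <- structure(list(transcript_id = transcript_id, gene_id = gene_id,
                       chrom = chrom, strand = strand, exons = exons,
                       sequence = toupper(sequence),
                       annotation_biotype = annotation_biotype,
                       source_catalog = source_catalog,
                       canonical_cds = canonical_cds),
                  class = "sorf_transcript")
  validate_transcript(tx)
  tx
}

validate_transcript <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 1L) stop("transcript ", tx$transcript_id, ": no exons")
  if (any(ex[, 2] <= ex[, 1]))
    stop("transcript ", tx$transcript_id, ": empty or inverted exon block")
  if (nrow(ex) > 1L) {
    if (is.unsorted(ex[, 1], strictly = TRUE) ||
        any(ex[-1L, 1] < ex[-nrow(ex), 2]))
      stop("transcript ", tx$transcript_id,
           ": exon blocks unsorted or overlapping")
  }
  if (!tx$strand %in% c("+", "-"))
    stop("transcript ", tx$transcript_id, ": bad strand")
  if (nchar(tx$sequence) != sum(ex[, 2] - ex[, 1]))
    stop("transcript ", tx$transcript_id,
         ": sequence length does not match exon total")
  if (!is.null(tx$canonical_cds)) {
    cds <- tx$canonical_cds
    if (cds[1] < 0 || cds[2] > nchar(tx$sequence) || cds[2] <= cds[1])
      stop("transcript ", tx$transcript_id, ": canonical CDS out of bounds")
  }
  invisible(tx)
}

tx_length <- function(tx) nchar(tx$sequence)

# Cumulative exon lengths in TRANSCRIPT order (for "-" strand the genomic
# blocks are traversed right to left).
tx_exon_lengths <- function(tx) {
  lens <- tx$exons[, 2] - tx$exons[, 1]
  if (tx$strand == "-") rev(lens) else lens
}

#' Project a transcript-relative interval onto genomic blocks
#'
#' Maps a 0-based half-open transcript interval through the exon chain to one
#' or more genomic blocks. Minus-strand transcripts project with reversed
#' orientation. Blocks are returned sorted by genomic start and their total
#' length equals the interval length.
#'
#' @param tx a \code{sorf_transcript}.
#' @param tx_start,tx_end transcript-relative interval, 0-based half-open.
#' @return Two-column matrix of genomic (start, end) blocks, 0-based half-open.
#' @export
tx_interval_to_genome <- function(tx, tx_start, tx_end) {
  if (tx_start < 0 || tx_end > tx_length(tx) || tx_end <= tx_start)
    stop("interval [", tx_start, ",", tx_end, ") out of transcript bounds")
  lens <- tx_exon_lengths(tx)
  offs <- c(0, cumsum(lens))
  n <- length(lens)
  # exon index in transcript order -> genomic exon row
  g_idx <- if (tx$strand == "-") rev(seq_len(n)) else seq_len(n)
  blocks <- NULL
  for (k in seq_len(n)) {
    lo <- max(tx_start, offs[k]); hi <- min(tx_end, offs[k + 1])
    if (hi <= lo) next
    ex <- tx$exons[g_idx[k], ]
    if (tx$strand == "+") {
      b <- c(ex[1] + (lo - offs[k]), ex[1] + (hi - offs[k]))
    } else {
      b <- c(ex[2] - (hi - offs[k]), ex[2] - (lo - offs[k]))
    }
    blocks <- rbind(blocks, b)
  }
  blocks <- blocks[order(blocks[, 1]), , drop = FALSE]
  dimnames(blocks) <- list(NULL, c("start", "end"))
  blocks
}

# Inverse projection: genomic position (0-based) -> transcript coordinate,
# or NA if the position falls in an intron / outside the transcript.
genome_pos_to_tx <- function(tx, gpos) {
  lens <- tx_exon_lengths(tx)
  offs <- c(0, cumsum(lens))
  n <- length(lens)
  g_idx <- if (tx$strand == "-") rev(seq_len(n)) else seq_len(n)
  for (k in seq_len(n)) {
    ex <- tx$exons[g_idx[k], ]
    if (gpos >= ex[1] && gpos < ex[2]) {
      return(if (tx$strand == "+") offs[k] + (gpos - ex[1])
             else offs[k] + (ex[2] - 1 - gpos))
    }
  }
  NA_real_
}

# Extract the sequence spanned by genomic blocks from a genome, reading in
# transcript orientation (reverse complement on "-").
extract_blocks_seq <- function(genome, chrom, blocks, strand) {
  chromseq <- genome[[chrom]]
  pieces <- vapply(seq_len(nrow(blocks)), function(i) {
    as.character(Biostrings::subseq(chromseq, start = blocks[i, 1] + 1L,
                                    end = blocks[i, 2]))
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (strand == "-") revcomp(s) else s
}

# Spliced transcript sequence straight from the genome.
spliced_sequence <- function(genome, chrom, exons, strand) {
  extract_blocks_seq(genome, chrom, exons, strand)
}
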
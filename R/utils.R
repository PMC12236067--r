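# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a labelled substream seed from a master seed
#'
#' Each simulated artifact draws from its own pseudo-random stream derived
#' deterministically from (master seed, label), so adding one simulator never
#' shifts another's draws.
#'
#' @param master integer master seed.
#' @param label character stream label.
#' @return An integer seed in [0, 2^31 - 1).
#' @keywords internal
substream_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer((abs(master) %% 2147483647 + h * 2654435 %% 2147483647) %% 2147483647)
}

# Evaluate `expr` under a labelled substream without disturbing the caller's
# RNG state.
with_substream <- function(master, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(master, label))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]

# Translate a DNA string (length divisible by 3) with the standard code.
# Codons containing N give NA; stop codons give "*".
translate_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  if (n == 0L) return(character(0))
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  unname(aa)
}

# Protein from an ATG..stop nucleotide span (stop codon included in `seq`).
translate_orf <- function(seq) {
  aa <- translate_codons(seq)
  if (anyNA(aa)) stop("untranslatable codon (ambiguous base)")
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) stop("internal stop codon")
  paste(aa, collapse = "")
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# The 61 sense codons (standard code).
sense_codons <- function() {
  all3 <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  setdiff(all3, STOP_CODONS)
}

# ATG + (n_codons - 1) sense codons + one stop codon; protein length n_codons.
make_orf_seq <- function(n_codons) {
  stopifnot(n_codons >= 1)
  body <- if (n_codons > 1)
    paste(sample(sense_codons(), n_codons - 1L, replace = TRUE), collapse = "")
  else ""
  paste0("ATG", body, sample(STOP_CODONS, 1L))
}

# Deterministic ORF identifier: transcript + frame + transcript-relative start.
orf_identifier <- function(transcript_id, frame, tx_start) {
  sprintf("%s:f%d:%d", transcript_id, frame, tx_start)
}

# Consistent TSV writers so pipeline outputs are byte-stable.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
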
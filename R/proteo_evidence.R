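#' In-silico tryptic digestion
#'
#' Cuts after K or R except when the next residue is P.
#'
#' @param protein amino-acid string.
#' @return character vector of peptides in order.
#' @export
tryptic_digest <- function(protein) {
  if (nchar(protein) == 0) return(character(0))
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- unique(c(0L, cut_after, n))
  substring(protein, utils::head(bounds, -1) + 1L, bounds[-1])
}

#' Minimum mismatch count to a canonical proteome
#'
#' Minimum Hamming distance between the peptide and any equal-length window
#' of any canonical protein (ungapped). Proteins shorter than the peptide
#' contribute nothing; if no window exists anywhere the peptide length is
#' returned.
#'
#' @param peptide amino-acid string.
#' @param proteome character vector of canonical protein sequences.
#' @param collapse_il treat I and L as identical (default FALSE).
#' @return integer minimum mismatch count.
#' @export
min_mismatch_to_canonical <- function(peptide, proteome, collapse_il = FALSE) {
  k <- nchar(peptide)
  stopifnot(k >= 1)
  if (length(proteome) == 0) {
    warning("empty canonical proteome")
    return(k)
  }
  if (collapse_il) {
    peptide <- gsub("I", "L", peptide)
    proteome <- gsub("I", "L", proteome)
  }
  pep <- utf8ToInt(peptide)
  best <- k
  for (prot in proteome) {
    n <- nchar(prot)
    if (n < k) next
    pv <- utf8ToInt(prot)
    for (s in 0:(n - k)) {
      d <- sum(pv[(s + 1):(s + k)] != pep)
      if (d < best) {
        best <- d
        if (best == 0L) return(0L)
      }
    }
  }
  best
}

#' Filter and map PSM peptides against SEP and canonical databases
#'
#' A peptide is accepted iff its search score is at least \code{min_score},
#' its length lies in [\code{min_len}, \code{max_len}], it is a substring of
#' exactly one SEP representative, and its minimum mismatch count to the
#' canonical proteome is at least \code{min_mismatches} (near-canonical
#' peptides could arise from SNPs and are discarded). Rows whose claimed SEP
#' is absent from the SEP set are treated as decoy/contaminant rows and
#' rejected; rows claiming a known SEP that does not contain the peptide
#' raise a data-integrity error. The rejection log records the first failing
#' rule in the fixed order score, length, decoy, uniqueness, canonical_match,
#' but acceptance itself is order-independent (a peptide is accepted only
#' when every rule passes).
#'
#' @param psms data.frame with peptide, sep_id, sample, psm_count, score.
#' @param sep_proteins named character vector of SEP representative
#'   sequences.
#' @param canonical_proteome character vector of canonical proteins.
#' @param min_len,max_len,min_score,min_mismatches filter thresholds
#'   (defaults 7, 20, 2.0, 2).
#' @param collapse_il treat I/L as identical in the mismatch search.
#' @return list: \code{accepted} (PSM rows passing all rules, with
#'   n_sep_hits and min_mismatch columns), \code{rejected} (peptide, reason).
#' @export
filter_and_map_peptides <- function(psms, sep_proteins, canonical_proteome,
                                    min_len = 7L, max_len = 20L,
                                    min_score = 2.0, min_mismatches = 2L,
                                    collapse_il = FALSE) {
  stopifnot(length(canonical_proteome) > 0)
  peptides <- unique(psms$peptide)
  n_hits <- vapply(peptides, function(p)
    sum(vapply(sep_proteins, function(s) grepl(p, s, fixed = TRUE),
               logical(1))), integer(1))
  mm <- vapply(peptides, function(p)
    min_mismatch_to_canonical(p, canonical_proteome,
                              collapse_il = collapse_il), integer(1))
  # data-integrity: claimed SEP must contain the peptide
  claimed_known <- psms$sep_id %in% names(sep_proteins)
  bad <- rep(FALSE, nrow(psms))
  bad[claimed_known] <- !mapply(function(p, s)
    grepl(p, sep_proteins[[s]], fixed = TRUE),
    psms$peptide[claimed_known], psms$sep_id[claimed_known])
  if (any(bad))
    stop("peptide not a substring of its claimed SEP: ",
         paste(utils::head(psms$peptide[bad], 3), collapse = ", "))
  pep_len <- nchar(psms$peptide)
  pass_score <- psms$score >= min_score
  pass_len <- pep_len >= min_len & pep_len <= max_len
  pass_decoy <- claimed_known
  pass_unique <- n_hits[psms$peptide] == 1L
  pass_canon <- mm[psms$peptide] >= min_mismatches
  ok <- pass_score & pass_len & pass_decoy & pass_unique & pass_canon
  reason <- rep(NA_character_, nrow(psms))
  reason[!pass_canon] <- "canonical_match"
  reason[!pass_unique] <- "not_unique"
  reason[!pass_decoy] <- "decoy_or_contaminant"
  reason[!pass_len] <- "length"
  reason[!pass_score] <- "score"
  accepted <- psms[ok, , drop = FALSE]
  accepted$n_sep_hits <- unname(n_hits[accepted$peptide])
  accepted$min_mismatch <- unname(mm[accepted$peptide])
  rejected <- data.frame(peptide = psms$peptide[!ok],
                         sep_id = psms$sep_id[!ok],
                         reason = reason[!ok], stringsAsFactors = FALSE)
  list(accepted = accepted, rejected = rejected)
}

#' Aggregate accepted PSMs into per-SEP evidence tiers
#'
#' Per SEP: unique accepted peptide strings, total PSM counts and the number
#' of distinct samples with at least one accepted PSM. Tier \code{high}
#' requires at least \code{min_psms} total PSMs AND at least
#' \code{min_samples} samples; otherwise \code{none}.
#'
#' @param accepted accepted PSM rows from
#'   \code{\link{filter_and_map_peptides}}.
#' @param min_psms,min_samples tier thresholds (defaults 10 and 3).
#' @return data.frame: sep_id, unique_peptides, total_psms, n_samples, tier.
#' @export
aggregate_sep_evidence <- function(accepted, min_psms = 10L,
                                   min_samples = 3L) {
  if (nrow(accepted) == 0)
    return(data.frame(sep_id = character(0), unique_peptides = integer(0),
                      total_psms = integer(0), n_samples = integer(0),
                      tier = character(0)))
  sp <- split(accepted, accepted$sep_id)
  out <- do.call(rbind, lapply(names(sp), function(id) {
    d <- sp[[id]]
    data.frame(sep_id = id,
               unique_peptides = length(unique(d$peptide)),
               total_psms = sum(d$psm_count),
               n_samples = length(unique(d$sample)),
               stringsAsFactors = FALSE)
  }))
  out$tier <- ifelse(out$total_psms >= min_psms &
                       out$n_samples >= min_samples, "high", "none")
  rownames(out) <- NULL
  out
}

#' Filter MHC-candidate immunopeptides
#'
#' Keeps peptides of 8-15 residues that map to exactly one SEP and are not
#' an exact substring of any canonical protein.
#'
#' @param peptides character vector of candidate peptides.
#' @param sep_proteins named character vector of SEP sequences.
#' @param canonical_proteome canonical protein sequences.
#' @return list: \code{accepted} (data.frame peptide, sep_id, length),
#'   \code{length_histogram} (table of accepted lengths).
#' @export
filter_immunopeptides <- function(peptides, sep_proteins,
                                  canonical_proteome) {
  peptides <- unique(peptides)
  len_ok <- nchar(peptides) >= 8 & nchar(peptides) <= 15
  keep <- list()
  for (p in peptides[len_ok]) {
    hits <- names(sep_proteins)[vapply(sep_proteins, function(s)
      grepl(p, s, fixed = TRUE), logical(1))]
    if (length(hits) != 1L) next
    if (any(vapply(canonical_proteome, function(s)
      grepl(p, s, fixed = TRUE), logical(1)))) next
    keep[[length(keep) + 1L]] <- data.frame(peptide = p, sep_id = hits,
                                            length = nchar(p),
                                            stringsAsFactors = FALSE)
  }
  accepted <- if (length(keep)) do.call(rbind, keep) else
    data.frame(peptide = character(0), sep_id = character(0),
               length = integer(0))
  list(accepted = accepted,
       length_histogram = table(factor(accepted$length, levels = 8:15)))
}

#' Disordered residue content of a SEP
#'
#' Residues with a per-residue disorder score of at least \code{threshold}
#' count as disordered; the flag is set when at least half the protein is
#' disordered.
#'
#' @param scores numeric per-residue disorder scores.
#' @param protein_length expected length (validation); defaults to
#'   \code{length(scores)}.
#' @param threshold per-residue cutoff (default 0.5).
#' @return list: fraction, flag.
#' @export
disordered_fraction <- function(scores, protein_length = length(scores),
                                threshold = 0.5) {
  if (length(scores) != protein_length)
    stop("score vector length (", length(scores),
         ") does not match protein length (", protein_length, ")")
  fraction <- mean(scores >= threshold)
  list(fraction = fraction, flag = fraction >= 0.5)
}
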
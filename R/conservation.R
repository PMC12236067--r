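#' Per-ORF conservation statistics from a per-base score track
#'
#' Computes the mean conservation score and the fraction of conserved
#' positions (score strictly > 0) over an ORF's genomic blocks. Positions
#' absent from the track are counted as missing and excluded from both
#' statistics, not imputed as zero; an ORF with no scored position is
#' flagged unscored.
#'
#' @param blocks genomic block matrix (0-based half-open).
#' @param track a \code{sorf_track} (named list of per-chrom score vectors,
#'   1-based positions, NA = missing).
#' @param chrom contig of the blocks.
#' @return list: mean_score, fraction_conserved, n_scored, n_missing,
#'   unscored.
#' @export
score_orf_conservation <- function(blocks, track, chrom) {
  total <- sum(blocks[, 2] - blocks[, 1])
  v <- track[[chrom]]
  if (is.null(v)) {
    return(list(mean_score = NA_real_, fraction_conserved = NA_real_,
                n_scored = 0L, n_missing = as.integer(total),
                unscored = TRUE))
  }
  idx <- unlist(lapply(seq_len(nrow(blocks)), function(b)
    seq.int(blocks[b, 1] + 1L, blocks[b, 2])))
  scores <- rep(NA_real_, length(idx))
  inside <- idx >= 1L & idx <= length(v)
  scores[inside] <- v[idx[inside]]
  ok <- !is.na(scores)
  n_scored <- sum(ok)
  if (n_scored == 0L)
    return(list(mean_score = NA_real_, fraction_conserved = NA_real_,
                n_scored = 0L, n_missing = as.integer(total),
                unscored = TRUE))
  list(mean_score = mean(scores[ok]),
       fraction_conserved = mean(scores[ok] > 0),
       n_scored = as.integer(n_scored),
       n_missing = as.integer(total - n_scored),
       unscored = FALSE)
}

#' Derive conservation cutoffs from canonical CDS statistics
#'
#' The score cutoff is the median of the canonical CDS mean scores; the
#' fraction cutoff is the 25th percentile of the canonical
#' fraction-conserved values (so that 75\% of canonical genes meet it).
#' Percentiles use linear interpolation (R quantile type 7).
#'
#' @param canonical_stats data.frame with columns mean_score and
#'   fraction_conserved (unscored rows NA).
#' @return list of class \code{conservation_cutoffs}: score_cutoff,
#'   fraction_cutoff, derivation.
#' @export
derive_cutoffs <- function(canonical_stats) {
  ms <- canonical_stats$mean_score
  fc <- canonical_stats$fraction_conserved
  ok <- !is.na(ms) & !is.na(fc)
  if (sum(ok) == 0) stop("all canonical entries are unscored")
  if (sum(ok) < 2) stop("need at least 2 scored canonical CDS entries")
  structure(list(score_cutoff = stats::median(ms[ok]),
                 fraction_cutoff = unname(stats::quantile(fc[ok], 0.25,
                                                          type = 7)),
                 derivation = c("median_of_cds_means",
                                "quartile_of_cds_fractions")),
            class = "conservation_cutoffs")
}

#' Classify an ORF as conserved
#'
#' Conserved iff mean score >= score cutoff AND fraction of conserved
#' positions >= fraction cutoff (both boundaries inclusive). Unscored ORFs
#' are never conserved.
#'
#' @param stats result of \code{\link{score_orf_conservation}} (or data.frame
#'   row with mean_score / fraction_conserved).
#' @param cutoffs a \code{conservation_cutoffs}.
#' @return logical.
#' @export
classify_conserved <- function(stats, cutoffs) {
  if (isTRUE(stats$unscored) || is.na(stats$mean_score)) return(FALSE)
  stats$mean_score >= cutoffs$score_cutoff &&
    stats$fraction_conserved >= cutoffs$fraction_cutoff
}

#' Conservation analysis over a whole ORF table
#'
#' Scores every ORF, derives cutoffs from the supplied canonical CDS entries
#' and classifies each ORF.
#'
#' @param orfs ORF table with orf_id, chrom and genomic_blocks columns.
#' @param canonical_blocks named list of canonical CDS block matrices
#'   (per gene), same chrom space.
#' @param track a \code{sorf_track}.
#' @param chrom contig name used when orfs lack a chrom column.
#' @param cutoffs optional pre-pinned \code{conservation_cutoffs}; derived
#'   from the canonical set when NULL.
#' @return list: \code{stats} (per-ORF data.frame with conserved flag),
#'   \code{canonical_stats}, \code{cutoffs}.
#' @export
conservation_analysis <- function(orfs, canonical_blocks, track,
                                  chrom = NULL, cutoffs = NULL) {
  canon <- do.call(rbind, lapply(names(canonical_blocks), function(g) {
    st <- score_orf_conservation(canonical_blocks[[g]], track,
                                 attr(canonical_blocks, "chrom") %||%
                                   chrom %||% names(track)[1])
    data.frame(gene_id = g, mean_score = st$mean_score,
               fraction_conserved = st$fraction_conserved,
               stringsAsFactors = FALSE)
  }))
  if (is.null(cutoffs)) cutoffs <- derive_cutoffs(canon)
  stats <- do.call(rbind, lapply(seq_len(nrow(orfs)), function(i) {
    blk <- blocks_from_string(orfs$genomic_blocks[i])
    st <- score_orf_conservation(blk, track, orfs$chrom[i])
    data.frame(orf_id = orfs$orf_id[i], mean_score = st$mean_score,
               fraction_conserved = st$fraction_conserved,
               n_scored = st$n_scored, n_missing = st$n_missing,
               unscored = st$unscored,
               conserved = classify_conserved(st, cutoffs),
               stringsAsFactors = FALSE)
  }))
  list(stats = stats, canonical_stats = canon, cutoffs = cutoffs)
}
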
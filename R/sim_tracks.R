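#' Simulate a per-base conservation score track
#'
#' Draws phyloP-like scores for every contig position: positions under
#' constraint (canonical CDS blocks and planted sORFs with
#' \code{is_conserved = TRUE}) get \code{Normal(cons_mu_cds, cons_sigma)},
#' everything else \code{Normal(cons_mu_neutral, cons_sigma)}.
#'
#' @param sim result of \code{\link{generate_toy_annotation}}.
#' @param config a \code{\link{sim_config}}; defaults to the one used to
#'   generate \code{sim}.
#' @return A conservation track: named list (one numeric vector per chrom,
#'   position 1-based), class \code{sorf_track}.
#' @export
simulate_conservation_track <- function(sim, config = sim$config) {
  with_substream(config$seed, "conservation", {
    lens <- Biostrings::width(sim$genome)
    track <- stats::setNames(vector("list", length(sim$genome)),
                             names(sim$genome))
    for (i in seq_along(track))
      track[[i]] <- stats::rnorm(lens[i], config$cons_mu_neutral,
                                 config$cons_sigma)
    constrained <- sim$truth[sim$truth$is_conserved, , drop = FALSE]
    for (r in seq_len(nrow(constrained))) {
      blk <- blocks_from_string(constrained$genomic_blocks[r])
      ch <- constrained$chrom[r]
      mu <- if (constrained$biotype[r] == "canonical_cds") config$cons_mu_cds
            else config$cons_mu_cds + (config$cons_sorf_margin %||% 0)
      for (b in seq_len(nrow(blk))) {
        idx <- (blk[b, 1] + 1L):blk[b, 2]
        track[[ch]][idx] <- stats::rnorm(length(idx), mu, config$cons_sigma)
      }
    }
    structure(track, class = "sorf_track")
  })
}

#' Write / read a conservation track as bedGraph
#'
#' bedGraph intervals are 0-based half-open; one row per base.
#'
#' @param track a \code{sorf_track} (named list of per-chrom score vectors).
#' @param path output file.
#' @return \code{write_track_bedgraph}: the path, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  rows <- lapply(names(track), function(ch) {
    v <- track[[ch]]
    keep <- !is.na(v)
    data.frame(chrom = ch, start = which(keep) - 1L, end = which(keep),
               score = round(v[keep], 4))
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               score = df$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_track_bedgraph
#' @export
read_track_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- as.data.frame(gr)
  track <- list()
  for (ch in unique(as.character(df$seqnames))) {
    d <- df[df$seqnames == ch, ]
    v <- rep(NA_real_, max(d$end))
    for (i in seq_len(nrow(d))) v[d$start[i]:d$end[i]] <- d$score[i]
    track[[ch]] <- v
  }
  structure(track, class = "sorf_track")
}
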
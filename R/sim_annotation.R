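#' Generate a toy annotated transcriptome with planted sORFs
#'
#' Builds a small single-contig genome carrying canonical protein-coding genes
#' (three exons, annotated CDS), UTR-embedded small ORFs, intergenic and
#' antisense lncRNAs, pseudogenes (mutated CDS copies) and TEC transcripts,
#' on both strands. Every planted sORF starts ATG, ends at a stop codon, is at
#' least \code{config$min_codons} codons long, and its true translation /
#' conservation status, generative NB rate and dispersion, and NMD status are
#' recorded in the truth table.
#'
#' Antisense lncRNAs sit on the opposite strand inside a host gene's first
#' intron so their genomic span overlaps the gene; intergenic features are
#' separated from every gene by at least 1 kb.
#'
#' @param config a \code{\link{sim_config}} object.
#' @param contig_length optional fixed contig length; an error naming the
#'   constraint is raised if the requested features do not fit.
#' @return A list with elements \code{genome} (named \code{DNAStringSet}),
#'   \code{transcripts} (list of \code{sorf_transcript}), \code{genes}
#'   (data.frame of canonical gene spans and CDS blocks), \code{truth}
#'   (data.frame, one row per planted ORF and canonical CDS) and
#'   \code{config}.
#' @export
generate_toy_annotation <- function(config, contig_length = NULL) {
  validate_sim_config(config)
  with_substream(config$seed, "annotation", {
    chrom <- "chrT"
    cursor <- 1000
    transcripts <- list()
    genes <- NULL
    truth <- NULL
    nS <- config$n_sorfs_per_biotype
    G <- config$n_canonical_genes
    if ((nS[["5utr"]] > G) || (nS[["3utr"]] > G))
      stop("cannot place more UTR sORFs than canonical genes (",
           G, " genes available)")
    if (nS[["lnc_antisense"]] > 0 && G < 1)
      stop("antisense lncRNAs require at least one canonical gene")

    rand_codons <- function(n) sample(config$sorf_codons_range[1]:
                                      config$sorf_codons_range[2], n,
                                      replace = TRUE)

    planted <- NULL  # accumulate planted sORF descriptors
    add_planted <- function(df, tx_id, biotype, tx_start, orf_seq, nmd_pass,
                            nmd_reason, nmd_exempt) {
      rbind(df, data.frame(
        transcript_id = tx_id, biotype = biotype, tx_start = tx_start,
        tx_end = tx_start + nchar(orf_seq), orf_seq = orf_seq,
        nmd_pass = nmd_pass, nmd_reason = nmd_reason,
        nmd_exempt_5utr = nmd_exempt, stringsAsFactors = FALSE))
    }

    # ---- canonical genes -------------------------------------------------
    cds_seqs <- character(G)
    for (i in seq_len(G)) {
      strand <- if (i %% 2L == 1L) "+" else "-"
      tid <- sprintf("tx_gene%02d", i); gid <- sprintf("gene%02d", i)
      has_u5 <- i <= nS[["5utr"]]
      has_u3 <- i <= nS[["3utr"]]

      if (has_u5) {
        nc <- rand_codons(1)
        u5_orf <- make_orf_seq(nc)
        pre <- random_dna(sample(20:60, 1))
        post <- random_dna(sample(40:80, 1))
        u5 <- paste0(pre, u5_orf, post)
        u5_orf_start <- nchar(pre)
      } else {
        u5 <- random_dna(sample(250:400, 1))
      }
      nc_cds <- sample(150:300, 1)
      cds <- make_orf_seq(nc_cds)
      cds_seqs[i] <- cds
      if (has_u3) {
        nc3 <- rand_codons(1)
        u3_orf <- make_orf_seq(nc3)
        pre3 <- random_dna(sample(30:60, 1))
        post3 <- random_dna(sample(40:80, 1))
        u3 <- paste0(pre3, u3_orf, post3)
        u3_orf_start <- nchar(pre3)
      } else {
        u3 <- random_dna(sample(200:300, 1))
      }
      seq <- paste0(u5, cds, u3)
      L <- nchar(seq); u5n <- nchar(u5); cdsn <- nchar(cds)
      # exon junctions: uORF stop stays in exon 1; canonical stop in exon 3
      j1 <- u5n - 20L
      j2 <- u5n + cdsn - 100L
      lens_tx <- c(j1, j2 - j1, L - j2)
      introns <- c(sample(600:900, 1), sample(400:600, 1))
      widths_gen <- if (strand == "+") lens_tx else rev(lens_tx)
      introns_gen <- if (strand == "+") introns else rev(introns)
      starts <- cursor + cumsum(c(0, widths_gen[-3] + introns_gen))
      exons <- cbind(start = starts, end = starts + widths_gen)
      tx <- new_transcript(tid, gid, chrom, strand, exons, seq,
                           annotation_biotype = "protein_coding",
                           source_catalog = "sim",
                           canonical_cds = c(u5n, u5n + cdsn))
      transcripts[[tid]] <- tx
      cds_blocks <- tx_interval_to_genome(tx, u5n, u5n + cdsn)
      genes <- rbind(genes, data.frame(
        gene_id = gid, chrom = chrom, strand = strand,
        start = min(exons[, 1]), end = max(exons[, 2]),
        cds_blocks = blocks_to_string(cds_blocks),
        intron1 = paste0(exons[1, 2], "-", exons[2, 1]),
        stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        transcript_id = tid, biotype = "canonical_cds", tx_start = u5n,
        tx_end = u5n + cdsn, orf_seq = cds, nmd_pass = TRUE,
        nmd_reason = "last_exon", nmd_exempt_5utr = FALSE,
        stringsAsFactors = FALSE))
      if (has_u5)
        planted <- add_planted(planted, tid, "5utr", u5_orf_start, u5_orf,
                               TRUE, "utr5_exempt", TRUE)
      if (has_u3)
        planted <- add_planted(planted, tid, "3utr", u5n + cdsn + u3_orf_start,
                               u3_orf, TRUE, "last_exon", FALSE)
      cursor <- max(exons[, 2]) + sample(1000:1500, 1)
    }

    # ---- antisense lncRNAs (in host introns, opposite strand) ------------
    for (k in seq_len(nS[["lnc_antisense"]])) {
      host <- genes[((k - 1L) %% G) + 1L, ]
      gap <- as.numeric(strsplit(host$intron1, "-")[[1]])
      tid <- sprintf("tx_aslnc%02d", k)
      nc <- rand_codons(1)
      orf <- make_orf_seq(nc)
      seq <- paste0(random_dna(30), orf, random_dna(30))
      w <- nchar(seq)
      if (gap[2] - gap[1] < w + 20)
        stop("host intron too small for antisense lncRNA (need ", w + 20,
             " nt, have ", gap[2] - gap[1], ")")
      st <- gap[1] + 10
      strand <- if (host$strand == "+") "-" else "+"
      tx <- new_transcript(tid, sprintf("aslnc%02d", k), chrom, strand,
                           cbind(st, st + w), seq,
                           annotation_biotype = "lncRNA",
                           source_catalog = "sim")
      transcripts[[tid]] <- tx
      planted <- add_planted(planted, tid, "lnc_antisense", 30L, orf,
                             TRUE, "single_exon", FALSE)
    }

    # ---- intergenic single-exon features ---------------------------------
    intergenic <- function(biotype_label, truth_biotype, n, seq_maker) {
      for (k in seq_len(n)) {
        tid <- sprintf("tx_%s%02d", truth_biotype, k)
        nc <- rand_codons(1)
        orf <- make_orf_seq(nc)
        parts <- seq_maker(orf, k)
        seq <- parts$seq
        strand <- sample(c("+", "-"), 1)
        w <- nchar(seq)
        tx <- new_transcript(tid, sprintf("%s_g%02d", truth_biotype, k),
                             chrom, strand, cbind(cursor, cursor + w), seq,
                             annotation_biotype = biotype_label,
                             source_catalog = "sim")
        transcripts[[tid]] <<- tx
        planted <<- add_planted(planted, tid, truth_biotype, parts$orf_start,
                                orf, TRUE, "single_exon", FALSE)
        cursor <<- cursor + w + sample(1000:1500, 1)
      }
    }
    plain_maker <- function(orf, k)
      list(seq = paste0(random_dna(50), orf, random_dna(50)), orf_start = 50L)
    pseudo_maker <- function(orf, k) {
      # mutated copy of a canonical CDS, middle replaced by an intact sORF
      base <- cds_seqs[((k - 1L) %% G) + 1L]
      b <- strsplit(base, "")[[1]]
      mut <- sample(length(b), max(1L, round(0.08 * length(b))))
      b[mut] <- vapply(b[mut], function(x) sample(setdiff(DNA_BASES, x), 1),
                       character(1))
      base <- paste(b, collapse = "")
      if (nchar(base) < nchar(orf) + 100)
        base <- paste0(base, random_dna(nchar(orf) + 100 - nchar(base)))
      list(seq = paste0(substr(base, 1, 50), orf,
                        substr(base, 51, nchar(base) - nchar(orf))),
           orf_start = 50L)
    }
    intergenic("lncRNA", "lnc_intergenic", nS[["lnc_intergenic"]], plain_maker)
    intergenic("pseudogene", "pseudogene", nS[["pseudogene"]], pseudo_maker)
    intergenic("TEC", "tec", nS[["tec"]], plain_maker)

    total_len <- cursor + 1000
    if (!is.null(contig_length)) {
      if (contig_length < total_len)
        stop("contig too small: requested features need ", total_len,
             " nt but contig_length = ", contig_length)
      total_len <- contig_length
    }

    # ---- assemble the genome --------------------------------------------
    gvec <- sample(DNA_BASES, total_len, replace = TRUE)
    for (tx in transcripts) {
      gen_order <- if (tx$strand == "+") tx$sequence else revcomp(tx$sequence)
      off <- 0L
      for (e in seq_len(nrow(tx$exons))) {
        w <- tx$exons[e, 2] - tx$exons[e, 1]
        piece <- substr(gen_order, off + 1L, off + w)
        gvec[(tx$exons[e, 1] + 1L):tx$exons[e, 2]] <- strsplit(piece, "")[[1]]
        off <- off + w
      }
    }
    genome <- Biostrings::DNAStringSet(stats::setNames(
      paste(gvec, collapse = ""), chrom))

    # ---- truth table ------------------------------------------------------
    truth$is_translated <- TRUE
    truth$is_conserved <- TRUE
    if (!is.null(planted)) {
      np <- nrow(planted)
      trans_idx <- sample(np, round(config$fraction_translated * np))
      cons_idx <- sample(np, round(config$fraction_conserved * np))
      planted$is_translated <- seq_len(np) %in% trans_idx
      planted$is_conserved <- seq_len(np) %in% cons_idx
      truth <- rbind(truth, planted)
    }
    n <- nrow(truth)
    truth$true_rate <- ifelse(truth$is_translated,
                              config$rate_translated * exp(stats::rnorm(n, 0, 0.3)),
                              config$rate_noise * exp(stats::rnorm(n, 0, 0.3)))
    truth$true_alpha <- ifelse(truth$is_translated, config$alpha_translated,
                               config$alpha_noise)
    truth$sep_abundance <- ifelse(truth$is_translated,
                                  stats::runif(n, 0.6, 0.95), 0)
    truth$frame <- truth$tx_start %% 3L
    truth$orf_id <- orf_identifier(truth$transcript_id, truth$frame,
                                   truth$tx_start)
    truth$n_codons <- (truth$tx_end - truth$tx_start) / 3L - 1L
    truth$length_nt <- truth$tx_end - truth$tx_start
    truth$protein <- vapply(truth$orf_seq, translate_orf, character(1),
                            USE.NAMES = FALSE)
    truth$chrom <- chrom
    truth$strand <- vapply(truth$transcript_id,
                           function(t) transcripts[[t]]$strand, character(1),
                           USE.NAMES = FALSE)
    truth$genomic_blocks <- vapply(seq_len(n), function(r) {
      blocks_to_string(tx_interval_to_genome(transcripts[[truth$transcript_id[r]]],
                                             truth$tx_start[r], truth$tx_end[r]))
    }, character(1))
    truth <- truth[order(truth$orf_id), ]
    rownames(truth) <- NULL
    stopifnot(!anyDuplicated(truth$orf_id))

    list(genome = genome, transcripts = transcripts, genes = genes,
         truth = truth, config = config)
  })
}

# "start-end,start-end" serialization of a block matrix (0-based half-open).
blocks_to_string <- function(blocks) {
  paste(sprintf("%d-%d", as.integer(blocks[, 1]), as.integer(blocks[, 2])),
        collapse = ",")
}

#' @rdname generate_toy_annotation
#' @param s a "start-end,start-end" block string (0-based half-open).
#' @export
blocks_from_string <- function(s) {
  parts <- strsplit(strsplit(s, ",")[[1]], "-")
  m <- do.call(rbind, lapply(parts, as.numeric))
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

#' Write the simulated annotation to disk
#'
#' Emits \code{genome.fa}, \code{annotation.gtf} (1-based inclusive, with
#' \code{gene_id}, \code{transcript_id}, \code{transcript_biotype}
#' attributes, CDS rows for canonical genes) and \code{truth.tsv}.
#'
#' @param sim result of \code{\link{generate_toy_annotation}}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_simulated_annotation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  tr <- file.path(dir, "truth.tsv")
  Biostrings::writeXStringSet(sim$genome, fa)
  rtracklayer::export(annotation_granges(sim$transcripts), gtf, format = "gtf")
  write_tsv(sim$truth, tr)
  invisible(c(genome = fa, gtf = gtf, truth = tr))
}

# GRanges of transcript/exon/CDS rows for GTF export.
annotation_granges <- function(transcripts) {
  rows <- list()
  for (tx in transcripts) {
    ex <- tx$exons
    span <- c(min(ex[, 1]), max(ex[, 2]))
    add <- function(type, blocks, phase = NA_integer_) {
      data.frame(chrom = tx$chrom, start = blocks[, 1] + 1, end = blocks[, 2],
                 strand = tx$strand, type = type, gene_id = tx$gene_id,
                 transcript_id = tx$transcript_id,
                 transcript_biotype = tx$annotation_biotype,
                 phase = phase, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- add("transcript", matrix(span, ncol = 2))
    rows[[length(rows) + 1L]] <- add("exon", ex)
    if (!is.null(tx$canonical_cds)) {
      cds_blocks <- tx_interval_to_genome(tx, tx$canonical_cds[1],
                                          tx$canonical_cds[2])
      widths <- cds_blocks[, 2] - cds_blocks[, 1]
      w_tx <- if (tx$strand == "-") rev(widths) else widths
      ph_tx <- (3 - cumsum(c(0, w_tx[-length(w_tx)])) %% 3) %% 3
      phase <- if (tx$strand == "-") rev(ph_tx) else ph_tx
      rows[[length(rows) + 1L]] <- add("CDS", cds_blocks, as.integer(phase))
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
  S4Vectors::mcols(gr)$transcript_biotype <- df$transcript_biotype
  S4Vectors::mcols(gr)$phase <- df$phase
  gr
}

#' Load a GTF + FASTA annotation into transcript records
#'
#' Reads an annotation written by \code{\link{write_simulated_annotation}} (or
#' any GTF carrying \code{gene_id}/\code{transcript_id}/
#' \code{transcript_biotype} attributes) and reconstructs spliced transcripts
#' with strand-corrected sequences and canonical CDS intervals.
#'
#' @param gtf_path,fasta_path file paths.
#' @param source_catalog label recorded on every transcript.
#' @return Named list of \code{sorf_transcript} objects.
#' @export
load_annotation <- function(gtf_path, fasta_path, source_catalog = "default") {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  df <- as.data.frame(gr)
  exons <- df[df$type == "exon", ]
  cds <- df[df$type == "CDS", ]
  out <- list()
  for (tid in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tid, ]
    e <- e[order(e$start), ]
    blocks <- cbind(start = e$start - 1, end = e$end)  # to 0-based half-open
    strand <- as.character(e$strand[1])
    chrom <- as.character(e$seqnames[1])
    seq <- spliced_sequence(genome, chrom, blocks, strand)
    tx <- new_transcript(tid, e$gene_id[1], chrom, strand, blocks, seq,
                         annotation_biotype =
                           e$transcript_biotype[1] %||% "lncRNA",
                         source_catalog = source_catalog)
    ccds <- cds[cds$transcript_id == tid, ]
    if (nrow(ccds) > 0) {
      gpos <- sort(c(ccds$start - 1, ccds$end - 1))
      tpos <- vapply(gpos, function(p) genome_pos_to_tx(tx, p), numeric(1))
      tx$canonical_cds <- c(min(tpos), max(tpos) + 1)
    }
    out[[tid]] <- tx
  }
  out
}
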
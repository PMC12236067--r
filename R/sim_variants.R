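#' Simulate variant and GWAS SNP tables overlapping planted ORFs
#'
#' Places single-nucleotide variants half inside planted ORF blocks and half
#' at random contig positions, with pathogenicity scores spanning the
#' filtering thresholds (FATHMM-MKL 0.7 for COSMIC records, CADD 15), and
#' GWAS SNPs with association P values spanning 5e-8 and study sizes spanning
#' 10,000. The truth ledger records every (variant, ORF) overlap and which
#' SNPs are significant.
#'
#' @param sim result of \code{\link{generate_toy_annotation}}.
#' @param config a \code{\link{sim_config}}.
#' @return list: \code{variants} (chrom, pos 1-based, ref, alt, source,
#'   fathmm, cadd, clinical_label), \code{gwas} (chrom, pos, pvalue, trait,
#'   study_n), \code{overlap_truth} (variant_key, orf_id),
#'   \code{gwas_truth} (snp row index, orf_id, significant).
#' @export
simulate_variants <- function(sim, config = sim$config) {
  with_substream(config$seed, "variants", {
    truth <- sim$truth
    chrom <- names(sim$genome)[1]
    glen <- Biostrings::width(sim$genome)[1]
    gseq <- strsplit(as.character(sim$genome[[1]]), "")[[1]]

    pick_inside <- function(n) {
      if (n == 0L) return(integer(0))
      vapply(seq_len(n), function(i) {
        r <- sample(nrow(truth), 1)
        blk <- blocks_from_string(truth$genomic_blocks[r])
        b <- blk[sample(nrow(blk), 1), ]
        as.integer(sample(seq.int(b[1] + 1L, b[2]), 1))  # 1-based pos
      }, integer(1))
    }
    nv <- config$n_variants
    n_in <- nv %/% 2L
    pos <- c(pick_inside(n_in),
             if (nv - n_in > 0) sample.int(glen, nv - n_in) else integer(0))
    variants <- NULL
    if (nv > 0) {
      ref <- gseq[pos]
      alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1),
                    character(1), USE.NAMES = FALSE)
      src <- sample(c("clinvar", "hgmd", "cosmic"), nv, replace = TRUE)
      variants <- data.frame(
        chrom = chrom, pos = pos, ref = ref, alt = alt, source = src,
        fathmm = ifelse(src == "cosmic", round(stats::runif(nv), 3), NA),
        cadd = round(stats::runif(nv, 0, 40), 2),
        clinical_label = sample(c("pathogenic", "likely_pathogenic", "vus"),
                                nv, replace = TRUE),
        stringsAsFactors = FALSE)
    } else {
      variants <- data.frame(chrom = character(0), pos = integer(0),
                             ref = character(0), alt = character(0),
                             source = character(0), fathmm = numeric(0),
                             cadd = numeric(0), clinical_label = character(0))
    }

    ng <- config$n_gwas_snps
    if (ng > 0) {
      gpos <- c(pick_inside(ng %/% 2L), sample.int(glen, ng - ng %/% 2L))
      gwas <- data.frame(
        chrom = chrom, pos = gpos,
        pvalue = sample(c(1e-9, 5e-8, 1e-6), ng, replace = TRUE,
                        prob = c(0.45, 0.1, 0.45)),
        trait = sample(sprintf("trait%02d", 1:5), ng, replace = TRUE),
        study_n = sample(c(5000L, 10000L, 50000L), ng, replace = TRUE,
                         prob = c(0.25, 0.15, 0.6)),
        stringsAsFactors = FALSE)
    } else {
      gwas <- data.frame(chrom = character(0), pos = integer(0),
                         pvalue = numeric(0), trait = character(0),
                         study_n = integer(0))
    }

    # brute-force overlap ledger (independent of the analysis module)
    ledger <- function(df) {
      hits <- list()
      for (i in seq_len(nrow(df))) {
        p0 <- df$pos[i] - 1L  # 0-based
        for (r in seq_len(nrow(truth))) {
          blk <- blocks_from_string(truth$genomic_blocks[r])
          if (any(p0 >= blk[, 1] & p0 < blk[, 2]))
            hits[[length(hits) + 1L]] <- data.frame(
              row = i, orf_id = truth$orf_id[r], stringsAsFactors = FALSE)
        }
      }
      if (length(hits) == 0)
        return(data.frame(row = integer(0), orf_id = character(0)))
      do.call(rbind, hits)
    }
    ov <- ledger(variants)
    gv <- ledger(gwas)
    gv$significant <- gwas$study_n[gv$row] >= 10000 & gwas$pvalue[gv$row] <= 5e-8

    list(variants = variants, gwas = gwas, overlap_truth = ov, gwas_truth = gv)
  })
}

#' Write simulated variant and GWAS tables
#'
#' @param vs result of \code{\link{simulate_variants}}.
#' @param dir output directory.
#' @return Paths written, invisibly.
#' @export
write_variants <- function(vs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vp <- file.path(dir, "variants.tsv")
  gp <- file.path(dir, "gwas.tsv")
  write_tsv(vs$variants, vp)
  write_tsv(vs$gwas, gp)
  invisible(c(variants = vp, gwas = gp))
}
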
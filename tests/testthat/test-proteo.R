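test_that("minimum-mismatch search equals the double-loop oracle", {
  expect_equal(min_mismatch_to_canonical("AAAAAAA", "AAAAAAC"), 1)
  expect_equal(min_mismatch_to_canonical("TAYIAK", "MKTAYIAKQR"), 0)
  # proteome windows shorter than the peptide contribute nothing
  expect_equal(min_mismatch_to_canonical("AAAAAAA", c("AAA", "CCC")), 7)
  expect_warning(got <- min_mismatch_to_canonical("PEPTIDE", character(0)),
                 "empty")
  expect_equal(got, 7)
  set.seed(17)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  proteome <- vapply(1:5, function(i)
    paste(sample(aa, 60, replace = TRUE), collapse = ""), character(1))
  for (i in 1:50) {
    pep <- paste(sample(aa, 9, replace = TRUE), collapse = "")
    expect_equal(min_mismatch_to_canonical(pep, proteome),
                 oracle_min_mismatch(pep, proteome))
  }
  # I/L collapse option
  expect_equal(min_mismatch_to_canonical("ILIL", "LLLL"), 2)
  expect_equal(min_mismatch_to_canonical("ILIL", "LLLL", collapse_il = TRUE), 0)
})

mk_psm <- function(peptide, sep_id = "sep1", sample = "s1", psm_count = 1L,
                   score = 3) data.frame(
  peptide = peptide, sep_id = sep_id, sample = sample,
  psm_count = psm_count, score = score, stringsAsFactors = FALSE)

test_that("peptide filtering applies every rule with exact boundaries", {
  seps <- c(sep1 = "MMKTAYIAKWWQISFVKLNDPQRS",
            sep2 = "MGGHHEECCDDLLNNPPQQRRSSTT")
  canonical <- c("MAAAAATAYIAKQQQQ",        # contains TAYIAK verbatim
                 "MKKKKKKKKKKKKKKK")
  # length boundaries: 6 rejected, 7 and 20 accepted
  p6 <- substr(seps[["sep1"]], 3, 8)    # 6 aa
  p7 <- "WWQISFV"                       # 7 aa, unique to sep1
  p20 <- substr(seps[["sep2"]], 2, 21)  # 20 aa
  p21 <- substr(seps[["sep2"]], 2, 22)
  psms <- rbind(mk_psm(p6), mk_psm(p7), mk_psm(p20, "sep2"),
                mk_psm(p21, "sep2"))
  res <- filter_and_map_peptides(psms, seps, canonical)
  expect_setequal(res$accepted$peptide, c(p7, p20))
  expect_equal(res$rejected$reason[res$rejected$peptide == p6], "length")
  expect_equal(res$rejected$reason[res$rejected$peptide == p21], "length")
  # canonical mismatch: 0 mismatches rejected, exactly 2 accepted
  pep0 <- "MTAYIAKW"                    # not in canon; craft variants below
  hit0 <- "AATAYIAK"                    # windows of canonical 1
  stopifnot(grepl("ATAYIAK", canonical[1]))
  p_exact <- "ATAYIAKQ"                 # 0 mismatches to canonical
  seps2 <- c(sep1 = paste0("MW", p_exact, "WM"))
  r0 <- filter_and_map_peptides(mk_psm(p_exact), seps2, canonical)
  expect_equal(nrow(r0$accepted), 0)
  expect_equal(r0$rejected$reason, "canonical_match")
  p_one <- "ATAYIAKM"                   # 1 mismatch
  seps3 <- c(sep1 = paste0("MW", p_one, "WM"))
  r1 <- filter_and_map_peptides(mk_psm(p_one), seps3, canonical)
  expect_equal(nrow(r1$accepted), 0)
  p_two <- "ATAYIAMM"                   # 2 mismatches
  seps4 <- c(sep1 = paste0("MW", p_two, "WM"))
  r2 <- filter_and_map_peptides(mk_psm(p_two), seps4, canonical)
  expect_equal(r2$accepted$peptide, p_two)
  expect_equal(r2$accepted$min_mismatch, 2)
  # uniqueness across the SEP set
  shared <- "LLNNPPQ"
  seps5 <- c(sep1 = paste0("MA", shared, "KK"), sep2 = paste0("MC", shared, "RR"))
  r3 <- filter_and_map_peptides(mk_psm(shared), seps5, canonical)
  expect_equal(nrow(r3$accepted), 0)
  expect_equal(r3$rejected$reason, "not_unique")
  # low score rejected; decoy rows rejected; integrity error on bad claims
  r4 <- filter_and_map_peptides(mk_psm(p7, score = 1.9), seps, canonical)
  expect_equal(r4$rejected$reason, "score")
  r5 <- filter_and_map_peptides(mk_psm("WWWWWWW", "DECOY_1"), seps, canonical)
  expect_equal(r5$rejected$reason, "decoy_or_contaminant")
  expect_error(filter_and_map_peptides(mk_psm("WWWWWWW", "sep1"), seps,
                                       canonical), "integrity|substring")
})

test_that("accepted set is independent of rule evaluation order", {
  # acceptance is the conjunction of all rules; shuffling rows (a proxy for
  # evaluation order) cannot change the accepted set
  set.seed(4)
  seps <- c(sep1 = "MMKTAYIAKWWQISFVKLNDPQRS")
  canonical <- "MAAAAATAYIAKQQQQ"
  psms <- rbind(mk_psm("WWQISFV"), mk_psm("WWQISF"), mk_psm("TAYIAK"),
                mk_psm("WWQISFVKL", score = 1),
                mk_psm("KLNDPQRS", sample = "s2"))
  base <- sort(filter_and_map_peptides(psms, seps, canonical)$accepted$peptide)
  for (i in 1:5) {
    sh <- psms[sample(nrow(psms)), ]
    expect_identical(
      sort(filter_and_map_peptides(sh, seps, canonical)$accepted$peptide),
      base)
  }
})

test_that("SEP evidence tiers use the 10-PSM / 3-sample conjunction", {
  acc <- function(psm_counts, samples) data.frame(
    peptide = sprintf("PEPTIDEK%02d", seq_along(psm_counts)),
    sep_id = "sep1", sample = samples, psm_count = psm_counts,
    score = 3, stringsAsFactors = FALSE)
  tier_of <- function(psm_counts, samples)
    aggregate_sep_evidence(acc(psm_counts, samples))$tier
  expect_equal(tier_of(c(4, 3, 3), c("a", "b", "c")), "high")    # 10 PSMs/3 samples
  expect_equal(tier_of(c(3, 3, 3), c("a", "b", "c")), "none")    # 9 PSMs
  expect_equal(tier_of(c(2, 2, 2, 2, 1), c("a", "b", "c", "d", "e")), "none")
  expect_equal(tier_of(c(6, 6), c("a", "b")), "none")            # 2 samples
  ev <- aggregate_sep_evidence(acc(c(5, 5, 5), c("a", "a", "b")))
  expect_equal(ev$n_samples, 2)
  expect_equal(ev$total_psms, 15)
  expect_equal(ev$unique_peptides, 3)
  expect_equal(nrow(aggregate_sep_evidence(acc(1L, "a")[0, ])), 0)
})

test_that("tier is monotone when PSM rows are added", {
  set.seed(6)
  base <- data.frame(peptide = "AAAAAAK", sep_id = "sep1",
                     sample = c("a", "b"), psm_count = c(4L, 4L), score = 3,
                     stringsAsFactors = FALSE)
  rank <- c(none = 0, high = 1)
  t0 <- aggregate_sep_evidence(base)$tier
  more <- rbind(base, data.frame(peptide = "CCCCCCK", sep_id = "sep1",
                                 sample = "c", psm_count = 3L, score = 3))
  t1 <- aggregate_sep_evidence(more)$tier
  expect_gte(rank[[t1]], rank[[t0]])
})

test_that("immunopeptide filter keeps unique 8-15-mers absent from canon", {
  seps <- c(sep1 = "MMKTAYIAWWQISFVKLND", sep2 = "MGGHHEECCDD")
  canonical <- "MAAAAFEDCBAQQQQ"
  nine <- "TAYIAWWQI"
  expect_true(nine %in% filter_immunopeptides(nine, seps,
                                              canonical)$accepted$peptide)
  # 16-mer rejected; 7-mer rejected
  p16 <- substr(seps[["sep1"]], 2, 17)
  expect_equal(nrow(filter_immunopeptides(p16, seps, canonical)$accepted), 0)
  expect_equal(nrow(filter_immunopeptides("TAYIAWW", seps,
                                          canonical)$accepted), 0)
  # exact canonical substring rejected even if in a SEP
  shared <- "AAAFEDCB"
  seps2 <- c(sep1 = paste0("MK", shared, "WW"))
  expect_equal(nrow(filter_immunopeptides(shared, seps2,
                                          canonical)$accepted), 0)
  h <- filter_immunopeptides(nine, seps, canonical)$length_histogram
  expect_equal(unname(h[["9"]]), 1)
})

test_that("disordered fraction counts inclusively", {
  expect_equal(disordered_fraction(rep(0.9, 10))$fraction, 1)
  expect_true(disordered_fraction(rep(0.9, 10))$flag)
  r <- disordered_fraction(c(rep(0.5, 5), rep(0.4, 5)))
  expect_equal(r$fraction, 0.5)
  expect_true(r$flag)      # >= 50% content is inclusive
  set.seed(2)
  v <- runif(40)
  expect_equal(disordered_fraction(v)$fraction, sum(v >= 0.5) / 40)
  expect_error(disordered_fraction(c(0.1, 0.2), protein_length = 5),
               "length")
})
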
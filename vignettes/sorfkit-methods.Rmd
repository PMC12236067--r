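---
title: "sorfkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sorfkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the models and rules
each stage implements, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made. No empirical claim is
made here that the test suite does not itself compute.

## 1. ORFome construction

**Enumeration.** Every transcript is scanned in all three reading frames.
Each ATG that opens a run to the next in-frame stop codon yields a candidate
when the ORF is at least `min_codons` codons long (default 30, stop codon
excluded; the boundary is inclusive and configurable). Nested in-frame ATGs
each yield their own candidate; redundancy is resolved downstream by
clustering rather than by a longest-only rule, so internal-start isoforms
are not silently lost. Codons containing an ambiguous base (N) reject the
candidate outright — translating masked sequence to `X` would create
phantom proteins that the proteomic stage could never match. An ATG with no
downstream in-frame stop yields nothing: an ORF without a stop codon has no
defined product and no NMD status.

**The 50-nt NMD rule.** Transcripts whose termination codon sits far
upstream of the final exon–exon junction are degraded by nonsense-mediated
decay and are unlikely to produce protein. An ORF passes when its stop
codon's last base lies (i) in the last exon, or (ii) in the penultimate exon
within `nmd_window_nt` (default 50) of that exon's 3′ end — the distance is
the number of nucleotides strictly between the stop and the junction, so 49
passes and 50 fails — or (iii) wholly within the 5′ UTR of a transcript
with an annotated CDS. The third clause is the upstream-ORF exemption:
uORFs terminate upstream of the CDS by construction, yet their host mRNAs
are demonstrably stable, so the rule cannot sensibly apply to them.
Single-exon transcripts have no junction and always pass. Enlarging the
window can only convert failures to passes (tested as a property).

**Biotype assignment** follows a fixed precedence: 5′ UTR, 3′ UTR,
pseudogene, TEC, antisense lncRNA (genomic span overlapping a canonical
gene on the opposite strand), then intergenic lncRNA. The precedence is a
design choice made for determinism; it is recorded in output metadata. One
boundary case is deliberately stricter than the minimum reading of the
rules: *any* ORF overlapping its own transcript's canonical CDS is excluded
(reason `cds_overlap`), not only same-frame overlaps and boundary
straddlers. A different-frame ORF buried inside a CDS would otherwise fall
through to a lncRNA label, which is plainly wrong for an mRNA; exclusion is
the conservative resolution, and such ORFs are not the workflow's target in
any case.

**Read-through removal** treats a transcript as read-through when its exon
chain overlaps the canonical CDS of two or more distinct genes on the same
strand — the standard annotation-pipeline notion, chosen because the
operational definition had to be fixed somewhere and this one is exactly
testable.

**Redundancy clustering** is greedy in order of decreasing length (ties by
identifier): a protein joins the first cluster whose representative aligns
at ≥ `cluster_identity` (default 0.90), else founds one. Identity is
matches / alignment length with gap columns counted in the denominator,
under a global alignment with unit match score and zero mismatch score; an
infinitesimal gap-extension cost (1e-4) breaks ties toward the compact
alignment without ever changing the attainable match count. The
representative is the longest member. This reproduces the conventional
high-identity clustering used for protein database deduplication while
remaining exactly reproducible — no external binary, no heuristic
pre-filter.

## 2. Conservation

Scores are phyloP-like: per-nucleotide, positive under constraint. A
position is *conserved* when its score is strictly positive (a tie at
exactly 0 is non-conserved). Cutoffs are derived from canonical CDS, the
one class whose constraint status is not in question: the score cutoff is
the median of per-gene mean scores, and the fraction cutoff is the 25th
percentile (linear interpolation) of per-gene conserved-position fractions,
so that 75 % of canonical genes meet it by construction. An ORF is
classified conserved iff its mean score *and* its conserved fraction meet
the cutoffs, both boundaries inclusive. Positions absent from the track are
excluded from both numerator and denominator rather than imputed as zero —
imputation would deflate conservation wherever the track has gaps, which is
a property of the track, not of the sequence. ORFs with no scored position
are flagged and never classified conserved. Raising either cutoff can only
remove ORFs from the conserved set (tested as a property). The derived
cutoffs can be pinned to fixed values via the `cutoffs` argument when
reproducing a previously derived pair.

## 3. Ribosome occupancy

**TPM with ORF length.** Footprint counts are normalized to transcripts per
million using the ORF length, not the transcript length, as the length
term: footprints are confined to the translated frame, so transcript-length
normalization would systematically deflate short ORFs on long transcripts.
The denominator sums over all ORFs present in the supplied matrix
(canonical and novel together); the choice of universe is recorded in the
output header since TPM values are only comparable within one universe.

**Tiers.** Detection defaults to a nonzero count in a sample. Per-sample
translation calls from an external caller can replace this via a boolean
`detection` matrix, in which case the package's tiers reproduce that
caller's semantics exactly; the caller's phase-score cutoff (0.440 in the
upstream toolchain) is passthrough metadata, not something this package
computes. High confidence requires detection in ≥ 40 samples across ≥ 4
independent datasets with median TPM over detected samples ≥ 1; low
confidence requires ≥ 20 samples. The median is taken over detected samples
only (configurable to all samples) — with hundreds of samples of which most
may not express a given ORF, an all-sample median would be dominated by
zeros and the criterion would become a detection-rate criterion in
disguise. Adding a detection can never demote a tier (tested as a
property).

**NB2 dispersion.** Counts for one ORF across samples are modelled as
negative binomial with mean μ_j = rate · T_j (log link, offset log T_j,
T_j the sample's total reads) and variance μ(1+αμ). The likelihood is
maximized over (log rate, log α) with L-BFGS-B (gradient tolerance 1e-8,
at most 200 iterations), initialized by method of moments; when the moment
variance does not exceed the mean, α starts at the floor 1e-8, which is
also the lower optimization bound, so Poisson-like rows fit cleanly instead
of diverging. Each ORF is fitted independently — no shrinkage across ORFs —
because the quantity of interest is the per-ORF dispersion itself, which
shrinkage would bias toward the trend. All-zero rows are flagged and not
fitted (rate 0, α undefined). The optimum likelihood is checked against the
moment start for every row.

## 4. Proteomic evidence

Peptides must score ≥ 2 (a cross-correlation-type search score consumed,
not computed — FDR control happens upstream in the search engine), be 7–20
aa, map to exactly one SEP representative, and differ from every
equal-length window of every canonical protein by at least 2 substitutions.
The mismatch search is an ungapped Hamming-window scan: for 7–20-aa
peptides at ≤ 2 substitutions it agrees with a short-peptide protein
alignment search (a gapped alignment at these lengths would imply an indel,
which the SNP rationale for the filter does not cover), and it is exactly
testable against a brute-force oracle. Isoleucine and leucine are treated
as distinct residues by default (`collapse_il = FALSE`); they are isobaric
in mass spectrometry, so a stricter analysis may collapse them, which makes
the canonical filter more aggressive. Peptide uniqueness is assessed
against representatives after clustering, so a peptide shared only among
members of one cluster still counts as unique. A SEP is high-confidence
with ≥ 10 PSMs in ≥ 3 samples; "sample" means a distinct sample identifier
as given — fractions or runs are not distinguished because the inputs do
not distinguish them. Acceptance is a pure conjunction, so the accepted set
is independent of rule order; only the *reported reason* for a rejected
peptide follows the fixed order score, length, decoy, uniqueness,
canonical-match.

Immunopeptides follow the MHC-I convention: 8–15 aa, unique to one SEP, and
rejected on any exact canonical substring match (one mismatch suffices to
keep, since HLA peptides are not tryptic and the SNP argument does not
apply). Disorder content is a simple per-residue count: residues with
disorder score ≥ 0.5 are disordered, and a SEP is flagged when at least
half its residues are.

## 5. Differential abundance

Proteins missing in strictly more than 50 % of samples are dropped.
Probabilistic quotient normalization divides each sample by the median of
its per-protein quotients against the reference profile (per-protein median
across samples, observed values only); the defining property — median
quotient exactly 1 against that reference after scaling — is asserted in
the tests. After log2 transformation, missing values are imputed with a
left-censored Gibbs sampler: per protein, observed values are
Normal(m, s²) under a conjugate normal-inverse-gamma prior (prior mean =
observed mean, one pseudo-observation, shape 1, scale = observed variance —
proper but weak), and the sampler alternates drawing (m, s²) from the
conjugate posterior given the completed data with drawing each missing cell
from Normal(m, s²) truncated above at its censoring limit. The limit is the
per-sample minimum observed value — the operational detection floor of that
sample; a global-quantile alternative can be chosen by flag. The imputation
is the posterior mean over post-burn-in sweeps (default 1000 sweeps, 200
burn-in), with the per-cell posterior SD exposed so unstable cells can be
flagged; single imputation keeps the downstream tables simple, and the SD
carries the uncertainty that multiple imputation would.

The tumor/normal contrast is a Welch two-sample t test (unpaired) or a
one-sample t test on within-pair differences (paired), with BH adjustment
across all tested proteins. For a balanced two-condition design with a
per-individual random intercept the paired t test is exactly equivalent to
the mixed-effects formulation, which is why the simpler contrast is used;
for unbalanced designs this is a documented simplification. Proteins
constant across all samples get p = 1 and a flag rather than an error.

## 6. Variants and GWAS

Variant positions are 1-based (VCF convention); ORF blocks are 0-based
half-open internally; the conversion lives in one function. Only
single-nucleotide variants are processed; indels and multi-allelic records
are rejected with a counted warning. COSMIC records are kept when
FATHMM-MKL > 0.7 (strictly); CADD Phred > 15 (strictly) flags
deleteriousness on any record; records lacking the relevant score pass
through with a provenance note rather than being silently dropped — a
missing score is not evidence of benignity. Consequence annotation projects
the position through the exon chain (complementing alleles on the minus
strand), substitutes within the affected codon, and classifies synonymous /
missense / stop gain / stop loss / start loss; a reference-base mismatch
against the transcript sequence is a hard error because it means the
variant table and genome disagree. GWAS SNPs require study n ≥ 10,000 and
P ≤ 5×10⁻⁸, both inclusive as printed; the region-based aggregation test
used alongside SNP mapping in large-scale analyses needs an external LD
reference and is out of scope here.

## 7. The synthetic world

`generate_toy_annotation` builds a single contig carrying canonical
three-exon mRNAs (annotated CDS, stop in the last exon), uORFs and 3′ UTR
sORFs embedded in the UTRs, antisense lncRNAs placed on the opposite strand
inside host-gene introns (so their spans overlap the gene and the biotype
rule is decidable), intergenic lncRNAs/pseudogenes/TEC transcripts ≥ 1 kb
from every gene, on both strands. Every planted sORF is an intact
ATG→stop frame of ≥ 30 codons whose coordinates, protein, NMD status,
translation status, conservation status, NB rate/dispersion and relative
protein abundance are recorded in the truth table. Each simulated artifact
draws from its own RNG substream derived from the master seed by a label
hash, so adding one simulator never shifts another's draws, and identical
(config, seed) pairs reproduce byte-identical files. GTF output is 1-based
inclusive, BED 0-based half-open, internal coordinates 0-based half-open —
each format's own convention.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| `n_canonical_genes` | 20 | enough CDS (> 10 kb) for stable cutoff derivation at toy scale |
| `fraction_translated` | 0.5 | balanced classes so precision and recall are both informative |
| `n_datasets` × `samples_per_dataset` | 6 × 20 | the smallest layout in which the 40-sample / 4-dataset tier is comfortably reachable |
| `rate_translated` / `rate_noise` | 2e-7 / 2e-9 per nt per read | mean counts of tens vs well below one at 0.5–2M-read libraries |
| `alpha_translated` / `alpha_noise` | 0.3 / 2.0 | canonical-like vs strongly overdispersed footprint behaviour |
| `zero_inflation_noise` | 0.7 | zero-heavy stochastic noise ORFs |
| `cons_mu_cds` / `cons_mu_neutral` / `cons_sigma` | 2.0 / −0.5 / 0.3 | clear constrained-vs-neutral separation in phyloP-like units |
| `cons_sorf_margin` | 0.5 | see below |
| `tmt_effect_size`, `tmt_sigma`, n/group | 1.0, 0.5, 10 | a standardized effect of 2, typical of detectable proteomic changes |
| `censor_quantile` | 0.2 | realistic left-censored missingness for intensity data |

`cons_sorf_margin` exists because the conservation cutoff is the *median*
of canonical per-gene means: elements drawn exactly at the canonical mean
would straddle their own cutoff and the planted conserved class would be
unrecoverable by construction (a coin flip, not a hard task). Conserved
sORFs are therefore planted half a unit above the canonical median —
clearly constrained elements — while canonical CDS remain exactly at
`Normal(cons_mu_cds, cons_sigma)`. The margin was fixed once, from this
argument, not tuned against test outcomes.

What the generator deliberately does **not** emulate: raw reads or spectra
(counts, PSMs and intensities are drawn at the level the analysis
consumes); genome-scale sequence composition, repeats, paralogy or
alignability; isoform complexity beyond one transcript per gene;
search-engine score distributions beyond a two-class surrogate;
batch/channel structure in the intensity matrices; linkage disequilibrium
among GWAS SNPs. A green test therefore establishes that the *rules and
statistics* are implemented correctly and recover planted structure under
the stated noise model — not that the workflow's biological error rates on
real data match any published figure.

## 8. Numerical and degenerate-input conventions

Percentiles use linear interpolation (R type 7) everywhere. The NB2 α is
bounded in [1e-8, 1e6] on the log scale; rates are bounded 20 log-units
around the moment start. Truncated-normal draws use the inverse-CDF method
with the uniform clamped away from 0/1, and a final `pmin` guard enforces
the truncation bound against floating-point round-off. Ties: identity
clustering breaks length ties by identifier; the tier and filter boundaries
are inclusive exactly where the rules say "at least"/"≥" and strict where
they say "more than"/">". Degenerate inputs (all-zero count rows/columns,
empty protein sets, empty variant tables, proteins with < 2 observed
intensities, samples with no reference overlap) return flagged empty
results or documented fallbacks rather than errors, except where the input
contradicts itself (peptide not contained in its claimed SEP,
reference-base mismatch, malformed exon chains), which fail loudly.

## 9. Known limitations

AUG-only starts (near-cognate initiation is out of scope by design); no
P-site-level translation calling (external calls can be injected via the
detection matrix); per-ORF dispersion without shrinkage is noisy below ~50
samples; the Hamming-window canonical filter does not credit gapped
similarity; single imputation understates downstream variance relative to
multiple imputation (the posterior SD is exposed to compensate); the
synthetic world's simplifications listed above.
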
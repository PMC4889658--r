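---
title: "Measuring exon-intron architecture: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring exon-intron architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The pipeline quantifies three intertwined
properties of protein-coding gene architecture: the strength of splice
sites, the size of intron-plus-next-exon (IpE) units — the distance
between two consecutive donor splice sites, which is the interval a
5′ss-bound U1 snRNP can shield from premature cleavage/polyadenylation —
and the strand asymmetry of polyadenylation-signal and donor-site-like
hexamers inside exons and introns.

## The survey: from annotation to records

One isoform per protein-coding gene is drawn uniformly at random. Using a
random isoform rather than the longest avoids the systematic bias toward
long first exons and long genes that longest-isoform selection introduces;
the draw is governed by a single seed and logged so a survey is exactly
reproducible. Introns are the gaps between consecutive exons in transcript
orientation; all records (sequences, windows, ordinals) are reported 5′→3′
along the transcript, with minus-strand features reverse complemented.

A surveyed intron must satisfy three filters:

* **Size ≥ 32 nt.** The donor model reads 6 intronic nt and the acceptor
  model reads 20 intronic nt; 6 + 20 = 26 ≤ 32 guarantees the two training
  windows never overlap inside one intron, so no dinucleotide is counted
  by both models.
* **Canonical GT..AG termini**, restricting the survey to
  major-spliceosome introns.
* **No nested gene.** A nested gene's own promoter, splice sites, and
  compositional biases would contaminate the host intron's motif counts.
  The default test flags an intron when another gene's genomic span (either
  strand) is fully *contained* in it; an `overlap` mode (≥ 1 nt of
  overlap) is available, since "nested" could reasonably be read either
  way. Containment is the default because partial overlaps are usually
  annotation disagreements at gene boundaries rather than genes inside
  introns.

Genes with fewer than two surviving introns are then dropped entirely, so
every surveyed gene contributes a first and a last intron and the
positional classes are comparable across genes.

Coordinates are handled in the Bioconductor convention, 1-based inclusive,
end to end (GTF is already 1-based inclusive); only the BED6 export
converts to 0-based half-open, at a single documented boundary.

## Splice-site strength

Strength is a log-likelihood ratio in bits, `log2(P_signal/P_background)`,
of a site's fixed window: 9-mer donors (last 3 exonic + first 6 intronic
nt) and 23-mer acceptors (last 20 intronic + first 3 exonic nt). Both
distributions are maximum-entropy models: the least-committed distribution
over all 4^k windows that reproduces the empirical joint frequencies of
the training windows on a chosen family of position subsets. This captures
adjacent-position dependencies (e.g. between the exonic tail and the U1
pairing region) that a position weight matrix cannot, while remaining
estimable from a few thousand sites.

* **Donor (k = 9):** dense fit with singleton plus all adjacent-pair
  constraints, by iterative proportional fitting (IPF) — a sequential
  variant of generalized iterative scaling whose training likelihood is
  non-decreasing and which terminates when every constrained marginal is
  within `tol` of its target.
* **Acceptor (k = 23):** too wide for dense enumeration, so the
  distribution is factorized along a chain of three 9-position fragments
  with 2-position overlaps (positions 1–9, 8–16, 15–23). Each fragment is
  a dense fit; dividing each later fragment by its overlap marginal turns
  the product into a chain of conditionals, so the factorized model is
  exactly normalized by construction. The obligate AG (window positions
  19–20) contributes no score because signal and background both fix it.
  The layout is configurable; any chain that covers the window is valid.

**Pseudocounts.** One count is added to every cell of each *maximal*
constraint's marginal table; targets of subsets contained in a maximal one
are derived by marginalizing that table. Deriving rather than
independently pseudocounting the non-maximal targets keeps the whole
target family self-consistent, which is what guarantees IPF convergence.
With pseudocount 0 a zero empirical cell is allowed (the fit carries
genuine zeros) but a warning is raised because such models can produce
infinite scores. Defaults: pseudocount 1, `tol` 1e-4 on marginals,
10,000 sweeps maximum (typical fits converge in well under 100).

**Background.** The default decoy background is trained on pre-mRNA
windows that carry the obligate dinucleotide at the splice-site offset
(GT at intronic +1/+2, AG at −2/−1) but are not annotated sites — the
natural "could be mistaken for a site" ensemble. A zero-order
mononucleotide background is available when transcript sequences are not
at hand; scores shift by a calibration constant but orderings are
essentially preserved.

Scores are summarized in empirical quartiles (type-7 percentiles at
25/50/75%), labelled weak → strong, with boundary values assigned to the
lower class.

## Strand asymmetry

For a motif m, `S = (Ns − Na)/(Ns + Na)`, with Ns and Na the
overlap-inclusive counts of m and of its reverse complement in a region
set's sense-strand sequence. Under Chargaff's second parity rule a neutral
region has S ≈ 0; persistent negative S is read as counter-selection of
the motif on the sense strand. Counting is restricted to trimmed
interiors — exons lose 3 nt at each end (splice-site cross-talk), introns
lose 6 nt at the 5′ end (donor signal) and 40 nt at the 3′ end
(polypyrimidine tract and branch site) — so the asymmetry of the splicing
signals themselves never leaks into the motif counts. Overlap-inclusive
counting is used because the studied hexamers self-overlap (a 10-nt A-rich
run can contain two AATAAA) and because it is deterministic and trivially
oracle-checkable.

S per group is computed from pooled counts (the ratio of summed counts),
which weights every nucleotide equally; the mean of per-region S values is
reported as a secondary column since the two conventions differ on skewed
region-size distributions and the convention used by any given published
table is rarely stated. Anagram controls (TAAAAA, AAAAAT) are profiled on
the same regions to flag dinucleotide-composition artifacts.

The co-occurrence analyses (GGTAAG × AATAAA by intron size class;
positional distribution of AATAAA relative to the first 500 nt of
~1000-nt introns; 5′/3′ ordering of the closest GGTAAG–AATAAA pair) use
uncorrected Pearson chi-square statistics — expected counts at survey
scale are large, and the uncorrected statistic is the one whose null
calibration the tests verify. Positional expectations are proportional to
searchable interior length on each side of the boundary.

## Rank statistics and the randomization test

Sliding-window medians (default: windows of 2000 observations, step 1,
after a stable sort on the ranking variable) are for *visualising* trends;
every reported correlation is computed on raw data, never on windowed
medians, because windowing inflates correlation magnitudes. Kendall
tau-b (tie-corrected) is the correlation of record; partial tau removes
the rank association explained by a third variable via the closed form
`(τ_xy − τ_xz τ_yz)/√((1−τ_xz²)(1−τ_yz²))`, with a normal-approximation
p-value that is explicitly approximate.

The IpE randomization test asks whether the observed sizes of
intron + next-exon units in a positional group could arise from free
combination: each replicate pairs as many introns and exons as observed,
both resampled uniformly with replacement from the group's pools, and
compares the resulting size distribution to the observed one with a
two-sample Kolmogorov–Smirnov test (asymptotic p — at survey scale the
exact computation is unnecessary and ties are rare on real length data).
The overall P is the *fraction of replicates whose KS test is
nonsignificant* (p ≥ alpha): the probability that a random pairing is
indistinguishable from the real architecture. A verbal definition of this
quantity can be read two contradictory ways ("times the test was
nonsignificant (P < 0.05)"); this package fixes the nonsignificant
reading, under which overall P ≈ 1 − alpha under a true null and ≈ 0 when
intron and exon sizes are genuinely coupled. Note that a single run's
overall P is conditional on the observed sample: its spread across data
realizations exceeds the pure Monte-Carlo error of the replicate count,
which is why calibration checks fix the data seed.

Defaults: 100,000 replicates at alpha 0.05. The test suite and the
acceptance script run 2,000 replicates — chosen as the smallest count
whose Monte-Carlo error (~0.005 on overall P) is negligible against the
0.02 calibration band.

## The synthetic genome generator

The generator emits FASTA + GTF + a ground-truth table such that running
the extraction pipeline on the files reproduces the truth records exactly.
It emulates precisely the statistical signatures the pipeline measures:

* **Per-class length distributions.** Intron lengths are log-normal with
  per-class medians 145 / 69 / 65 nt (first / internal / last) and
  log-sds 2.18 / 2.35 / 1.90 chosen to reproduce the heavy mean-to-median
  ratios characteristic of fly introns (first introns average an order of
  magnitude above their median); draws are clamped to [32, 50000] nt —
  clamping (rather than resampling) leaves the median untouched. Exon
  medians are 230 / 233 / 212 / 596 nt for first / second / internal /
  last. The first-exon distribution (median 230, log-sd 0.9) puts roughly
  half the genes on each side of the 250-nt cap-proximal boundary so both
  first-unit classes are populated.
* **Splice signals with a strength dial.** Donor and acceptor windows are
  drawn from consensus position-probability models interpolated toward
  the background composition by a per-intron sharpness w ∈ [0,1]; GT/AG
  are fixed so every emitted intron is canonical. A shared Gaussian
  latent per intron drives both the length quantile and w, so the
  realized Kendall tau between length and the *latent* sharpness is
  exactly `2/π·asin(rho)`; the tau recovered through fitted scores is
  attenuated by estimation noise but preserves the sign — which is what
  the recovery tests assert.
* **Motif planting.** Motifs are inserted at Poisson sense/antisense
  rates per kb of plantable interior, never touching splice-site windows
  or each other, so the planted asymmetry of a region set converges to
  `(rs − ra)/(rs + ra)`. The default background is 60% AT (fly introns
  are AT-rich), which matters for false-positive motif matches:
  spontaneous AATAAA occurrences are strand-symmetric and dilute a
  planted asymmetry toward 0 — exactly the artifact the anagram controls
  diagnose on real data. Recovery checks therefore plant a GC-rich probe
  hexamer (GCCGCC) whose spontaneous rate in an AT-rich background is
  negligible, at a 3:1 ratio (expected S = 0.5).
* **Nested genes** (optional fraction) embed a small two-exon gene inside
  a large intron to exercise the nested-gene filter.

What the generator does **not** emulate: codon structure and UTR/CDS
composition differences, positional autocorrelation of base composition,
alternative isoforms (one transcript per gene is emitted; isoform
sampling is exercised on hand-built annotations in the tests),
chromatin- or expression-linked covariates, and any mechanistic model of
transcription or telescripting. Passing recovery tests therefore
demonstrates that the *measurement machinery* is unbiased and correctly
plumbed end to end on data of realistic scale and composition — not that
the biological conclusions drawn from any particular real genome are
right.

## Problem sizes and reproducibility

The test suite validates on genomes of 60–400 genes; the end-to-end
recovery check and the acceptance script use ~800–1250 genes
(~3000–5000 introns), sizes at which median, asymmetry, and correlation
recovery bands are a few percent wide. A single master seed fans out to
named substreams (isoform lottery, decoy sampling, randomization,
synthesis), so stages are independently reproducible; regenerating with
the same spec is byte-identical, and model serialization round-trips
byte-identically.

## Known limitations

* Acceptor factorization with fully constrained 9-mer fragments estimates
  higher-order dependencies than the donor's pairwise model; with small
  training sets the acceptor model is correspondingly noisier.
* Decoy backgrounds depend on the annotation's completeness:
  unannotated real splice sites in the decoy pool compress scores.
* Partial-tau p-values use a normal approximation on the transformed
  statistic.
* Exact-hexamer counting only; no PWM-based polyadenylation-signal
  scanning, no branch-site model, and no handling of minor-spliceosome
  (U12) introns beyond the GT..AG filter.
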
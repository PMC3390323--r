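---
title: "Methods: DGE tag profiling, the exact tag-count test, and the supporting analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DGE tag profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

This vignette is the package's account of the science it implements: the
assumptions behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical and design choices that were
genuinely open.

## The assay

NlaIII/MmeI digital gene expression tag profiling reduces each polyadenylated
transcript to a 21-bp signature: NlaIII cuts cDNA at every `CATG`; the
3'-most site survives on the oligo-dT bead; MmeI then cuts 17 bp
downstream of that `CATG`, releasing a `CATG` + 17-base tag that is
sequenced as part of a 35-bp read (tag plus 3' adaptor). Counting reads
per tag therefore counts transcripts, provided the tag can be assigned to
a unique gene. Two structural consequences drive the whole pipeline:

* a transcript with no `CATG` followed by at least 17 bases is invisible
  to the assay (in the simulated uniform-composition transcriptomes with
  lengths 200–2000 bp this affects a few percent of genes, matching the
  ~92 % `CATG`-bearing fraction typical of real transcript catalogs);
* the observable tag universe can be enumerated in advance — the
  "virtual library" of all `CATG`+17-mers in the reference transcripts,
  on both strands, which is what `build_tag_index()` builds.

## Cleaning rules and their order

`clean_reads()` applies the standard six rules: trim to the first 21
bases, drop adaptor-only (empty) reads, drop tags containing `N`, drop
tags not exactly 21 bp, aggregate to counts, drop copy-number-1 tags.
Two points were open and are fixed here:

* **Order.** Singleton removal must follow aggregation to be
  well-defined, so the order is trim → empty → N → length → anchor →
  aggregate → singleton.
* **Anchor rule.** Tags whose trimmed prefix is not `CATG` cannot come
  from a genuine NlaIII site. They are removed under their own ledger
  entry (`no_anchor`) rather than being left to fall into the mapper's
  "unknown" category; this keeps the downstream category accounting
  about biology (organellar, genomic, novel transcripts) rather than
  about read structure.

The ledger is disjoint and exhaustive — `raw_total = clean_total +
sum(ledger)` is asserted property-style in the tests — and cleaning is
idempotent.

## Mapping policy

`map_tags()` assigns each distinct clean tag by a two-dimensional
precedence: compartment-major (gene > mitochondrion > chloroplast >
genome, mirroring the conventional category table ordering), tier-minor
(exact match before 1-mismatch within each compartment). Choices made
where the convention is silent:

* **Mismatch region.** The single tolerated mismatch may fall only in
  the 17 variable bases, never in the `CATG` anchor: the anchor is an
  enzymatic constant, not a sequenced-variable region. This also shrinks
  the 1-mismatch search to 51 variants per tag.
* **Ambiguity.** Hits on several distinct genes at the deciding tier
  make a tag `gene_ambiguous`, excluded from per-gene counts; several
  sites *within* one gene (or both strands of one gene) stay
  unambiguous for that gene. A tag with one exact gene hit is
  unambiguous even if other genes sit at distance 1.
* **Strand.** An unambiguous tag hitting both strands of its gene counts
  as sense (the rarer antisense signal should not absorb sense mass).

The implementation is verified against an exhaustive Hamming-distance
oracle (distance matrix over all index keys, same precedence re-derived
with independent code) on 100 random toy transcriptomes, and the category
totals are asserted to partition the clean totals exactly.

## Quantification

TPM here is *tags per million clean tags*: `count × 10⁶ / clean_total`.
The denominator is deliberately the clean-tag total, not the mapped
total — that is the defining convention for this assay — so TPM sums to
10⁶ × (mapped fraction). Abundance distributions use bins [2,5], (5,100],
(100,∞): the conventional category edges overlap at 5 and 100, and the
closed-left reading was fixed and documented. Saturation analysis
subsamples the clean-tag stream with *nested* subsamples under one seeded
permutation, which makes the detected-gene curve deterministically
non-decreasing; the plateau is reported at the first grid step whose
relative gain falls below 1 % (configurable).

## The exact test

For tag counts the Audic–Claverie conditional is the natural test: given
count $x$ in a library of $N_1$ tags, the count $y$ in a library of $N_2$
tags has

$$p(y\mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{\!y}
\frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

a negative-binomial distribution in $y$ with size $x+1$ and success
probability $N_1/(N_1+N_2)$ — the closed form used as an independent
cross-check in the tests, while the implementation evaluates the formula
directly via log-gamma so counts of order $10^6$ cannot overflow.

Numerical choices:

* **Two-sidedness.** $p = \min(1,\, 2\min(P(Y\le y),\,P(Y\ge y)))$ —
  doubling the smaller tail rather than summing equal-probability
  extremes; both constructions appear in the literature, doubling was
  chosen and is stated here.
* **Truncation.** The upper tail is summed forward from $y$ in blocks and
  truncated once past the distribution mode when the last term falls to
  $10^{-16}$ of the running sum (a non-strict comparison, so the loop
  also terminates when both sides underflow to zero).
* **Conditioning asymmetry.** The test conditions on the first library's
  count, so swapping the libraries changes p-values slightly (ratios and
  directions mirror exactly); this is a property of the test itself, not
  of the implementation, and the tests assert the mirror-symmetry that
  does hold.
* **Library size.** $N$ is the clean-tag total (the same denominator as
  TPM), not the mapped total; a flag is available via the `total_a` /
  `total_b` arguments.

Significance uses FDR ≤ 0.001 **and** p ≤ 0.01 **and** |log₂ ratio| ≥ 1,
boundary ties included; all three thresholds are arguments. For the
ratio only, zero counts are floored at 0.5 tags before TPM conversion
(p-values always see the true zeros); a double-zero gene gets ratio 1.
BH adjustment is the standard step-up (`stats::p.adjust`).

Calibration is checked, not assumed: on 20-seed null simulations (2000
genes, two multinomial libraries of 10⁶ tags each) the fraction of genes
with p < 0.05 stays at or below 0.05 within Monte-Carlo error, and on
planted 4-fold simulations the empirical false-discovery proportion at
the full threshold rule stays ≤ 0.05.

## Enrichment

Over-representation only (upper hypergeometric tail via
`stats::phyper`), since that is what this kind of study reports. BH
correction is applied within each GO namespace separately (and across
pathways), a scope choice that is not universal and is therefore exposed
by simply passing an annotation with or without a `namespace` column.
GO-DAG propagation is out of scope: terms are treated as flat labels.

## geNorm and Pfaffl

Reference-gene stability follows geNorm: pairwise variation $V_{jk}$ is
the SD (n−1 denominator — the secondary literature is ambiguous, n−1 was
fixed) across samples of per-sample log₂ quantity ratios; $M_j$ is the
mean over partners; stepwise exclusion drops the highest-M gene
(lexicographic tie-break, documented) until two remain. Normalization
factors are per-sample geometric means of the $n$ most stable genes, and
$V_{n/n+1} < 0.15$ decides how many references suffice, never fewer than
3 (geNorm convention; with all-identical candidates every $V$ is 0 and
the answer is 3). Pfaffl quantification is implemented as its per-gene
kernel $q(g,s) = E_g^{\,Ct(g,\mathrm{cal}) - Ct(g,s)}$ with efficiency
defaulting to 2; standard-curve fitting of $E$ is routine lab practice
and out of scope.

## Phenotype indices

K content arrives as percent of dry weight and is converted to mg/g with
the factor 10 before use: K accumulation = content (mg/g) × dry weight
(g), KUE = dry weight × 1000 / content (mg/g), so
`k_accumulation × kue = 1000 · w²` exactly — an identity the tests
exercise. "Ground biomass" is read as shoot mass and root = total −
ground; this interpretation reproduces the published shoot/root column
(5.40, 2.10, …) exactly, which is the validation. The published KUE
relative-index column exceeds 1 and its formula is not derivable from
the stated definitions; it is deliberately not reproduced.

## What the generator emulates — and what it does not

`simulate_truth()` + `simulate_libraries()` emulate the eight-library
design (2 genotypes × 2 tissues × 2 periods) with:

* log-normal baseline expression (meanlog 0, sdlog 1) — a standard,
  deliberately simple abundance model; fold changes are planted
  multiplicatively (default 4-fold, never below 2 so planted genes are
  detectable in principle at |log₂| ≥ 1), only among genes that carry a
  usable tag site, because the assay cannot see the others;
* multinomial tag sampling at exact depth; per-base substitution error
  (default 1 %) on the 21 tag bases; a fixed synthetic 14-mer adaptor and
  adaptor-only reads (default 5 %);
* antisense transcription at 20 % of gene-tag mass, drawn from the
  3'-most `CATG`+17 site of the reverse-complement strand — a naive
  reverse complement of the sense tag would lack the `CATG` anchor and
  be (correctly) discarded by cleaning, so the anchored antisense site is
  the faithful emulation; the default 20 % sits near the ~23 % antisense
  fraction reported for real libraries;
* organellar/genomic decoys at rates typical of real category tables (mitochondrion
  5 × 10⁻⁵, chloroplast 0.4 %, genome 10 %).

Not emulated: quality scores and quality-dependent error, PCR
duplication, MmeI star activity, positional/sequence-composition biases,
incomplete reference catalogs (the main source of real "unknown" tags —
here unknowns arise only from sequencing error), and biological
replicate variability (each library is a single multinomial draw, which
is exactly the sampling model the exact test assumes). Passing tests
therefore demonstrate correctness of the pipeline's accounting and
calibration of the test under its own sampling assumptions — not
robustness to overdispersion across biological replicates, for which
dispersion-based count models would be the right tool and are a
non-goal here.

Ct simulation plants reference-gene (in)stability as per-gene Gaussian
Ct noise (cycles) on top of a shared per-sample input offset and a
per-gene baseline; the offset cancels in pairwise ratios, so the planted
noise SD is the direct target of the geNorm machinery. The recovery
experiment (2 planted unstable of 5, noise 1.0 vs 0.15 cycles, 8
samples) is recovered in ≥ 95 of 100 seeds.

## Problem sizes used by the test suite

Chosen as desk-scale versions of the real design that keep the full suite
in minutes while leaving the statistical checks well-powered: toy
transcriptomes of 8 genes for oracle equivalence (100 replicates);
1000-gene transcriptomes at 10⁶ tags per library for the end-to-end
experiment (the real study sequenced ~66 000 genes at ~6 × 10⁶ tags);
2000 genes × 10⁶ tags × 20 seeds for calibration. All generator seeds are
fixed in the tests; every simulation function is bit-reproducible for a
fixed seed.

## Known limitations

* Mapping precedence is compartment-major; a tag with an exact organellar
  hit and a 1-mismatch gene hit is assigned to the gene. The reverse
  (tier-major) convention is defensible too; the choice is documented
  above and enforced consistently against the oracle.
* The exact test treats each library as one multinomial draw;
  replicate-level dispersion is not modeled.
* The saturation plateau depth depends on the grid supplied; it reports
  the first grid point below the gain threshold, not an interpolated
  depth.
* Term enrichment ignores the GO hierarchy.
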
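---
title: "Models and methods behind haplosel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind haplosel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`haplosel` analyses how haploid-biased (male), diploid-biased (female)
and constitutively expressed genes of a haplodiploid genome differ in
polymorphism, divergence, selection, composition and recombination.
This vignette documents the models, the tunable parameters and their
defaults, the synthetic world the generator emulates, the numerical
choices, and the limits of what a green test establishes.

## 1. Expression classification

Counts are filtered (genes with fewer than 10 reads across all samples
are dropped), normalized by median-of-ratios (the size factor of sample
*j* is the median over genes nonzero in every sample of
count~gj~ / geometric-mean~g~), and compared pairwise between
(sex, tissue) groups by a two-sided Welch *t*-test on log2(x+1), with
Benjamini–Hochberg adjustment within each comparison.

A gene joins a (sex, tissue) set iff its fold change points toward that
group **and** q < 0.01 in *every required comparison* for the group:
against the opposite-sex group of the same tissue and against same-sex
groups of other tissues. Labels: member of ≥1 male set and no female
set → `haploid_biased`; symmetric for `diploid_biased`; members of sets
of both sexes → `constitutive`; otherwise `unclassified`. Adult and
larval datasets are classified separately and merged by union of set
memberships; a gene called haploid-biased in one dataset and
diploid-biased in the other is demoted to `unclassified` with a warning
(the merger is otherwise silent on how such conflicts should be read,
so the conservative choice is made).

The published analysis used a shrinkage-based DE package; re-deriving
its dispersion estimators is out of scope here and would add nothing to
the classification *logic*, which is the part under test. The Welch
test on normalized log counts is fully specified, assumption-light, and
calibrated on the synthetic data (type-I tests at three seeds confirm
the haploid-biased false-call rate stays at alpha-level noise).

## 2. Sites, diversity, divergence

Synonymous (Ls) and nonsynonymous (Ln) site totals use Nei–Gojobori
(1986) equal-weight counting: per codon, ls is the number of the nine
single-nucleotide changes that are synonymous, divided by 3; ls+ln = 3.
Changes creating stops are nonsynonymous; reference stop codons
(terminal or internal) are excluded from all denominators, and genes
whose reference CDS carries an internal stop are excluded entirely with
a warning (effect classification is undefined for them).

Per-site diversity is the unbiased estimator
π = (n/(n−1))·(1 − p² − q²). Gene-level πS (πNS) sums site π over
classified variants with minor-allele frequency strictly above 0.01 and
divides by Ls (Ln). With the default 22 sampled allele copies the MAF
filter excludes nothing (min MAF ≈ 0.045) — it only bites for larger
samples — but it is implemented and tested because it is part of the
contract. The MAF filter applies to diversity only, not to the Pn/Ps
counts that enter MK/DoS (a flag enables filtering there too).

Polymorphisms are classified by applying the focal variant alone to the
reference codon; codons carrying two polymorphisms are classified
per-variant independently. Divergence counts a site only when the
ingroup is monomorphic (absent from the VCF, AC = 0, or AC = AN) and
differs from the single haploid outgroup allele; codons with several
fixed differences are counted by averaging synonymous/nonsynonymous
steps over the minimal mutational paths, excluding paths through
intermediate stops (if all are blocked, all paths are used with
stop-creating steps counted as nonsynonymous). Ingroup-fixed sites with
no outgroup call cannot be polarised and are skipped with a log entry.
Whether the original study's diversity tool used the n/(n−1) correction
or how it resolved multi-variant codons is unstated; these choices are
therefore declared here rather than inferred.

## 3. Selection statistics

DoS = Dn/(Dn+Ds) − Pn/(Pn+Ps), undefined (NA) when a denominator is
zero. The MK test is the Pearson χ² (df = 1) on [[Dn,Ds],[Pn,Ps]]
without continuity correction — the plain "χ² test" reading; a Yates
flag exists but defaults off for determinacy. Degenerate margins give
χ² = 0, p = 1. The positive-selection flag is MK p < 0.05 **and**
DoS > 0: the source text prints "DoS > 1", which is unsatisfiable for a
statistic bounded in [−1, 1], so 0 is the default and the threshold is
a parameter.

## 4. The relaxed-selection null model

The expected dN/dS of a gene class is the relative fixation rate of a
semidominant mutation, ω(g) = g/(1 − e^(−g)), evaluated at
g = c·γ where γ = 2·Nₑ·s and c ∈ (0,1] is an **exposure coefficient**:
the fraction of selection the class "sees". Defaults: constitutive
c = 1; sex-limited c = 1/2, mirroring the two-fold relaxation that also
doubles the expected Pn/Ps (0.10 → 0.20); genes under postcopulatory
sexual selection c = ½·H/(H+1), increasing in the harmonic mean mate
number H (default 13.984) and saturating at the sex-limited exposure —
with honey-bee-scale polyandry PCSS genes are barely more relaxed than
other sex-limited genes.

Observed constitutive dN/dS is inverted to γ̂ by bisection on
g ∈ [−1000, 1000] to tolerance 1e−10 (round trips reproduce ω to
< 1e−8; overflow guarded by the limits ω → 0 as g → −∞ and ω → g as
g → +∞, with ω(0) = 1 by continuity). The exact coefficients linking
the companion theory's Nₑs to ω are not reproducible from the source
text (which prints both 0.092 and 0.11 for constitutive dN/dS, and an
expectation of 0.37); under the default form, 0.11 at half exposure
maps to ≈ 0.369 — close to, but not constrained to equal, the printed
value. The exposure coefficients are deliberately the one tunable place
where better theory can be plugged in.

## 5. Recombination

Marey maps are fitted per chromosome as a monotone piecewise-cubic
interpolant of genetic position against physical position
(`splinefun(method = "hyman")`). The binding physical constraint is
monotonicity: the derivative (the local recombination rate) must be
≥ 0 everywhere. R's Fritsch–Carlson variant (`monoH.FC`) was tried
first and empirically undershoots (derivatives near −1 cM/Mb on random
monotone maps), so Hyman filtering — also exact-interpolating,
shape-preserving, and linear-reproducing — is used instead. A gene's
rate is the difference quotient over its span in cM/Mb (robust for
genes crossing knots); the derivative at the midpoint is available
behind a flag, and a zero-length span falls back to the point
derivative. Genes outside the marker span are flagged `outside_map`
rather than extrapolated.

## 6. The synthetic world

The generator's defaults state a honey-bee-like world and are not
revisited per test:

| Parameter | Default | Why |
|---|---|---|
| genes | 2,000 (demo) of 100–500 codons | desk-scale stand-in for the ~12k-gene genome |
| chromosomes | 16 × 14 Mb | honey-bee karyotype and genome size |
| θ_S | 0.02 / synonymous site | high diversity of African *A. mellifera* populations |
| allele copies n | 22 | 11 diploid ingroup samples |
| synonymous divergence | 0.05 / site | *A. mellifera*–*A. cerana* scale |
| ω classes (poly, div) | constitutive (0.10, 0.092); sex-biased (0.20, 0.37); unclassified (0.15, 0.15) | the null-model world: observed constitutive intensities and their two-fold/model-mapped relaxation |
| linkage map | 125 markers/chromosome, mean 23 cM/Mb | ~2,000-marker map; the honey bee's exceptional map length |
| expression | baseline mean 200, NB dispersion 0.1, fold 8, 5 samples per (sex × tissue) group | typical bulk RNA-seq moments; 5 drones / 5 queens |
| class mix | 16% haploid-, 22% diploid-biased, 25% constitutive | the reported male-biased fraction, with the rest chosen once |

Polymorphism counts per gene are Poisson(θ·L·a₁) with
a₁ = Σ₁ⁿ⁻¹ 1/i, and frequencies are drawn from the neutral spectrum
P(i) ∝ 1/i, which together make E[π per site] = θ — the calibration
that parameter-recovery tests rely on. Substitution counts are
Poisson(d_S·L·ω). Events are placed only where a single-nucleotide
change has the intended effect class, one event per site, at most one
substitution per codon, and never a stop-gaining substitution (a fixed
nonsense change contradicts an intact CDS and would be excluded by the
divergence counter, breaking exact truth recovery). The outgroup is a
single haploid allele column; substitutions land on the ingroup or
outgroup branch with equal probability. Planted expression bias raises
one (sex, tissue) group for sex-biased genes and one complementary pair
of adult groups (e.g. male gonad + female soma) for constitutive genes
— the only pattern that satisfies "up-regulated in both sexes" under
the pairwise rule, since same-tissue groups of opposite sexes are
compared against each other.

What the generator does **not** emulate: read-level noise and mapping
artifacts, linked selection and demography, recombination within genes,
rRNA contamination, batch effects, or dispersion trends across the mean.
A green recovery test therefore establishes that the estimators are
correct and calibrated *under the stated model*, not that they are
robust to every pathology of real sequencing data.

## 7. Determinism and degenerate inputs

Every generator draws from a seed-local RNG stream (the caller's RNG
state is restored), so identical (seed, config) give byte-identical
outputs and the pipeline's master-table checksum is reproducible.
Degenerate cases are defined, not accidental: zero-variance expression
groups with equal means give p = 1; empty variant tables give
πS = πNS = 0 when sites exist and NA otherwise; MK tables with a zero
margin give χ² = 0, p = 1; genes with Ls = 0 are skipped for synonymous
planting with a warning; undefined CpGo/e (no C or G) is NA.

## 8. Known limitations

- The exposure coefficients are placeholders for companion theory, not
  derived quantities; conclusions about *how close* observed values sit
  to "the" null depend on them.
- Divergence uses raw counts (no multiple-hit correction), appropriate
  at the simulated densities but conservative for distant outgroups.
- The DE replacement has no dispersion shrinkage, so its power at very
  low counts is below a shrinkage estimator's; the classification
  thresholds compensate at the simulated depths.
- dN/dS and γ per gene are consumed from side tables when provided, not
  estimated.
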
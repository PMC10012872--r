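---
title: "Inferring age-related ceRNA networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring age-related ceRNA networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAfly)
```

## The biological question and the inference chain

Competing endogenous RNAs (ceRNAs) are transcripts — here circRNAs and
lncRNAs — that carry binding sites for a miRNA and can titrate it away from
its mRNA targets. The ceRNA hypothesis makes a falsifiable directional
prediction for any (sponge, miRNA, mRNA) triple along an ageing contrast:
the sponge and the mRNA should move in the **same** direction between the
two ages, and the miRNA in the **opposite** direction. ceRNAfly implements
the full inference chain for a two-age fly design (day 7 vs day 42):

1. differential expression (DE) of mRNAs, lncRNAs, circRNAs (RNA-seq, 2
   biological replicates per age) and miRNAs (miRNA-seq, 5 replicates);
2. miRNA binding-site prediction on sponge transcripts and mRNA 3'UTRs;
3. triple construction by shared-miRNA site overlap, then the
   sign-consistency ("ceRNA mechanism") filter;
4. GO enrichment of the network's target mRNAs;
5. qPCR validation via 2^-ddCt relative quantification and direction
   concordance with RNA-seq.

Every stage is exercised end to end on a synthetic-data generator that
plants known triples, so recovery is measurable against ground truth.

## Differential expression model

Counts are modelled as negative binomial with variance
$\mathrm{Var}(y) = \mu + \alpha\mu^2$; $\alpha$ is the dispersion and
$\alpha = 0$ recovers Poisson. We state this parameterization explicitly
because "dispersion" conventions differ across tools.

**Normalization.** Median-of-ratios size factors: each sample's factor is
the median over features of its count divided by the feature's geometric
mean across samples; features containing any zero are excluded from the
median. If no feature has all-positive counts the function fails loudly
rather than silently switching to a pseudo-reference.

**Dispersion.** Per feature, a method-of-moments estimate on normalized
counts, $\hat\alpha_{raw} = \max(0, (s^2 - m)/m^2)$, with $m$ the grand
mean and $s^2$ the df-weighted pooled *within-condition* variance.
Within-condition pooling matters: folding the between-condition signal into
$s^2$ would inflate $\alpha$ exactly for true DE features and destroy
power at the planted effect size. Raw estimates are then shrunk toward a
lowess trend over features of similar abundance with empirical-Bayes
weight $df/(df + df_{prior})$, $df_{prior} = 10$ (the prior strength
edgeR defaults to). With 2 replicates per condition the per-feature moment
estimate carries only 2 residual df and is nearly uninformative; an equal
raw/trend split leaves enough estimation noise to visibly inflate the null
rejection rate, while df-weighted shrinkage keeps the exact test calibrated
(the test suite checks the null raw-p fraction on 2,000 simulated null
features).

**Testing.** An exact conditional test on group sums: the sum of $n$
i.i.d. NB$(\mu, 1/\alpha)$ variables is NB$(n\mu, n/\alpha)$, and under a
shared per-sample mean the law of one group sum given the total is free of
$\mu$. Replicates are summed after normalization (rounded pseudo-counts),
a documented approximation required by the conditional construction. The
two-sided p-value is the total probability of all partitions no more
likely than the observed one, ties included — this matches a brute-force
enumeration oracle exactly at $\alpha = 0$ (conditional binomial), which
the tests verify for every total up to 30.

**Screening.** circRNAs are screened at raw p < 0.05 with no fold-change
floor; miRNAs at fold change >= 1.5 and raw p < 0.05. The published mRNA
and lncRNA lists derive from an earlier study whose thresholds are not
restated, so those assays use the miRNA screen as a reasonable default.
All fold changes are handled as log2(day42/day7); published "fold change"
values such as 0.74 flagged up and -0.49 flagged down are only coherent on
the log2 scale. Raw-p screening reproduces the published criterion;
BH-adjusted p-values are always reported alongside for stricter use.

## Binding-site model

**Seed anchors.** Watson-Crick complementarity (no G:U inside the seed) to
miRNA positions 2-8 defines the anchor classes: 8mer (positions 2-8
plus target A opposite position 1), 7mer-m8, 7mer-A1, and 6mer.
Coordinates are 1-based inclusive on the target's 5'->3' strand. DNA input
is converted T->U with a warning rather than rejected.

**Alignment.** Each anchor is extended by Smith-Waterman local alignment
of the full miRNA against the reversed +/-30-nt target window
(antiparallel pairing): match +5, G:U wobble +2, mismatch -3, gap open
-9, gap extend -4, with substitution scores doubled at miRNA positions
2-8 (5' dominance). A perfectly complementary 22-mer scores
22x5 + 7x5 = 145; a seed-only duplex scores 70. The default score
threshold is 140, so a reported site needs substantial 3' pairing beyond
the seed — the published tool's exact parameters are not printed anywhere,
and this scheme is a documented, configurable default in its style.

**Free energy.** Duplex dG is nearest-neighbor: initiation (+4.09
kcal/mol) plus stack terms for consecutive pairs (Watson-Crick values in
the style of the Turner rules; G:U stacks included with representative
values) plus a linear penalty (3.0 + 0.3/nt) per internal loop or bulge.
Terminal overhangs and end penalties are not modelled. Sites must reach
dG <= -10 kcal/mol by default. These parameters are a self-contained
approximation adequate for ranking and thresholding synthetic duplexes;
absolute published energies for specific fly duplexes are
parameter-dependent and deliberately not an acceptance quantity.

**circRNA circularity.** Back-splice-spanning sites are found by scanning
the linearized circRNA with its first L-1 nt appended (L = miRNA length);
seed start coordinates are reported modulo the sequence length (a
junction-spanning site may have end > sequence length, meaning it wraps).
Wrapped duplicates of the same seed position are collapsed, keeping the
copy with the better extension context.

**Overlap resolution.** Per (miRNA, target) pair, the best-scoring site is
kept and non-overlapping sites are added greedily; equal scores break ties
toward the lower start coordinate.

## Network construction and the mechanism filter

A candidate triple is any (sponge, miRNA, mRNA) with at least one
predicted site on each side and all three members DE. No statistical test
is applied to shared-site counts — membership is driven by the hard DE
lists, mirroring the original analysis. The mechanism filter then keeps
exactly the two direction patterns compatible with sponging, (up, down,
up) and (down, up, down); the unfiltered table is always exported too so
both network variants are reproducible.

## qPCR model

Relative quantity per sample: $2^{-\Delta\Delta C_t}$ with
$\Delta C_t = C_t^{gene} - C_t^{rp49}$ and $\Delta\Delta C_t$ centred on
the mean day-7 (calibrator) $\Delta C_t$. Amplification efficiency is
fixed at 2. Group comparisons are two-sided Welch t-tests on
$\Delta\Delta C_t$ (log-scale symmetry; the published methods say only
"independent-samples t-tests", so the unequal-variance form is a
documented choice). A gene is concordant "(+)" with RNA-seq when the sign
of its mean day-42 log2 RQ matches the DE direction and both calls are
significant at 0.05.

## The synthetic-data generator

The generator *is* the study design, not a tuning dial. Defaults:

| parameter | default | meaning |
|---|---|---|
| replicates | 2 (RNA-seq), 5 (miRNA-seq) | per age, as in the emulated design |
| qPCR replicates | 3 per age | as in the emulated validation |
| baseline_mean | 500 counts | typical well-quantified transcript |
| log2fc_effect | 2.0 | planted effect on triple members |
| dispersion | 0.05 | moderate biological variability |
| features | 60 mRNA / 15 lncRNA / 15 circRNA / 20 miRNA | desk-scale universe |
| planted triples | 10 | half (up, down, up), half (down, up, down) |
| lengths | 600 nt UTR, 800 nt sponge, 22 nt miRNA | typical magnitudes |
| ct_noise_sd | 0.2 cycles | realistic technical scatter |

Sequencing depth and dispersion are not stated in the emulated study;
these values are one-time choices a practitioner would call realistic, and
the recovery results must be read as conditional on them.

Background sequence composition is i.i.d. uniform A/C/G/U, which makes
chance-hit rates analytically tractable. Planted sites are
*full-complement* sites: the reverse complement of miRNA positions 2..L
plus an A opposite position 1. A bare planted 8mer over random flanks
scores only ~90-110 under the alignment scheme and could never pass the
default threshold of 140, so plantings carry the 3' supplementary pairing
that threshold implies; recorded ground-truth coordinates are the 8mer
seed span, which is exactly what the scanner reports. Per-sample library
size factors are drawn log-uniform in [0.7, 1.4] so normalization is
non-trivial. Counts, sequences, Ct tables and the GO map are all
deterministic given (config, seed).

What the generator does **not** emulate: realistic 3'UTR base composition
and secondary structure, multi-miRNA co-targeting, partially overlapping
sites, correlated replicates, batch effects, read-level artefacts
(adapters, PCR duplicates, back-splice mis-calls), or a real GO DAG.
Passing recovery tests therefore demonstrates internal consistency of the
pipeline under the stated noise model — not field performance on real fly
libraries.

## Numerical choices and degenerate inputs

- Exact-test tie detection uses a relative log-probability tolerance of
  1e-7; all-zero features are dropped before testing; a zero conditional
  total returns p = 1 with a warning.
- log2 fold changes use a +0.5 pseudo-count on normalized group means.
- The dispersion trend falls back to the global mean of raw estimates
  when fewer than 10 features (or a degenerate abundance spread) make a
  lowess fit meaningless.
- GO enrichment is flat (terms tested exactly as mapped, no DAG ancestor
  propagation, since annotation provenance varies); the default
  background is the union of the annotation map and the query. Note that
  adding never-annotated genes to the background makes any fixed overlap
  *more* surprising — the upper-tail p shrinks — which the property tests
  assert in that direction.
- Ranking ties in top-term reporting break lexicographically by GO id;
  site-overlap ties break toward the lower start.
- Pipeline outputs are byte-stable: TSVs with headers, tab delimiters,
  LF endings; reruns with the same config hash identically.

## Problem sizes used by the checks

The test suite and the acceptance script run at desk scale, chosen to
give tight Monte-Carlo error while staying comfortably interactive:
exhaustive oracle sweeps (all exact-test totals <= 30; all hypergeometric
configurations with N <= 25; 100 random seed-scan pairs up to 1 kb), 2,000
null features for the type-I check, and 5 generator seeds for the
planted-triple recovery summary (reported as the mean over seeds).

## Known limitations

- The exact test's replicate summation is an approximation; a GLM/Wald
  route (as in DESeq2) would model per-sample means directly.
- Energy parameters are a compact approximation of the published
  nearest-neighbor tables; G:U stack values are representative.
- mRNA/lncRNA screening thresholds are a package default, not a published
  value.
- The hypergeometric enrichment ignores annotation length bias (GOseq-style
  corrections are out of scope).
- Single reference gene, fixed efficiency 2.0, and one-factor comparisons
  only on the qPCR side.
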
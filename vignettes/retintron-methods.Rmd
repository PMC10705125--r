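---
title: "Quantifying and modeling intron retention with retintron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and modeling intron retention with retintron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retintron)
```

## The problem

Intron retention (IR) is the alternative-splicing outcome in which an
intron remains in the mature transcript. In tumors it is frequent and
consequential: a retained intron can introduce a premature termination
codon (PTC) and route the transcript to nonsense-mediated decay (NMD), or
lengthen a 5'UTR and seed upstream open reading frames (uORFs) that
suppress translation. `retintron` implements a complete rule-based IR
analysis: quantification with explicit decision rules, differential IR
between paired tumor/normal samples, sequence-feature characterization,
and diagnostic/prognostic modeling — together with a synthetic-data
generator that plants known effects so every stage can be verified.

## Quantification model and its decision rules

The retention level of an intron in one sample is estimated by

$$\mathrm{IRratio} = \frac{m}{m + j},$$

where $m$ is the median per-base read depth across the intron and $j$ the
number of split reads across the intron's flanking exon–exon junction.
Under the generative model the two isoforms share the locus depth budget
$d$: intron base depth is Poisson$(d\psi)$ and junction reads are
Poisson$(d(1-\psi))$ for retention fraction $\psi$, making IRratio a
consistent estimator of $\psi$.

A raw ratio is only reported when the evidence supports a call:

* $j < 4$: the spliced isoform is not demonstrably expressed → **missing**;
* intron coverage (fraction of bases with depth $\ge$ 1) $< 20\%$:
  confidently spliced → **zero**;
* coverage $> 70\%$ and $m > 3$: trusted **value** (necessarily $> 0$);
* otherwise → **missing** (undecidable).

All comparisons are strict, mirroring the wording of the rules ("at least
4", "less than 20%", "above 70%", "above 3"); the boundary cases —
coverage exactly 0.20 or 0.70, $m$ exactly 3 — therefore resolve to
*missing*, the conservative state. "Coverage" carries no depth cutoff
beyond $\ge 1$, the minimal reading. The matrix encodes the three states
as `NA` (missing), `0` (confident zero) and positive values; a trusted
value is always positive because it requires $m > 3$, so the encoding is
lossless.

Sample-level QC excludes libraries whose intergenic/coding read ratio
exceeds 10% (strictly; a ratio of exactly 0.10 passes). Because most bulk
libraries are unstranded, apparent retention can be antisense
bleed-through; introns whose maximum trusted IRratio across
strand-specific libraries exceeds 0.08 (strictly; 0.08 exactly is
excluded) form a whitelist to which differential and prognostic calling
is restricted.

## Differential IR

Per whitelisted intron, per-pair tumor$-$normal differences are tested
with the Wilcoxon signed-rank test — the conventional reading of a
"paired Wilcoxon" test. The exact null distribution is used below 25
usable pairs (unless ties force the approximation) and the normal
approximation with continuity correction otherwise. A pair is usable when
both sides are decidable: confident zeros participate as 0.0 (the intron
*is* measured as spliced), missing cells drop the pair. An intron is a
DIR when $p < 0.05$ and $|\Delta\,\mathrm{median}| > 0.1$, both strict; no
multiple-testing correction is applied by default (an optional
Benjamini–Hochberg mode exists) because the effect-size filter carries
most of the specificity. Introns with fewer than two usable pairs are
skipped and logged. DIRs are categorized *cancer associated* (median 0 in
normal, $> 0.1$ in tumor), *normal associated* (the mirror) or *altered
level*.

For pan-cancer feature sets, DIR tables are merged by union, introns
called in opposite directions in different cancers are dropped, and
introns with a missing rate above 30% are dropped; remaining missing
cells are imputed with the intron's mean over observed cells.

## Sequence features and the NMD rule chain

Introns are classified as *constitutive* (median IRratio 0 in tumor and
normal across all cancers), *unregulated retained* (retained somewhere,
never differential), *dir up* or *dir down*. Features: GC fraction,
length, and relative gene position $(\mathrm{ordinal}-1)/(n-1)$ so the
first and last introns of a gene map to 0 and 1; genes with fewer than 3
introns are excluded from the position analysis since they only admit the
degenerate ranks.

NMD prediction evaluates an escape chain on the retained-intron mRNA, in
order: intron in a UTR; intron 5' end < 200 nt downstream of the start
codon; last intron; no PTC when translating the retained transcript from
the annotated start; PTC within 55 nt upstream of the retained
transcript's last exon–exon junction (the retained intron itself
contributes no junction). Only if every escape fails is the transcript
predicted NMD-sensitive. All distances are measured in transcript
coordinates — NMD is defined on the mRNA, not the genome. The PTC
position is the first nucleotide of the stop codon, and "within 55 nt"
means $\mathrm{junction} - \mathrm{PTC} \le 55$, which also covers a PTC
at or downstream of the junction. The implementation is verified against
an independent oracle that rebuilds the mRNA by string concatenation and
scans codons linearly; the two agree on 100% of several hundred
randomized transcripts in the test suite.

uORF detection scans the mRNA-sense 5'UTR (with the retained intron) for
ATGs strictly upstream of the main start and pairs each with its first
in-frame stop, which may lie beyond the main start. ATGs with no
downstream in-frame stop are not open reading frames and are excluded by
default; uORFs overlapping the main ORF are counted.

## Diagnostic model

A Random Forest (500 trees, mtry 3) is evaluated by repeated stratified
4-fold cross-validation (100 repeats by default). Folds are assigned at
the patient-pair level: a tumor sample and its paired normal always share
a fold, otherwise the patient's IR profile would leak across the
train/test boundary and inflate the AUC. The *pooled AUC* is one AUC
computed over all out-of-fold class probabilities concatenated across
folds and repeats — the most literal reading of pooling — with per-repeat
AUCs kept for transparency. The confusion matrix uses a 0.5 probability
threshold. Class imbalance is left unadjusted. The feature-reduction
curve ranks features once by Gini importance and re-estimates 5-fold CV
error on geometrically shrinking subsets, $n \leftarrow \lceil 0.9\,n
\rceil$ (decreasing by at least one each step, down to 2).

## Prognostic models

An intron enters survival screening when at least 50% of patients have a
valid (non-missing) IRratio and at least 5% of the valid values exceed
0.1. Screening restricts to patients with IRratio > 0, splits them at the
median of that restricted set (ties at the median go to the low group — a
deterministic convention), and fits univariate Cox regression with Efron
tie handling; $p < 0.05$ unadjusted is called significant. Patients with
missing survival are excluded before the median is computed. The gene
-expression analog applies the same median split to genes with median
expression above 1 TPM.

The IRR model takes introns with missing rate below 20% (mean-imputed),
fits a 10-fold cross-validated LASSO Cox path (features standardized
internally, coefficients reported on the IRratio scale), and selects
coefficients at `lambda.min` by default or `lambda.1se` on request. Each
patient's risk score is $\mathrm{IRR} = \sum_i \beta_i\,
\mathrm{IRratio}_i$; the cohort median splits risk groups (ties low),
which are compared by Kaplan–Meier curves, the log-rank test, and the Cox
hazard ratio of high vs low.

## What the synthetic generator emulates — and what it does not

The generator emulates the study design the pipeline targets: a genome
and annotation with controllable intron GC/length and a positive-control
5'UTR intron carrying a configurable number of uORF start codons; paired
tumor/normal cohorts with per-intron baseline retention drawn from
U(0.05, 0.5), planted differential effects ($\Delta\psi$ on selected
introns), and a per-patient logit-normal random effect (sd 0.3) on $\psi$
shared by a patient's tumor and normal sample, which induces the
within-pair correlation the paired test exploits; a small strand-specific
subset for whitelist construction; and exponential survival with hazards
$h_0 e^{\sum_j \beta_j x_{ij}}$ planted on IR-high group membership, with
independent uniform censoring calibrated numerically so the expected
censored fraction matches the target.

Default study conditions: locus depth $d = 100$, 30 pairs, 4 stranded
samples, intergenic/coding ratio 0.05, planted $\Delta\psi = 0.3$,
baseline hazard $h_0$ = 0.002/day, 20–30% censoring.

The generator does **not** emulate read-level error, mappability or GC
bias, fragment-length effects, isoform competition beyond the one
retained/spliced pair, pre-mRNA contamination, batch effects, or
dependence between introns of the same gene. Passing tests therefore
demonstrate the correctness of the decision rules, tests and models under
the stated statistical contract — not robustness to the artifacts of real
alignments, which an IR study must still address upstream.

## Numerical choices and degenerate inputs

* Ties: medians are R's default (mean of central order statistics); ties
  at any median split go to the low group; Wilcoxon zero differences are
  dropped (all-zero difference vectors give $p = 1$).
* Spearman correlation uses midranks under ties, with the t
  approximation for the p-value; constant vectors are an error.
* Mutation proximity is inclusive at 20 bp on both sides of either
  splice site.
* Degenerate inputs error with actionable messages rather than
  returning silent NAs: empty depth profiles, zero coding reads, cohorts
  with $\le$ 15 complete pairs, single-class classification labels,
  empty risk groups, splits with fewer than two patients per group, or
  survival tables without events.
* Every stochastic function takes a mandatory seed and restores the
  caller's RNG state; the pipeline derives per-stage child seeds as
  `100 * seed + stage_index`, so any stage can be reproduced alone.

## Design choices where the design was open

* **Intron deduplication.** Identical genomic intervals arising from
  different transcripts are deduplicated by (chrom, start, end, strand),
  with ordinal and region taken from the first transcript in canonical
  (chrom, start, transcript id) order; region conflicts across
  transcripts become "mixed". A deduplicated universe matches how
  genome-wide intron counts are usually reported.
* **"Paired Wilcoxon".** Interpreted as the signed-rank test on paired
  differences; a rank-sum test on paired columns would discard the
  pairing that motivates the design.
* **Zero-state cells** count as observations (a measured "spliced"
  outcome), not as missing, in missing-rate filters, imputation and
  pairing.
* **Percentile convention** $(\mathrm{ordinal}-1)/(n-1)$ maps first/last
  introns to the ends of the axis; equal spacing across a gene follows.
* **Pooled AUC** concatenates out-of-fold probabilities rather than
  averaging per-fold AUCs; pair-aware folds are enforced even though
  protocols often leave this unstated, because leakage inflates AUC.
* **Problem sizes in the tests** (cohorts of 25–30 pairs, 120–1000
  introns, depth 100; 20 replicates for selection/recovery properties)
  are chosen so each property is measured with useful Monte-Carlo
  precision while the whole suite stays desk-scale.

## Known limitations

IRratio treats the flanking junction as a single count and performs no
isoform deconvolution; transcripts with complex local splicing violate
the two-isoform assumption. The NMD rule is a deliberately simple,
auditable chain — it ignores reinitiation, readthrough and
exon-junction-complex deposition details. LASSO selection frequencies and
the λ rule are sensitive to the event count at desk-scale sample sizes;
`lambda.1se` yields sparser, more stable models than `lambda.min` when
events are few. The classifier reports no calibration, only ranking
performance.
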
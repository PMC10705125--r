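# retintron

Intron retention (IR) is the splicing outcome in which an intron survives
into the mature transcript. In tumors, IR is widespread, often
tumor-specific, and can silence a gene post-transcriptionally (through
nonsense-mediated decay of the PTC-carrying transcript) or dampen its
translation (through upstream open reading frames introduced into the
5'UTR). `retintron` is an R package for scientists who want to quantify IR
from bulk RNA-seq alignment summaries, call differential IR between paired
tumor/normal cohorts, characterize the sequence features of retained
introns, and evaluate IR as a diagnostic and prognostic biomarker — with a
fully seeded synthetic-data generator so every stage can be validated
against planted ground truth.

## The quantities at the core

**IRratio.** For an intron with median per-base read depth *m* and *j*
split reads across its flanking exon–exon junction,

    IRratio = m / (m + j)

which estimates the retention fraction ψ (the two isoforms share the locus
coverage). The raw ratio is only trusted under explicit decision rules: at
least 4 junction reads (otherwise *missing*); intron coverage < 20% →
confidently spliced (*zero*); coverage > 70% and *m* > 3 → trusted value;
anything else → *missing*. Samples whose intergenic/coding read ratio
exceeds 10% are excluded, and differential/prognostic analyses are
restricted to a *whitelist* of introns with maximum IRratio > 0.08 in at
least one strand-specific library.

**Differential IR (DIR).** Per intron, a paired Wilcoxon signed-rank test
on tumor−normal IRratio differences across patient pairs; an intron is a
DIR when *p* < 0.05 and |Δ median IRratio| > 0.1. DIRs are categorized as
cancer-associated (spliced in normal, median 0; retained in tumor, median
> 0.1), normal-associated (the mirror), or altered-level.

**NMD rule.** A retained intron in a coding transcript elicits NMD unless
it lies in a UTR, starts < 200 nt from the start codon, is the last
intron, introduces no premature termination codon, or the PTC falls within
55 nt upstream of the last exon–exon junction of the retained transcript.

**Models.** A Random-Forest classifier (500 trees, mtry 3) separates tumor
from normal samples on merged pan-cancer DIR features under 100×4-fold
cross-validation with patient pairs held together, reporting one AUC over
all pooled out-of-fold probabilities. A LASSO-Cox model on IRratios yields
the intron-retention risk score IRR = Σᵢ βᵢ·IRratioᵢ; the cohort median
IRR splits patients into risk groups compared by Kaplan–Meier curves and
the log-rank test.

## Worked example

```r
library(retintron)

demo <- make_demo(seed = 42)
str(demo$manifest)
```

```
List of 9
 $ seed         : num 42
 $ n_introns    : int 119
 $ n_quantified : int 119
 $ n_whitelist  : int 115
 $ n_dirs       : int 20
 $ dir_recall   : num 1
 $ pooled_auc   : num 0.994
 $ n_irr_introns: int 2
 $ logrank_p    : num 0.00152
```

The demo generates a 25-gene genome and a 20-pair tumor/normal cohort with
20 planted differential-retention events (Δψ = 0.3), quantifies 119
introns, whitelists 115 of them from the stranded subset, and recovers all
20 planted DIRs (`dir_recall = 1`) with no false positives. The
Random-Forest classifier reaches a pooled cross-validated AUC of 0.994 on
the DIR features, and the LASSO-Cox IRR score (2 introns selected)
stratifies the simulated patients into risk groups that differ in survival
(log-rank p = 0.0015). All outputs are written under the run directory
with the configuration hash stamped into each file; re-running with the
same seed reproduces every file bit for bit.

Individual stages are plain functions — `read_gtf()`, `extract_introns()`,
`simulate_cohort()`, `build_ir_matrix()`, `build_whitelist()`,
`call_dirs()`, `predict_nmd()`, `find_uorfs()`, `train_eval_cv()`,
`median_split_cox()`, `fit_irr()`, `km_logrank()` — see the package help
and the methods vignette (`vignettes/retintron-methods.Rmd`). A thin
command-line wrapper over the same functions is installed at
`inst/cli/retintron.R`.

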
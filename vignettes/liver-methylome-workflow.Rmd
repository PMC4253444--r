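---
title: "Multi-etiology liver-disease methylome analysis with methylrun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-etiology liver-disease methylome analysis with methylrun}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylrun)
```

## The analysis problem

Hepatocellular carcinoma (HCC) develops almost always on a background of
cirrhosis, itself driven by distinct environmental exposures — chronic
hepatitis B or C infection (HBV/HCV), chronic alcohol abuse (EtOH), or
rarer/cryptogenic causes.  Genome-scale DNA methylation arrays (Infinium
450k-style) measure a beta value $\beta \in [0,1]$ — the methylated
fraction — at each of hundreds of thousands of CpG probes, across normal
liver, cirrhotic liver, tumors, and cultured cells.  The scientific
questions this package operationalizes are:

1. Which CpGs change methylation in each etiology, at each disease stage,
   and which changes are shared across etiologies?
2. Are changes organized into *differentially methylated regions* (DMRs) —
   long runs of consecutively assayed CpGs all shifted in the same
   direction?
3. Where do changes fall relative to CpG islands (island / shore / shelf /
   open sea) and gene models (TSS1500, TSS200, 5'UTR, 1st exon, body,
   3'UTR), and how does promoter vs gene-body methylation relate to gene
   expression?
4. Are early (cirrhosis) changes conserved in tumors, are primary-tumor
   changes conserved in cell-culture models, and how frequently is a CpG
   aberrant across individual tumor samples?

`methylrun` implements this pipeline for any beta matrix + probe manifest +
sample sheet, and ships a fully seeded synthetic-cohort generator so every
stage can be verified by planted-signal recovery without access to patient
data.

## Statistical model

**Per-CpG differential test.**  For reference group $A$ (size $n_A$) and
test group $B$, `compare_groups()` computes, per probe,
$\Delta\beta = \bar\beta_B - \bar\beta_A$ (disease minus reference, so
"hyper" means a gain in disease) and a two-sided pooled-variance
(Student's) $t$:

$$ t = \frac{\bar\beta_B - \bar\beta_A}
           {s_p\sqrt{1/n_A + 1/n_B}},\qquad
   s_p^2 = \frac{(n_A{-}1)s_A^2 + (n_B{-}1)s_B^2}{n_A + n_B - 2}. $$

A Welch variant is available (`var_equal = FALSE`).  P-values are adjusted
by the Benjamini–Hochberg step-up rule over the probes actually tested in
that comparison (not the full manifest): adjusting after the missingness
filter is standard practice and keeps the FDR interpretable for the tested
family.  Probes with missing values in more than 20% of either group (or
fewer than 2 usable values) are skipped — a deliberately conservative rule,
configurable via `max_missing`, because a near-empty group makes the
pooled variance unstable.  Zero-variance probes get $p=1$ when the means
are equal and $p=0$ otherwise, avoiding NaN propagation.

**Call sets.**  `call_cpgs()` applies strict thresholds
$\mathrm{FDR} < 0.05$ and $|\Delta\beta| > \delta_{\min}$; the working
thresholds are $\delta_{\min}=0.1$ for cirrhosis-stage comparisons and the
more stringent $0.25$ for tumor comparisons, reflecting the larger effect
sizes there.  One analysis family is defined on *raw* p-values rather than
FDR (early/late conservation); `use_raw_p = TRUE` reproduces that
convention, with FDR the default.

**DMR detection.**  `find_dmrs()` walks probes in manifest (array) order
within each chromosome and emits every *maximal* run of at least
`min_run = 10` consecutive probes with $|\Delta\beta| > 0.1$ of constant
sign.  "Consecutive" means adjacent assayed probes, not a genomic distance
window: the defining publications of this style of analysis count array
neighbors, and a distance cap would make the definition density-dependent.
A `max_gap` option (off by default) is provided for genomic realism, and
`require_fdr` optionally co-requires per-probe significance — whether the
original analyses did so is not stated, so both behaviors exist and
neither is asserted as canonical.  DMR boundaries are reported at the
member-probe positions (no midway extension toward non-member neighbors):
conservative and exactly reproducible.

**Feature distribution and metagene profiles.**  Calls are tabulated over
the island-relation and genic-feature vocabularies
(`feature_distribution()`), per-gene feature-level mean $\Delta\beta$ is
correlated between features (`feature_correlation()`, Pearson + least
squares), and `metagene_profile()` averages values in strand-oriented gene
coordinates: a 5,000 bp upstream flank, the body rescaled to percent of
gene length, and a 5,000 bp downstream flank.  Bin counts (25 per flank =
200 bp bins, 50 body bins = 2% bins) are a package choice made for stable
occupancy at 450k-like density; they are configurable and the flank width
is part of the profile definition.  Probes overlapping several gene
windows contribute to each gene (no deduplication) — the simplest
defensible rule; probes are pooled within bins rather than averaged per
gene first (a gene-first variant can be built by restricting `genes`).

**Expression integration.**  `summarize_expression()` averages probe
intensities per gene on the given scale (a `log2` option exists; whether
intensities should be log-transformed first is a judgment call — the
default matches plain intensity averaging).  `expression_strata()` takes
the top/bottom 25% by nearest-rank quantile with ties broken by gene id,
so strata are deterministic; degenerate all-equal summaries are an error
rather than an arbitrary split.

**Progression and conservation.**  `stage_call_counts()` bins disease
samples into cirrhosis, HCC T1+T2, and HCC T3+T4 and counts calls against
normal at $\Delta\beta > 0.25$.  `sample_hyper_frequency()` calls an
*individual* disease sample aberrant at a probe when its beta deviates
from the normal-group mean by more than the same margin used for group
calls (default 0.25).  This per-sample rule is the package's most
consequential interpretation: frequency-of-hypermethylation screens are
usually reported without a formal per-sample definition, and defining the
call against the normal mean with the group-call margin is the simplest
rule that uses no per-sample variance estimate.  The margin is exposed as
`delta` so other conventions can be swapped in.
`culture_conservation()` scores a primary-tissue call conserved when the
culture comparison shifts past the same margin in the same direction.

**Clone tables and clinical tabulation.**  Bisulfite-clone tables are
compared with a two-sided Fisher's exact test.  The p-value is computed
in-package by hypergeometric enumeration under the "minlike" rule (sum of
table probabilities no larger than the observed one, with the customary
$1+10^{-7}$ tie tolerance); the odds ratio is the sample OR with the
Haldane 0.5 correction when a cell is zero — reported this way because the
conditional-MLE OR of `fisher.test` answers a different question, while
the p-values agree exactly.  `summarize_clinical()` cross-tabulates
clinical covariates by etiology with a Total column; percentages use the
column's total sample count as denominator and are rounded half-up to two
decimals, matching the rendering convention of clinical cohort tables.

## The synthetic cohort generator

`sim_design()` fixes the study conditions; `simulate_manifest()`,
`simulate_cohort()`, `simulate_expression()` and `simulate_clone_table()`
are pure functions of (design, seed), so every run is reproducible
byte-for-byte.

What the generator emulates:

* **Array geometry.**  Genes laid non-overlapping on synthetic autosomes,
  a CpG island centered on each TSS plus occasional intergenic islands;
  probes placed densely around promoters/islands and sparsely elsewhere,
  then annotated exactly as a manifest would be (shore = within 2 kb of an
  island edge, shelf = 2–4 kb, `N_`/`S_` by genomic side; TSS200 $\le$
  200 bp upstream, TSS1500 200–1500 bp, then 5'UTR/1st-exon/body/3'UTR).
* **Bimodal baselines.**  Island/TSS-proximal probes start near
  $\beta \approx 0.1$, everything else near $0.8$, with per-probe jitter —
  the canonical bimodality of methylation arrays.
* **Noise.**  Sample values are drawn from a beta distribution
  parameterized by (mean, precision), precision defaulting to 50.  This
  respects the $[0,1]$ support and the shrinking variance near 0 and 1;
  published cohorts report no variance model, so the precision is a
  modeling choice (50 gives within-group SDs of ~0.05–0.07 at
  intermediate means, typical of tissue cohorts).
* **Planted effects.**  Effect specs target (tissue, etiology) cells with
  a base $\Delta\beta$; cirrhosis samples receive 0.5x the tumor effect
  and T3+T4 tumors 1.3x (defaults chosen to reproduce the monotone
  cirrhosis < T1+T2 < T3+T4 trend qualitatively), hyper effects are
  planted on low-baseline probes and hypo on high-baseline ones so group
  means stay inside $[0.02, 0.98]$ (violations are an error, not a clamp).
* **Planted DMRs.**  Contiguous manifest runs (default 12 probes at
  $|\Delta\beta| = 0.3$).  Member baselines are overridden into
  0.10–0.30 (hyper runs) or 0.60–0.85 (hypo runs): coordinately
  hypermethylated domains in liver tumors are island-rich loci of low to
  intermediate baseline methylation, and the override keeps the planted
  shift feasible.
* **Cell-line conservation.**  HCC-scoped effects propagate to HCC cell
  lines per probe with probability `line_conservation` (default 0.85);
  cultured hepatocytes are the unaffected culture reference.  Cell lines
  inherit effects regardless of the effect's etiology because lines derive
  from tumors of mixed etiology and carry no etiology label of their own.
* **Expression coupling.**  When enabled, each gene is assigned an
  expression class (25% high / 25% low / 50% mid); low-expression genes
  get promoter baselines raised by `promoter_margin` (default 0.3) and
  body baselines lowered by `body_margin` (default 0.15) relative to
  high-expression genes, and `simulate_expression()` gives the same
  classes separated intensities.  This reproduces the promoter-low /
  body-high signature of highly expressed genes.

What it deliberately does **not** emulate: raw two-channel intensities and
normalization artifacts, probe cross-reactivity and SNP-overlap artifacts,
batch effects, copy-number contamination, or cell-type heterogeneity.
Passing recovery tests on these cohorts therefore demonstrates that the
*algorithms* are correct at realistic noise levels and effect sizes — not
that real cohorts are free of the confounders above.

Default group sizes are a desk-scale cohort (20,000 probes, groups of
6–15); `design_full_cohort()` reproduces the full layout of the motivating
study population: 34 normal, 77 cirrhosis (39 HCV / 21 EtOH / 6 HBV / 3
cryptogenic / 8 other), 45 HCC (12 HCV / 2 HBV / 15 EtOH / 6 cryptogenic /
10 other), 15 cultured hepatocyte and 10 HCC cell-line samples.

## Worked example

```{r example, eval = FALSE}
design <- sim_design()                      # desk-scale defaults
sm <- simulate_manifest(design, seed = 1)
co <- simulate_cohort(sm, design, seed = 2)

ids <- split(co$sheet$sample_id, co$sheet$group)
diff <- compare_groups(co$beta, ids$normal, ids$HCC_EtOH)
calls <- call_cpgs(diff, fdr_max = 0.05, delta_min = 0.1,
                   comparison = "HCC-EtOH vs normal")
calls

dmrs <- find_dmrs(diff, sm$manifest, min_run = 10, delta_min = 0.1)
summarize_dmrs(dmrs)
fraction_of_calls_in_dmrs(calls, dmrs)

fd <- feature_distribution(calls, sm$manifest)
subset(fd, direction == "hyper" & vocabulary == "island")
```

## Numerical and testing choices

* All randomness flows through explicit seeds; global RNG state is saved
  and restored around every simulation call.
* The verification suite checks the BH adjustment against an exhaustive
  step-up oracle (all vectors of length $\le 12$), the DMR caller against
  brute-force maximal-run enumeration (hundreds of random tracks of up to
  1,000 probes), and Fisher's p against full hypergeometric enumeration on
  every 2x2 table with row margins $\le 15$.
* Recovery tests run 20 seeded replicates of a 20,000-probe cohort with 15
  samples per group, planted $\Delta\beta = 0.3$ CpGs and 12-probe DMR
  runs at precision 50, requiring $\ge 0.95$ recall at $\le 0.01$
  false-call rate; null cohorts of the same size must stay call-free.
  These problem sizes keep a full verification run under a minute on a
  laptop-class core while leaving the binomial noise on each recovery rate
  well below the tolerance being asserted.

## Known limitations

* Paired tumor/adjacent designs and covariate-adjusted models (age, sex,
  batch) are out of scope; the test is a plain two-group comparison.
* DMRs carry no significance assessment (no permutation p-values); they
  are descriptive maximal runs, and run length is the only filter.
* M-value transforms are not offered; tests operate on beta values as the
  conventions above prescribe.
* The autosome filter recognizes `chr1`..`chr22` labels only; manifests
  with other chromosome naming should be filtered by the caller.
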
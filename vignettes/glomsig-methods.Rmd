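---
title: "Methods: glomerular proteome signatures and connectivity mapping"
author: "glomsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glomerular proteome signatures and connectivity mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The analysis this package implements

Diabetic kidney disease (DKD) is routinely treated with renin–angiotensin
blockade (ACE inhibitors such as ramipril), yet a substantial fraction of
patients progresses regardless. One systems-level route to new add-on
therapies is to ask: *which glomerular proteins are altered by disease but
untouched by the standard drug?* — and then to search a compendium of
compound-induced expression signatures for molecules predicted to push that
residual signature back toward normal.

`glomsig` implements that workflow as a pipeline of composable functions:

1. **Preprocessing** of a label-free protein quantification table
   (proteins × samples; four groups — WT, DKD, DKD+R, WT+R — with 8
   biological replicates each): contaminant and low-evidence filtering,
   median normalization, per-comparison quantification filtering, and
   low-percentile noise imputation.
2. **Differential abundance** per protein for the three pairwise
   comparisons Set1 = DKD vs WT, Set2 = DKD+R vs DKD, Set3 = WT+R vs WT,
   using two-tailed unpaired Welch tests on log2 intensities with
   Benjamini–Hochberg annotation.
3. **Signature selection**: the flowchart that classifies DKD-associated
   proteins (Set1-significant) into ramipril-insensitive (RI) and
   ramipril-sensitive (RS) subsets from their Set2/Set3 behavior.
4. **Query conversion**: mouse protein ids → human gene symbols through an
   ortholog table, yielding disjoint up/down query sets.
5. **Connectivity mapping**: Kolmogorov–Smirnov (KS) scoring of the query
   against a database of per-compound-instance full gene rankings,
   reporting mean score, enrichment, permutation p, specificity and
   percent non-null per compound, plus a simplified CMap2-style
   standardized score.
6. **Gene-set overlap enrichment**: hypergeometric upper-tail tests against
   GMT collections with BH FDR.

Every input can be simulated with planted ground truth, so the full chain is
testable without any external download.

## Statistical model and conventions

### Preprocessing

All modeling happens on the log2 scale; tables are stored on the raw scale
(`2^x`) to mirror MaxQuant-style outputs. Median normalization shifts each
sample column (one analytical run — each sample is injected once) so that
all column log2 medians equal the grand median of the pre-normalization
column medians. Any common target is equivalent up to a global shift, and
two-sample t-statistics are shift-invariant, so this choice cannot affect
downstream inference; the operation is idempotent, which the tests assert on
fuzzed tables.

A protein enters a given two-group comparison only if it was quantified in
at least 4 of 8 replicates in *at least one* of the two groups (a
disjunctive rule: 4/8 observed in one group and 0/8 in the other is
retained). The mask depends only on the missingness pattern.

Missing values in retained proteins are replaced per run by a constant noise
value: the 1% percentile of that run's observed intensities. This models
left-censored missingness — label-free values are missing mostly because
they fell below detection, so a low-percentile constant is a deliberately
conservative stand-in. The percentile convention is linear interpolation
between order statistics (`stats::quantile` type 7) and is configurable
(`quantile_type`), since "1% percentile" alone does not pin down a
convention. Proteins excluded by the quantification filter are not imputed:
they are excluded from that comparison anyway.

### Differential abundance

Per protein, a two-tailed unpaired Welch test (`stats::t.test`,
Welch–Satterthwaite degrees of freedom) on log2 intensities;
`log2fc = mean(groupA) − mean(groupB)` with the first-listed group as A.
Significance for selection uses the raw p < 0.05, matching the selection
rule the flowchart counts are defined by; BH q-values are computed and
reported as annotation, and a `select = "q"` switch allows q-based
selection. A `test = "student"` switch provides the equal-variance variant,
because the source description of the test is ambiguous between the two.

### Signature selection flowchart

With DKD-GPs = Set1-significant proteins split by fold-change sign:

* **RI branch** — Filter 3 keeps DKD-GPs *not* significant in Set2
  (no detectable ramipril response in diabetic animals); Filter 4 then
  removes candidates significant in Set3 (a ramipril response in
  non-diabetic animals disqualifies "insensitive"). The reported RI
  fraction is `100·|RI|/|DKD-GP|` truncated to an integer percentage
  (the truncation convention reproduces the printed 350/666 → 52%).
* **RS branch** — Filter 1 keeps DKD-GPs significant in Set2 with the
  *opposite* trend to Set1 (counter-regulation); Filter 2 removes
  candidates whose Set3 behavior shows a ramipril sensitivity not specific
  to disease.

The Filter 2 pattern was a genuinely open design point: the source
description is internally ambiguous between "same trend as Set2 in Set3"
and "opposite trend". We default to **same trend** — if ramipril moves the
protein the same way in non-diabetic animals as it did in diabetic ones,
the response is not DKD-specific — and expose `opposite_sign` and `any`
readings as configuration. Proteins absent from a comparison (failed its
quantification filter) count as not significant there, with the number
logged; a significant protein with log2fc exactly 0 cannot be oriented and
is excluded with a warning.

### Connectivity mapping

The per-tail statistic is the classic connectivity-map KS construction: for
tag positions $V(1) < \dots < V(n)$ in a ranked list of $N$ genes,

$$a = \max_j\left(\frac{j}{n} - \frac{V(j)}{N}\right),\qquad
  b = \max_j\left(\frac{V(j)}{N} - \frac{j-1}{n}\right),$$

with the statistic equal to $a$ if $a > b$ and $-b$ otherwise. An instance's
raw score is $s = KS_{up} - KS_{down}$ when the two tails disagree in sign
and 0 otherwise; negative $s$ marks a profile that *opposes* the query (a
potential reverser). Raw scores are scaled across the database (positives by
the maximum positive, negatives by the absolute minimum), instances are
ordered by scaled score (ties broken by compound then instance id for
determinism), and a compound's enrichment is the KS statistic of its
instances' positions in that ordering. The permutation p places the
compound's $n$ instances uniformly at random among the $M$ database
instances, counting placements at least as extreme *with matching sign*,
with the add-one correction $p = (r+1)/(n_{perm}+1)$. Specificity is the
fraction of random null queries (same up/down sizes) under which the
compound reaches an enrichment at least as extreme with the same sign —
the real historical-query compendium used for this purpose is not
available, so generated null queries stand in for it, which is a documented
divergence. Percent non-null is the percentage of the compound's instances
whose scaled score is non-zero with the enrichment's sign.

The CMap2-style score aggregates a compound's instances into one profile by
mean gene rank (ties broken by gene name), computes
$wtcs = (ES_{up} - ES_{down})/2$ when the tails disagree (else 0),
normalizes by the mean $|wtcs|$ of same-sign compounds, and standardizes
against random reference queries:
$score = \mathrm{sign}(ncs)\cdot 100\cdot
\Pr(|ncs_{ref}| < |ncs|)$, spanning −100..100. This is a simplified
analogue of the modern connectivity score, not a re-implementation of the
production pipeline; recovery is validated by planting, never by comparing
to published compound tables (which depend on a proprietary compendium).

Two properties of this statistic are worth knowing:

* **Discreteness**: reversing a ranking maps $a' = b - 1/N$ and
  $b' = a + 1/N$, so scores are antisymmetric under rank reversal only to
  within $1/N$ per tail, and a tail sitting near the $a \approx b$ boundary
  can legitimately flip the zero-combination rule.
* **The permutation p is sign-directed** (one-sided): under its own null
  $P(p \le \alpha) \approx 2\alpha$. It orders compounds usefully but
  should not be read as a calibrated two-sided p-value. Additionally, when
  many instances score exactly 0 (common under weak queries), the
  deterministic tie ordering makes compound positions non-exchangeable, so
  the random-placement null is only an approximation in the tie block.

### Ortholog mapping and overlap enrichment

Mouse protein → human symbol mapping is table-driven (the resource choice
is an input, not a hard-coded database). Unmapped ids are dropped and
counted; 1-to-many mappings are dropped by default (`ambiguous = "expand"`
keeps all targets); a symbol reached from both the up and down side is
removed from both — a gene cannot be simultaneously up and down in a query.

Overlap significance is the hypergeometric upper tail
$P(X \ge x)$, $X \sim \mathrm{Hypergeom}(U, m, k)$, with the universe
defaulting to the union of all genes in the loaded GMT collection (the
"Compute Overlaps" convention) and an explicit universe as an option; BH
FDR is applied across all tested sets.

## The synthetic-data generator

`simulate_study()` emulates the study design, not the instrument: four
groups × 8 replicates, per-protein log2 baselines $\sim N(25, 2)$ (typical
MaxQuant intensity magnitudes), replicate noise $\sim N(0, 0.5)$, and
planted effect classes with $|{\Delta}| \sim U(1.5, 3)$ log2 units:

* **plain DKD effects** (the RI truth): the DKD shift persists in DKD+R;
* **counter-regulated** (`frac_rs = 0.125`): DKD+R carries the DKD shift
  minus $f\Delta$, $f \sim U(0.8, 1.2)$ — counter-regulation without exact
  cancellation (a `rs_reversal_range = c(1, 1)` setting gives full
  reversal);
* **non-specific responders** (`frac_nonspecific = 0.25`): a
  counter-regulating ramipril shift in *both* DKD+R and WT+R, so they are
  Set2-significant and exercise the RS Filter 2 removal;
* **ramipril-only** proteins shift in both +R groups with no DKD effect.

The default 500 planted effects among 2,500 proteins was chosen to mirror
the proportion of disease-associated proteins the emulated study reports
(roughly a quarter of quantified proteins, with ~12.5% of those
counter-regulated — hence `frac_rs`), and missingness follows a per-cell
logistic left-censoring model
$P(\text{missing}) = 1/(1 + e^{(x - \mu)/s})$ with $\mu = 19.1$, $s = 1$,
calibrated once against the full default generator so the mean per-run
missing fraction lands near the ~2% figure reported for the emulated
dataset. Contaminant flags (2%) and peptide counts
($\max(1, \mathrm{Pois}(4))$) are assigned so the identification filter has
work to do; planted-effect proteins always get $\ge 2$ peptides and no
contaminant flag, so ground-truth recovery measures the selection logic
rather than the identification filter. A single `noise_log2_sd` is used for
all proteins — the emulated study reports no per-protein variance structure
to match — so the generator does not reproduce the heteroscedasticity,
intensity-dependent variance, or protein–protein correlation of real
label-free data. Passing recovery tests therefore demonstrates the
pipeline's logic under a faithful *design*, not performance on real tissue.

Consequences of the planting scheme worth noting: non-specific responders
are Set2-significant, so they leave the RI branch at Filter 3, and the RI
Filter 4 removals on synthetic data arise from chance Set3 significance
(~5% of candidates) rather than from a planted class. The expected RI
sensitivity is governed by the two 5% type-I filters
($0.95^2 \approx 0.90$), which is what the recovery tests measure.

`simulate_compound_db()` plants one **reverser** (query down-genes near the
top, up-genes near the bottom, each signature gene misplaced with
probability `reverser_noise`) and one **mimic** among uniformly random
decoy rankings. It emulates none of the correlation structure of a real
compound compendium (cell lines, doses, batch structure); it exists so that
a known answer can be recovered end to end.

## Problem sizes and numerical choices

The shipped tests run the full default study (2,500 × 32) for recovery, a
2,000-protein null study for p-value calibration, a 22-compound × 4-instance
database over 1,000 genes for reverser recovery, and exhaustive
KS-vs-oracle enumeration for all tag sets with $n \le 3$, $N \le 8$; the
whole suite completes in about a minute on one core, and
`scripts/acceptance.R` recomputes the headline quantities in under a
minute. Tolerances: hypergeometric p vs the exact combinatorial oracle to
1e-12; median normalization equalizes column medians to below 1e-9;
deterministic outputs are compared byte-for-byte. Degenerate inputs are
errors, not silent results: all-missing runs, empty tag sets, inconsistent
overlap counts, empty mapped query sides, and invalid configurations all
abort with named messages before computation.

## Known limitations

* The RI/RS selection inherits the raw-p selection rule of the emulated
  analysis; with ~2,300 tested proteins this implies a non-trivial
  false-positive load in the DKD-GP sets (the BH q column is provided, and
  `select = "q"` switches the rule).
* The connectivity module implements the classic build-02 procedure and a
  simplified CMap2 analogue; published compound tables from the production
  services are used as schema references only and are not reproducible
  from this code.
* Specificity uses generated null queries rather than a historical query
  compendium.
* The permutation p is sign-directed and approximately calibrated only
  (see above); rank order, not p magnitude, is the primary output.
* Ortholog mapping quality is entirely determined by the supplied table;
  protein-level signatures queried against transcriptional databases
  assume protein and mRNA changes agree in direction.

## Reproducing the headline numbers

```{r acceptance}
# from the repository root:
#   Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The script simulates the default study at the given seed, runs every stage,
and writes the recomputed quantities (quantified-protein count, mean
missingness, flowchart counts and identities, RI/RS recovery, type-I rate
on a null study, reverser rank/enrichment/support, planted gene-set
recovery) as JSON. Nothing in it is hard-coded: rerunning with another seed
regenerates everything from scratch.
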
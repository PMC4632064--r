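---
title: "Rare-variant gene-set burden analysis: models, parameters and design choices"
author: "rvburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant gene-set burden analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The scientific setting

22q11.2 deletion syndrome (22q11.2DS) is a genomic disorder in which a
recurrent hemizygous microdeletion confers roughly 25% risk of
schizophrenia. An extreme-phenotype design — contrasting deletion carriers
who developed schizophrenia against carriers who remained free of psychosis
past age 50 — concentrates information into very few genomes, and the
analysis must therefore aggregate: not variant-by-variant association, but
the *burden* of qualifying rare variants within biologically motivated gene
sets, compared between groups.

`rvburden` implements this workflow end to end: variant prioritization into
three damage categories, percent-normalized gene-set burden testing with a
joint multivariate stage, effect-size and power projection, polygenic risk
scoring, and conservation-restricted noncoding-RNA burden, together with a
synthetic-cohort generator so every stage is testable without subject-level
data (which, for such cohorts, is not publicly distributable).

## Variant prioritization

A variant enters the analysis only if it passes, in order:

1. **Quality** — only calls flagged high-quality (VCF `FILTER` of `PASS`
   or `.`).
2. **Rarity** — alternate-allele frequency strictly below a threshold
   (default 0.01) in *every* population database where the variant is
   observed. A variant absent from a database imposes no constraint there;
   a variant observed nowhere is rare. This matches standard rare-variant
   practice: the rarity rule is only evaluable on observed frequencies.
3. **Category** — one of three mutually exclusive damage categories, most
   severe first:
   - `LOF`: stop-gain/nonsense, frameshift, core splice-site;
   - `DAMAGING_MISSENSE`: missense called deleterious by at least
     `consensus_k` of `consensus_n` prediction tools (default 5 of 7; the
     tool panel is consumed as seven annotation columns, not recomputed);
   - `SPLICE_REG`: predicted exon-inclusion change at or below
     `splice_score_cutoff` (default −5 percent-units), for variants outside
     the LoF classes. The per-variant splicing score comes from an upstream
     predictor and is consumed as an annotation column.

   The most-severe-first precedence resolves variants qualifying under
   several rules (e.g., a damaging missense with a poor splicing score
   stays `DAMAGING_MISSENSE`); a precedence is needed because the
   categories must partition the qualifying variants, and most-severe-first
   is the conventional resolution.
4. **Region partition** — qualifying variants overlapping the configured
   22q11.2 exclusion interval or chromosome X are tallied separately and
   excluded from burden testing *a priori* (hemizygosity makes the deleted
   interval incomparable, and X-linked counts are confounded by sex in a
   small mixed-sex cohort). The shipped default interval is
   chr22:18,900,000–21,500,000 (hg19, the typical deletion span), supplied
   as a BED input rather than a constant because the analysis states the
   exclusion rule, not fixed coordinates; per-cohort deletion boundaries
   can be substituted.

Zygosity is ignored in counting — a homozygous variant counts once. This is
haploinsufficiency-model counting: what matters is whether a gene copy is
damaged, and burden tables count variants, not alleles.

Internally, coordinates follow one rule: BED inputs stay 0-based
half-open, VCF positions stay 1-based, and a position $p$ overlaps a
region $[s, e)$ iff $s < p \le e$. Conversion happens only in readers and
writers, and the boundary behaviour is property-tested.

## Percent normalization and the burden tests

For a gene set $G$ and category $c$, subject $i$ contributes the count
$k_i$ of retained category-$c$ variants whose annotated genes intersect
$G$ (a variant counted once even if it hits two set genes), and the
percent burden

$$b_i = 100 \cdot k_i / K_i,$$

where $K_i$ is the subject's genome-wide total of the category's *broad
class* — all missense variants (damaging or not) for `DAMAGING_MISSENSE`,
all LoF-class variants for `LOF`, and the splice-qualifying variants
themselves for `SPLICE_REG` — computed on the same quality-, rarity- and
region-filtered stream. The normalization corrects for per-subject
differences in overall variant load (platform and ancestry effects), so
group comparisons ask "is a *larger share* of this subject's damage in
these genes?".

- **Univariate test:** one-sided pooled-variance two-sample $t$ on the
  percents, direction fixed as case > control. Pooled (Student) rather
  than Welch because it is the classical default and makes the Hotelling
  reduction below exact; Welch is available by flag. Degenerate inputs
  (zero pooled variance) return $p = 0.5$ at equal means, $0/1$ by sign
  otherwise, flagged.
- **Screening rule:** a set enters the joint stage when any category is
  nominally significant — strictly $p < 0.05$ for damaging missense,
  $p < 0.10$ for LoF and splicing-regulatory (the rarer categories get the
  laxer screen).
- **Joint test:** two-sample Hotelling $T^2$ on the per-subject vectors of
  the three category percents,
  $T^2 = \frac{n_1 n_2}{n_1+n_2}\, \mathbf d^\top S^{-1} \mathbf d$, with
  $F = \frac{n_1+n_2-p-1}{p\,(n_1+n_2-2)} T^2$ on $(p,\; n_1+n_2-p-1)$
  degrees of freedom. Whether the joint stage should run on percents or
  raw counts is genuinely open; percents are the default for consistency
  with the univariate tests, with a raw-count mode by flag. A
  zero-variance category makes the pooled covariance singular;
  `hotelling_t2()` errors with the offending variable names by default
  (a silent pseudo-inverse would change the null distribution), while the
  pipeline passes `drop_degenerate = TRUE` because an all-zero category is
  routine at $n = 9$ — the dropped variables are reported alongside the
  result.
- **Effect size:** the between-group ratio of mean raw counts,
  `mean(case)/mean(control)`, reported as `nc` (not calculable) when the
  control mean is zero. Displayed means are raw per-subject count means
  even though tests run on percents, mirroring how such burden tables are
  printed.
- **No multiple-testing correction** is applied; every p-value is labelled
  nominal. A hypothesis-generating extreme-phenotype screen expects
  replication in a larger cohort rather than family-wise control.

The DGCR8 restriction — intersecting each set with genes predicted to be
dysregulated under haploinsufficiency of *DGCR8*, the miRNA-biogenesis
gene inside the deletion — produces a restricted twin of every set,
analysed identically.

Display rounding follows the reference table format: two decimals for
means and ratios, three for p-values.

## Effect sizes and power projection

Cohen's $d$ is the standardized mean difference with the df-weighted
pooled SD, sign convention case − control. Power for a two-sample $t$ at
$n$ per group uses the exact noncentral-$t$ computation: noncentrality
$\delta = d\sqrt{n_1 n_2/(n_1+n_2)}$, $\mathrm{df} = n_1+n_2-2$, power
$= P(T'_{\delta} > t_{\mathrm{crit}})$ (both tails when two-sided). The
normal approximation is deliberately avoided — at the sample sizes where
such projections matter it is visibly off — and the implementation is
cross-checked in the tests against `stats::power.t.test` (whose two-sided
variant omits the opposite-tail rejection region; the tests account for
that) and against simulation. Defaults are $\alpha = 0.05$, one-sided, to
match the burden tests' sidedness; both sidedness options reproduce the
reference projections (power > 0.99 at $d = 1.90$ and > 0.94 at
$d = 0.55$ for $N = 100$ per group):

```{r power}
power_two_sample_t(d = 1.90, n_per_group = 100)$power
power_two_sample_t(d = 0.55, n_per_group = 100)$power
```

## Polygenic risk scoring

Panel SNPs (with published effect alleles, odds ratios and association
p-values) are matched per subject either by a variant call at the same
coordinates with agreeing alleles — effect-allele count 0/1/2 from the
genotype — or by falling inside one of the subject's *reference intervals*
(spans confidently called identical to the reference), which asserts
homozygous reference: count 2 when the effect allele is the reference
base, 0 otherwise. Resolving a reference-interval match requires knowing
which panel allele is the reference base; the PRS table accepts an
optional `ref_allele` column and otherwise assumes `other_allele` is the
reference, the usual convention for reference-aligned summary tables. A
call with non-matching alleles leaves the SNP unresolved (logged, not an
error), and only SNPs resolved in *every* subject are scored — the only
completeness mechanism; there is no imputation and no strand
reconciliation (alleles must match as given).

Scores are $S_i = \sum_j a_{ij}\beta_j$ with $\beta_j = \ln \mathrm{OR}_j$,
accumulated in sorted key order so SNP order cannot perturb the floating
sum. The threshold sweep uses inclusive risk bins
($p \le 0.001, 0.0001, 0.00001$) and strict negative-control bins
($p > 0.5, > 0.9$), exactly as such bins are conventionally printed.
Group comparison: one-sided pooled $t$, one-sided Wilcoxon rank-sum
(exact for combined $n \le 20$ without ties, tie-corrected normal
approximation otherwise), and the maximum correctly-predicted percentage —
implemented as *balanced* accuracy (mean of per-group percent correct) of
the rule "case if score ≥ threshold", maximized over midpoints of adjacent
distinct scores, with overall accuracy by flag. The printed definition of
"percentage correctly predicted" is not fully specified in this
literature; balanced accuracy is consistent with the reported 83%/75%
values on a 6-vs-3 cohort and does not reward always guessing the majority
class.

## Noncoding RNA burden

lincRNA burden counts *distinct genes hit* per subject (two variants in
one gene count once), not variants — at these sample sizes the
gene-level unit is the robust one, and it matches how such results are
reported; a variant-count mode is available. Conservation restriction
ranks lincRNA genes by their regional conservation score and keeps the top
$\lceil 0.10 \cdot N \rceil$ (ties at the cut all included); when per-base
scores are supplied, an optional nucleotide-level cutoff applies at the
variant position, so both stated levels of conservation prioritization are
honoured independently. The one-sided test runs on the conserved-subset
counts. miRNA genes are tiny, so rarity is broadened to < 5% and the
result is a per-subject tally; a burden test is attempted only when both
groups have a nonzero subject and the cohort-wide total reaches a
configurable minimum (default 5), otherwise a "tally-only" decision is
emitted rather than a meaningless p-value.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, at
the emulated study's conditions: 6 cases vs 3 controls; genome-wide
Poisson loads of 13.8 LoF and 94.3 missense variants per subject; lincRNA
hit means 2.0 (case) and 1.3 (control). Values the study design does not
pin down were chosen once as field-realistic defaults: splicing-regulatory
rate 20/subject, damaging share of missense 0.35, a 1000-gene toy
universe, a 500-SNP PRS panel with 10% causal SNPs (positive log odds
ratios, association $p \le 0.001$, case effect-allele frequency shifted by
0.15), miRNA rate 0.1/subject, and Beta(2, 5) regional conservation.
Poisson is the minimal noise model given that only means are specified; a
negative-binomial option adds overdispersion. Gene-set enrichment is
configured as case:control rate ratios; effect sets are generated on
disjoint gene pools so the configured ratio is exact.

Coordinates are fabricated on a toy genome (chr1–chr6, a designated
chr22 interval, chrX, a PRS contig) because positions carry no signal in
the burden model beyond region membership — which is exactly what the
exclusion logic needs exercised. The generator also plants
filter-exercising noise: common, low-quality and synonymous variants that
must be discarded, and qualifying variants inside the 22q11.2 interval and
on X that must be tallied but never tested.

What passing tests on this generator do **not** show about real data:
no linkage disequilibrium or haplotype structure, no annotation error or
tool disagreement structure, no relatedness or ancestry stratification,
no platform-specific callability patterns, and gene lengths do not vary —
so real-data burdens need the percent normalization more than synthetic
ones do. The generator validates the machinery (counting, partitioning,
test calibration, recovery of configured effects), not the biology.

A counts-level shortcut, `simulate_burden_replicate()`, draws only
$(k_i, K_i)$ pairs for calibration studies; the test suite uses it to
verify type-I error of the one-sided burden test at $\alpha = 0.05$ over
1000 replicates of a 50-vs-50 null cohort (band 0.03–0.07) and
ratio-of-means recovery within 10% at 100 subjects per group over 200
replicates for true ratios 1.5/2/4 — sizes chosen so the whole suite runs
comfortably on a laptop while keeping Monte-Carlo error well inside the
asserted bands.

## The worked example

`generate_worked_example()` builds a deterministic 6-vs-3 cohort whose
damaging-missense counts encode fixed group means, so the ratio-of-means
column of the report reproduces exactly: 1.80 (neuron projection, 54
case variants over 6 subjects vs 15 over 3), 4.00 (its DGCR8-restricted
twin, 16 vs 2), 2.50 (synaptic pathways), 1.27 (abnormal sensory system),
and `nc` for a set with no control variants. Genome-wide missense totals
vary mildly across subjects (90–100) so the percent-normalized tests are
non-degenerate. The p-values of this fixture are *not* meaningful
reproductions — they depend on the within-group spread, which the fixture
fixes arbitrarily; only the means, ratios and the `nc` convention are the
reproduced quantities.

```{r worked, message = FALSE}
we <- generate_worked_example()
pvs <- prioritize(we$calls, we$annotations, we$regions_22q11, we$subjects)
ba <- run_burden_analysis(pvs, we$gene_sets, restriction = we$dgcr8_genes)
subset(ba$results, category == "DAMAGING_MISSENSE",
       select = c(gene_set, mean_case, mean_control, effect_ratio))
```

## Numerical and degenerate-input choices

- Rarity and screening thresholds are strict (`<`), threshold bins follow
  the printed inclusive/strict rules (`<=` risk, `>` control); boundary
  cases are unit-tested.
- Missing population frequency = unobserved = no constraint; a missense
  variant without all seven tool calls is a hard error (the consensus rule
  is undefined on partial panels).
- `hotelling_t2()` requires $n_1+n_2-2 \ge p$ and a nonsingular pooled
  covariance; degenerate variables are either a named error or dropped on
  request (see above). At $p = 1$ it reduces to the squared pooled $t$,
  asserted to $10^{-10}$.
- Ties in the conservation ranking at the cut are all included, making the
  restriction deterministic under score ties.
- Reports and generated cohorts are byte-reproducible given the same seed
  and inputs; scores accumulate in sorted key order.

## Known limitations

- Gene symbols are opaque upper-case strings; no alias resolution.
- No de novo/inherited status, no CNV/SV handling, no covariate
  adjustment, no permutation tests, and no LD-aware PRS processing
  (clumping, strand reconciliation) — the SNP panel is consumed as
  published.
- The Hotelling percent-vs-count question and the exact definition of the
  correctly-predicted percentage are resolved by documented defaults with
  flags, as discussed above.
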
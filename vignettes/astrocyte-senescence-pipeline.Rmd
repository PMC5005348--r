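---
title: "Methods: negative-binomial differential expression and gene-set analysis for astrocyte senescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: negative-binomial differential expression and gene-set analysis for astrocyte senescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senastro)
```

# Scope and model

`senastro` implements the computational arm of a two-condition bulk RNA-seq
study of oxidative stress-induced senescence in cultured human astrocytes:
pre-senescent versus senescent cells, two biological replicates per
condition. The package covers five stages — differential expression,
gene-ontology enrichment, tissue-expression summaries, gene-set overlap and
qRT-PCR validation — plus a synthetic-data generator that emulates the
study design so each stage's statistical behaviour can be measured.

## Count model

Counts $K_{ij}$ for gene $i$ in sample $j$ are negative binomial,

$$K_{ij} \sim \mathrm{NB}\!\left(\mu_{ij} = q_{i,\rho(j)}\, s_j,\;
\mathrm{Var} = \mu_{ij} + \alpha_i \mu_{ij}^2\right),$$

where $q_{i,\rho(j)}$ is the per-condition expression level, $s_j$ a
per-sample size factor and $\alpha_i$ the gene's dispersion. The model
assumes independent samples, a common dispersion across conditions, and no
additional structure (no batch terms, no length/GC effects).

**Size factors** are median-of-ratios: each column is compared to the
per-gene geometric-mean reference, and $s_j$ is the median ratio over genes
detected in every sample. The median is taken on the log scale
(`exp(median(log ratio))`), the convention of the NB differential-expression
packages this module follows; for an odd number of reference genes this is
exactly the median ratio, and for an even number the two central ratios are
interpolated geometrically rather than arithmetically. There is no
pseudo-reference fallback: if no gene is positive in all samples the
function stops, because the estimator is undefined there and silently
switching estimators would change results between datasets.

**Dispersions** are estimated per gene by method of moments on normalized
counts, $\hat\alpha_i = \max\{0, (v_i - \bar\mu_i)/\bar\mu_i^2\}$ with
$v_i$ the within-condition pooled variance, then shared through the
parametric curve $\alpha(\mu) = a_0 + a_1/\mu$ fitted by ordinary least
squares of $\hat\alpha$ on $1/\mu$. The working dispersion is
$\max(\hat\alpha_i, \alpha(\bar\mu_i))$ — the conservative choice
appropriate when each condition contributes only two replicates, since a
per-gene estimate from two observations is extremely noisy and taking the
maximum guards against underestimating variability (at the price of some
power). Fitted values are floored at $10^{-8}$ so downstream likelihoods
stay defined.

A note on the moment estimator: because the estimated mean appears in the
denominator, $\hat\alpha$ carries a small finite-replicate bias of relative
order $\alpha/r$. The recovery test therefore checks the fitted intercept
at $r = 10$ against a band (±0.03 at $\alpha = 0.2$) sized for three
Monte-Carlo standard errors *plus* that bias, rather than the naive
regression standard error, which is tighter than the estimator is accurate.

## The conditional exact test

For each gene the per-condition sums $k_A, k_B$ are compared conditionally
on their total. Each sum is NB with mean $q\sum_{j\in g} s_j$ and variance
$q\sum s_j + \alpha q^2 \sum s_j^2$ ($q$ = pooled mean estimate), and the
two-sided p-value is

$$p = \frac{\sum_{a:\, P(a) \le P(k_A)} P(a)}{\sum_a P(a)},
\qquad P(a) = P_A(a)\, P_B(k_A + k_B - a).$$

Two numerical choices matter. First, split probabilities are compared with
a relative tolerance of $10^{-7}$ when accumulating the "no more likely"
set, so floating-point noise cannot drop an exactly symmetric split; the
test fixture verifies $k_A = k_B \Rightarrow p = 1$ with equal size
factors. Second, the enumeration runs over the full support $0..k_A+k_B$
(errors above $2\times10^6$ total counts rather than silently truncating);
at the depths the package targets this is exact and fast. In the
$\alpha \to 0$ limit the test converges to the conditional binomial test,
which the suite checks to $10^{-3}$.

Genes with zero counts in every sample are excluded before testing and are
not part of the "detected transcripts" denominator. When either normalized
mean is zero, the fold change uses a pseudocount of 0.5 on both means and
the gene is flagged (`pseudocount` column) — fold changes stay finite
without disturbing genes where both means are positive.

BH adjustment, and the BY adjustment used for gene sets, delegate to
`stats::p.adjust`; re-implementing a step-up procedure the standard library
already provides would only add risk.

## Sample-level QC

PCA runs on $\log_2(\text{normalized count} + 1)$ over samples; the
transformation is a package choice (the study does not state one) — it
stabilises the heavy right tail of count data while keeping zeros finite.
If total variance is numerically zero the result is flagged `degenerate`
with all variance fractions 0 rather than returning noise components.
Replicate agreement is the squared Pearson correlation of the same
log-normalized values within condition.

# Gene-set enrichment

With universe size $N$ (detected transcripts), term size $B$, query size
$n$ and intersection $b$: enrichment $= (b/n)/(B/N)$, $p = P(X \ge b)$
hypergeometric. A term is *enriched* when count $\ge 10$, enrichment
$\ge 2$ (both inclusive, "10 or greater" / "2 or greater") and BY FDR
strictly $< 10\%$. The BY family is all terms tested in the run, and FDR
filtering happens **before** collapsing — the collapsing rule is defined on
enriched terms, and collapsing first would make the FDR family depend on
its own output.

**Collapsing.** Enriched terms sharing $\ge 25$ differentially expressed
transcripts are functionally synonymous and merged. Pairwise merging is
order-dependent, so the implementation builds the sharing graph and takes
connected components (transitive closure); the test suite asserts
permutation invariance and idempotence on block-structured fixtures. Each
component is represented by its smallest-FDR member, ties broken
lexicographically by term id so output is fully deterministic.

**Weights.** Each gene's weight is the reciprocal of the number of terms
containing it, and a term's weight is the sum over its DE members. The
membership count is taken *within the term list under analysis* (typically
the filtered enriched terms): the annotation-wide count is simply not
available from the inputs this pipeline consumes, and the within-list
convention has the useful identity that term weights sum to the number of
distinct annotated DE genes, which the suite checks on random collections.
Users comparing against annotation-wide weighting should be aware of this
interpretation.

**Tissue summaries** aggregate set-size mass: the CNS share of a record
table is $\sum(\text{CNS set sizes})/\sum(\text{all set sizes})$, with hit
counts ($b$) on the query side and term sizes ($B$) on the universe side,
reported as rounded percentages. The package's worked example —
$100 \cdot 7858 / 29348 \to 27\%$ — is computed by this function in the
acceptance script.

# Set overlap

The representation factor $x N/(n_1 n_2)$ is algebraically the same
quantity as the enrichment ratio, and the suite asserts the cross-module
identity on random inputs. Significance is hypergeometric in both
directions; the two tails share the mass at $x$, so $p_{over} + p_{under}
\ge 1$. Defaults follow the study: universe 19580. The study's figures also
quote 19520 detected transcripts in the differential-expression summary;
the configuration deliberately keeps these as two independent numbers (a
DE-summary denominator and an overlap universe) rather than reconciling
them, since the provenance of the 60-transcript difference is not
recoverable from the inputs.

The matched-expression filter keeps genes strictly above the cutoff (100,
in whatever matched units both datasets share) in both datasets or strictly
below in both — values exactly at the cutoff are excluded, reading "greater
than or less than" literally. Direction intersection treats "decrease
greater than 1.5-fold" as linear ratio $\le 1/1.5$ (inclusive).

# qRT-PCR validation

Standard comparative Ct: technical wells are averaged per (gene, sample);
$\Delta Ct$ subtracts the reference gene (GAPDH); $\Delta\Delta Ct$
subtracts the baseline-condition mean $\Delta Ct$ from the treated mean,
averaged within condition before differencing (error bars in validation
figures are SEMs over independent samples, so aggregation happens at the
sample level); $RQ = 2^{-\Delta\Delta Ct}$. Per-sample RQs are retained for
the per-gene two-sample t-test, equal-variance Student by default (as
validation captions specify) with Welch behind a flag. Zero-variance
degenerate input returns $p = 1$ for identical groups (and 0 when the
means differ), since `stats::t.test` refuses essentially-constant data.

Concordance between qPCR and RNA-seq $\log_2$ fold changes is Pearson $r$
with a Fisher-z 95% interval, $\tanh(\operatorname{atanh} r \pm
1.96/\sqrt{n-3})$. The interval construction used in the original
validation figure is not stated, so the package documents Fisher-z as its
method and does not treat any printed interval as a target; at $|r| = 1$
the interval degenerates to the point $r$.

# The synthetic-data generator

`simulate_counts()` draws from exactly the model the DE stage assumes:
point-null non-DE genes ($\delta_i = 0$), a configured DE fraction
(default 0.18, the proportion observed in the study), log-normal baseline
means (median 100), dispersion $\alpha(\mu) = a_0 + a_1/\mu$ with defaults
$a_0 = 0.01$, $a_1 = 1$ (typical bulk RNA-seq values: moderate biological
variability plus shot-noise-dominated low counts), and size factors spread
over $2^{\pm 0.8}$, emulating the roughly three-fold library-depth range of
the study. The default design is $2\times2$ like the study, but the
replicate count is a parameter so power and FDR suites can use larger
designs. Non-zero fold changes default to balanced signs with magnitude at
least $\log_2 1.5$, so every planted DE gene is in principle callable at
the study's fold filter.

`simulate_genesets()` plants (i) enriched terms by odds-weighted sampling
of DE genes and (ii) collapse blocks whose members share an *exact* number
of DE genes — fillers are drawn from non-DE genes only, so a block planted
at 25 shared genes collapses and one at 24 does not, deterministically.
`simulate_tissue_annotation()` plants CNS-like blocks that oversample
downregulated genes; `simulate_ct_table()` generates per-well Ct values
under $Ct = \text{intercept} - \log_2(\text{expression}) + \varepsilon$,
so $\Delta\Delta Ct$ recovers $2^{\delta}$ exactly at zero noise. All
generators are pure functions of their parameters and seed, and return a
truth object sufficient to score the downstream stage without re-reading
parameters.

**What passing these tests does and does not show.** The generator matches
the analysis model by construction, so recovery and calibration results
demonstrate correctness of the implementation, not robustness of the method
to real-data violations: outlier samples, batch effects, length/GC bias,
correlated genes within pathways, or annotation bias are all absent. In
particular, the hierarchical GO structure (parent terms containing their
children) is only crudely mimicked by planted sharing blocks.

# Problem sizes and test design

The statistical suites run at sizes chosen to make Monte-Carlo bands
meaningful while keeping the default test run fast: the all-null FDR suite
uses 200 datasets of 2000 genes in the $2\times2$ design; fold-change
recovery uses 1000 genes at 5 replicates with planted $|\delta| = 2$ and
means $\ge 100$ (mean absolute error bound 0.25); planted-enrichment
sensitivity uses 20 terms at odds 5 and sizes 50–150 (bound 0.9); null
calibrations use 500 terms / 500 overlap draws with three-Monte-Carlo-SE
bands around 0.05. Exact-test oracle equivalence enumerates every split of
every total up to 20 under three size-factor/dispersion settings, and
hypergeometric tails are checked against closed-form binomial-coefficient
sums for universes up to 30 (plus one full $\binom{20}{8}$ subset
enumeration). The acceptance script reuses these designs at 100 null
datasets and reports each quantity with the problem size it used.

# Known limitations

* Single-factor, two-condition designs only; no covariates or shrinkage
  estimators of fold change.
* The exact test operates on condition sums, as the original conditional
  formulation does; it does not model per-replicate variation beyond the
  dispersion estimate.
* Gene weights are list-relative (see above), not annotation-wide.
* GO structure is flat: no ancestor propagation, and the Fisher test is
  the plain hypergeometric, not a jackknifed variant some annotation
  servers use.
* The qPCR module assumes perfect amplification efficiency (the factor-2
  base of the $\Delta\Delta Ct$ model).
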
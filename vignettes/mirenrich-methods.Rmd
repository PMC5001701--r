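---
title: "Methods: relevance-weighted miRNA-in-pathway enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relevance-weighted miRNA-in-pathway enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirenrich)
```

## The problem and the model

A microRNA (miRNA) represses genes post-transcriptionally, both directly
and through the transcription factors (TFs) of those genes. Given a
curated panel of disease-relevant pathways, we ask: which miRNAs have
their target genes over-represented across the panel as a whole? The
pipeline ranks miRNAs by a single combined significance level built in
four stages.

**1. Pathway extension.** Each pathway's gene set is extended with every
TF that has at least one regulatory edge into a member gene. The
extension is single-pass over the original members: TFs of TFs are not
pulled in, because iterating the closure rapidly absorbs much of the
regulatory genome and dilutes pathway identity. Pathways are treated
independently; a TF acquired by one pathway does not alter any other.

**2. Per-pair over-representation.** For a miRNA with target set $T$ and
a pathway with extended gene set $P$, the background population is the
*target universe* $U$: the union of the target sets of all analyzed
miRNAs. Genes never annotated as anyone's target carry no information
under the annotation process, so the pathway side is restricted to
$P \cap U$. The contingency counts are

$$N_{p+} = |T \cap P \cap U|, \quad N_{p-} = |P \cap U| - N_{p+}, \quad
N_{m+} = |T|, \quad N_{m-} = |U| - |T|,$$

and the pair p-value is the one-tailed Fisher exact (upper-tail
hypergeometric) probability
$\Pr(X \ge N_{p+})$ with $X \sim \mathrm{Hyper}(N = N_{m+}+N_{m-},
K = N_{p+}+N_{p-}, n = N_{m+})$. A pair with $|P \cap U| = 0$ is
*degenerate*: it carries no evidence either way, so it is dropped from
the miRNA's combination together with its weight rather than entered as
$p = 1$ (which would penalize miRNAs for untestable pathways). Because
degeneracy depends only on the pathway and the universe, the same
pathways drop for every miRNA.

**3. FDR before combination.** Within each miRNA, the pathway p-values
are Benjamini–Hochberg adjusted. Adjusting *before* combining is
statistically unconventional — the adjusted values are no longer uniform
under the null — but it is the documented order of the original
procedure, and the permutation machinery below calibrates the combined
statistic around exactly the statistic that is computed, adjusted values
included. The adjustment scope is a switch: `per_mirna` (default)
treats one miRNA's 39 pathway tests as the family, matching the
per-miRNA combination that follows; `global` pools all pairs, which
couples miRNAs' scores through the shared adjustment and is provided for
sensitivity analysis only.

**4. Weighted Lancaster combination.** Each adjusted p-value is mapped
through the quantile transform
$q_{w}(1-p)$ of a $\chi^2_{w}$ distribution — implemented as
$\mathrm{Gamma}(w/2, \text{scale } 2)$ so fractional weights are exact —
and summed:

$$T = \sum_i F^{-1}_{\chi^2_{w_i}}(1 - p_i).$$

The weight $w_i$ encodes the curator-assigned relevance class of pathway
$i$: class A (highly specific) $w = 2$, class B $w = 1$, class C (very
general) $w = 0.5$. At $w = 2$ the transform is Fisher's $-2\log p$, so
with an all-A panel the method reduces exactly to Fisher's combined
probability test. Weights are configurable but default to 2/1/0.5.

miRNAs with empty target sets cannot be enriched and are skipped
entirely (and logged), rather than scored with $p = 1$ across the board,
which would distort the BH pool.

## The null of the combined statistic

Because gammas with a common scale add, under independent uniform
p-values $T \sim \mathrm{Gamma}(\sum_i w_i / 2, 2) = \chi^2_{\sum w_i}$
*exactly*; `null_kind = "independent"` uses this closed form. Two things
break independence in practice: pathways share genes (positive
correlation between pair tests), and the BH step distorts the marginal
distribution of what is summed. Both are handled empirically:

- `estimate_null()` draws pseudo-miRNAs — uniform random subsets of the
  universe, sizes resampled from the empirical target-set sizes — and
  pushes each through the *identical* pipeline (contingency, Fisher,
  BH, transform, sum).
- `moment_matched` (the default) fits a Brown-style scaled chi-square to
  the permuted statistics: $\text{scale} = \mathrm{Var}(T)/(2\,\overline{T})$,
  $\mathrm{df}_\text{eff} = 2\,\overline{T}^2/\mathrm{Var}(T)$. Perfectly
  duplicated pathways halve the effective df, as they should.
- `permutation` uses the empirical tail
  $(1 + \#\{T_\text{perm} \ge T\})/(1 + n_\text{perm})$, which is
  guaranteed in $(0, 1]$ but granular below $1/n_\text{perm}$.

The default is `moment_matched` with 1000 permutations: it is smooth in
the far tail where the permutation null is granular, while inheriting
the permutation null's robustness to both correlation and the BH
distortion. If the permuted variance is numerically degenerate the
estimator falls back to the independent form with a warning. The
selection threshold is strict, $p < 0.01$ by default, and ranking breaks
ties by larger $T$, then miRNA name, so output order is deterministic.

Zero p-values (floating underflow) are clamped to the smallest positive
double before the quantile transform; every clamp is logged. Reported
$-\log p$ values use base 10, recorded in the run manifest.

## Target modes and filters

Validated targets (VMT) and computationally predicted targets (CMT) are
two inputs to the same analysis; the loaders assume the CMT table is
already aggregated across prediction repositories, and the synthetic
generator enforces the superset property (every VMT set is contained in
its CMT set), which implies $N_{m+}^{\text{CMT}} \ge N_{m+}^{\text{VMT}}$
for every miRNA. miRNA name aliases (nomenclature version drift) are
applied before grouping, so rows recorded under an old name merge with
rows under the current one.

Two filters define the analyzed miRNA set: expression in a declared
tissue/cell vocabulary (defaulting to lung tissue, B lymphocytes,
natural killer lymphocytes, monocytes, dendritic cells, granulocytes,
and A549 cells), and intragenic residence in a host gene belonging to
any extended pathway. The two criteria are combined by union by default —
the published description reads as two parallel admission routes into
one annotated candidate list — with intersection available as a switch;
each candidate carries provenance flags. Filters run *before* scoring by
default (they define the dataset, and the universe, that the statistics
see); a `post` switch restricts the report instead, leaving every score
unchanged. Filtering never alters a p-value, only membership.

The random-pathway control re-runs the full pipeline on $k = 39$
pathways sampled uniformly without replacement from a pathway pool.
Random pathways have no curated class, so classes are assigned by
policy: `preserve_proportions` (default) samples labels from the
configured A/B/C proportions; `all_B` weighs everything 1. A curated
panel whose selection count clearly exceeds its own random control
supports the specificity of the panel.

## The synthetic generator

`synthetic_scenario()` fixes the study conditions; `generate_synthetic_data()`
writes every file dialect the loaders read, plus a truth table. Defaults
emulate the published setting at desk scale, chosen once:

- 39 pathways of 30–80 genes with class proportions A/B/C = 0.3/0.4/0.3
  (the curated panel mixes a minority of highly specific pathways with
  broader ones; the exact published proportions are not machine-readable,
  so a balanced mix was fixed). Classes are assigned deterministically in
  pathway-id order, so planted pathway ids have known classes.
- a 4000-gene pool, sized so that 39 disjoint pathways always fit
  (disjointness is the reference configuration for calibration studies)
  while remaining in the range of an ever-targeted background.
- 349 miRNAs (the published analyzed count) with 10–100 validated
  targets each, the density scale of validated-target repositories; CMT
  sets add 50% extra uniform targets on top of each VMT set.
- TF edges over a regulator subset of 2% of the gene pool (at least 5),
  each (regulator, gene) pair present with probability 0.05; regulators
  are ordinary pool genes, so extension genes can also be targets.
- expression coverage 0.7 (1–3 labels per covered miRNA) and intragenic
  fraction 0.3, loose desk-scale analogues of the published filters.

Pairwise pathway overlap is controlled by a shared core pool included in
every pathway, sized so two average pathways have the requested Jaccard
index; `overlap_jaccard = 0` partitions the gene pool instead, giving
exactly disjoint pathways. Infeasible combinations (pool too small,
shared pool larger than the smallest pathway) fail with the violated
bound.

A planted miRNA with odds $r$ on pathway union $P_u$ draws its target
count inside $P_u$ as $\mathrm{Bin}(|T|,\ r|P_u|/(r|P_u| + N - |P_u|))$
and then samples uniformly inside and outside. The binomial split makes
the expected in-pathway count exactly $|T| \cdot r|P_u|/(r|P_u| + N - |P_u|)$,
which a test can check in closed form — the main reason for preferring
it over sequential weighted draws, whose expectation is only
asymptotically equal. Everything is generated under a single seed;
identical scenarios produce byte-identical files.

What the generator does *not* emulate: real pathway topology and
size distributions, hub-gene structure in TF networks, correlated
target annotations between paralogous miRNAs, and annotation-depth bias
(well-studied miRNAs having systematically larger validated sets).
Passing calibration and recovery tests on this generator therefore
demonstrates correctness of the machinery, not performance on any real
annotation snapshot.

## Calibration and power at the default conditions

The test suite exercises the pipeline at fixed problem sizes chosen to
make its statistical properties measurable in seconds: 500 simulated
miRNAs for calibration runs, 1000 pseudo-miRNA permutations for null
estimation, and 20 generator seeds for recovery averages.

Two calibration facts are verified: on disjoint panels, the
moment-matched combined test rejects at the nominal 1% rate (within the
exact binomial 99% interval); under heavy overlap (Jaccard 0.5) the
independent null over-rejects several-fold while the moment-matched
null returns to nominal.

Recovery of planted signal at modest odds is *information-limited*, and
the package makes no pretense otherwise. At odds $r = 5$ with three
planted 30–80-gene pathways in a 4000-gene pool, a planted miRNA's
expected per-pathway hit count is about $0.06\,|T|$ against a background
of roughly $0.8$; for target sets below ~50 genes this is under 3
expected hits, which no exact test can separate from background, and
raising the odds cannot fix it (even $r \to \infty$ caps the hit count
at $|T|\,|P_j|/|P_u|$). Planted miRNAs with large target sets rank
highly; small-target planted miRNAs are, and should be, statistically
invisible. The truth-recovery report exists precisely to make this
visible per miRNA rather than hiding it in an average.

## Known limitations

- The gene namespace is one flat symbol space (uppercased, trimmed); no
  identifier conversion is attempted.
- The `global` FDR scope is approximated in the permutation null by
  per-pseudo-miRNA adjustment; the default `per_mirna` scope is exact.
- Combining *adjusted* p-values follows the original procedure; users
  wanting a conventional combined test should set `combine_on = "raw"`,
  whose independent null is exact.
- The moment-matched null fits two moments; in panels whose permuted
  statistic is strongly zero-inflated the far tail beyond the fitted
  region is approximate. The stored permutation statistics let users
  switch to the empirical tail at no extra cost.
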
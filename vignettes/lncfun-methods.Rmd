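---
title: "Guilt-by-association annotation of lncRNAs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guilt-by-association annotation of lncRNAs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncfun)
```

## The model

`lncfun` implements a two-stage guilt-by-association procedure for assigning
functions to long non-coding RNAs.

**Stage 1 — co-expression.** For each lncRNA $l$ and protein-coding gene $g$
with expression profiles $x_l, x_g$ over $T$ conditions, the sample Pearson
correlation $r_{lg}$ is computed. Its significance is assessed with the
exact test for bivariate-normal data,
$t = r\sqrt{T-2}/\sqrt{1-r^2} \sim t_{T-2}$, two-sided. All
lncRNA $\times$ coding pairs form a single multiple-testing family adjusted
by Benjamini–Hochberg, and a pair is retained when $|r| > 0.9$ (strict) and
adjusted $p < 0.05$ (strict). The assumptions are the usual ones for the
Pearson $t$-test: profiles roughly bivariate normal, conditions
exchangeable. With a tissue panel of $T = 19$ the test has only 17 degrees
of freedom, which is why the correlation threshold — not the p-value — does
most of the filtering work at the default operating point.

**Stage 2 — enrichment.** The retained neighbours of a lncRNA form its
query set of size $n$. For each functional term with $M$ annotated genes in
a universe of $N$ protein-coding genes, with $m$ annotated genes in the
query, the p-value is the hypergeometric upper tail
$$p = \sum_{i=m}^{\min(n,M)} \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}.$$
For GO, a term's annotated genes include those of all its descendants
(`is_a` and `part_of` edges, the pair safe for propagation); pathways are
flat sets. GO families are corrected by Benjamini–Yekutieli — the harmonic
penalty keeps FDR control valid under the strong positive dependence that
propagation induces between nested terms — and pathway families by
Benjamini–Hochberg, each family being exactly the set of terms tested for
that one query.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `r_cutoff` | 0.9 | correlation | strict absolute-correlation rule for calling a pair co-expressed |
| `coexp_alpha` | 0.05 | probability | cutoff on the BH-adjusted pair p-value |
| `min_term_size` | 5 | genes | terms with $M < 5$ are excluded: the tail test is unstable at tiny $M$ |
| `min_coexp` | 5 | genes | lncRNAs with $n < 5$ are explicitly "not annotatable" rather than weakly annotated |
| `enrich_alpha` | 0.05 | probability | cutoff on the corrected term p-value |
| `k` | 1 | lncRNAs | set analysis: minimum number of query lncRNAs a coding gene must support |

Both inequalities at stage 1 and the two size filters are strict, and the
defaults are the published operating point of the method. `K` trades recall
for precision in set analysis; no data-driven heuristic for choosing it is
implemented — it is an analyst's knob, to be raised with the size of the
query set.

The expression matrix is used exactly as read. A `log2(x+1)` transform and
a minimum-expression filter are exposed (`log_transform_expression()`,
`filter_expressed()`, both reachable from the run configuration) but default
to off: correlation on raw FPKM-like values is the documented behaviour,
and the flags exist because both preprocessing choices are common in
practice and materially change which pairs pass a 0.9 threshold.

## Choices the design left open

Several aspects of the procedure are under-determined by its published
description; the package fixes them as follows and treats them as its own
design decisions.

* **Form and family of the pair p-value.** The two-sided $t_{T-2}$ test is
  the standard exact test for a Pearson coefficient, and BH is applied over
  the full pair family: distinct gene pairs are far closer to the
  independent regime BH assumes than nested GO terms are, which is the same
  reasoning that assigns BY to GO and BH to pathways at stage 2.
* **Universe $N$.** The count of protein-coding genes in the supplied
  catalog (equivalently, the coding partition of the matrix), not only the
  annotated ones. This matches the constant published denominator and makes
  $N$ independent of annotation coverage; `enrich()` accepts any universe
  vector if the analyst prefers the annotated-only convention.
* **Correction family for GO.** One BY family per query across all loaded
  namespaces (restrictable with `namespaces=`). Per-namespace families are
  defensible too; corrected values are only comparable within whichever
  convention is used.
* **Undefined correlations.** Zero-variance profiles are dropped with a
  logged count, never assigned $r = 0$: a constant profile carries no
  co-expression evidence either way.
* **Evidence codes.** All GAF evidence codes are accepted by default, with
  an opt-in exclusion list (e.g. `IEA`), since the published method states
  no filter.
* **CLI configuration format.** The run configuration file is YAML (flags
  take precedence over the file, the file over defaults).

## The synthetic generator

`generate_fixture()` emulates the structure the method was designed for — a
gene $\times$ tissue panel with 19 conditions — using a Gaussian latent
factor model: module $j$ has a latent profile $z_j \sim N(0, I_T)$, and each
member gene (coding or lncRNA) is $s\,z_j + \varepsilon$ with
$\varepsilon \sim N(0, \sigma^2 I_T)$. Two members then have expected
correlation $\rho = s^2/(s^2+\sigma^2)$, so the generator solves
$s = \sigma\sqrt{\rho/(1-\rho)}$ for the requested $\rho$ (default 0.95 —
high enough that, with the sampling spread of $r$ at $T = 19$
(Fisher-$z$ SD $\approx 0.25$), most within-module pairs clear the 0.9
threshold). Background genes are independent noise. Values are shifted by
the global minimum to be non-negative (Pearson correlation is
translation-invariant, so planted correlations are untouched); an
exponentiation option gives skewed FPKM-like marginals instead. Each
module's coding genes are directly annotated to a planted leaf GO term
under a common root, and to one pathway, with defaults (5 modules, 20
coding + 3 lncRNA members, 200 + 20 background genes) chosen so every
planted term clears the $M \ge 5$ filter with a wide margin and the
universe is large enough for the tail test to be discriminative.

What the fixture deliberately does **not** emulate: count noise
(negative-binomial dispersion, library-size effects), heavy-tailed or
skewed expression marginals in the default shift mode, correlated
background structure, and annotation incompleteness or bias. Passing the
planted-recovery tests therefore demonstrates that the pipeline's wiring
and statistics are correct under its own model, not that the biological
annotations produced from any real panel are accurate.

## Numerical choices

* The hypergeometric tail is evaluated in log space: terms
  $\log\binom{M}{i} + \log\binom{N-M}{n-i} - \log\binom{N}{n}$ via
  `lchoose` (log-gamma), combined by log-sum-exp from the smallest term
  upward in a reverse cumulative pass. p-values of order $10^{-109}$ (and
  anything above ~$10^{-300}$) are computed without underflow at relative
  error far below $10^{-6}$; $m = 0$ returns exactly 1; the log of the full
  sum is pinned to 0.
* The test suite checks this path against an *exact* oracle: big-integer
  Pascal-triangle binomials (base-$2^{24}$ limbs, every limb operation below
  $2^{53}$ and hence exact in doubles) summed term by term, for **all**
  instances with $N \le 60$, where the largest value $\binom{60}{30} < 2^{57}$
  still fits in three limbs. Base R's own `choose(60, 30)` is off by 272
  from the exact integer, which is precisely the kind of error this oracle
  is immune to.
* Correlations from the blocked matrix product are clamped to $[-1, 1]$;
  results are invariant to block size, and all outputs are deterministically
  ordered (lexicographic by lncRNA then coding gene; enrichment sorted by
  corrected p with raw-p and term-ID tie-breaks) so repeated runs are
  byte-identical.
* Network and expression TSVs are written at 17 significant digits so round
  trips are lossless.

## Validation problem sizes

The suite validates at sizes chosen to exercise every code path while
remaining quick on a laptop: the exhaustive oracle comparison covers all
$(N \le 60, M, n, m)$ instances; planted-truth recovery runs the full
pipeline on 20 fixture seeds at the default configuration (335 genes
$\times$ 19 conditions, 10,500 correlation tests per seed) and requires at
least 90% of planted (lncRNA, term) pairs significant at corrected
$p < 0.05$ with at most 5% of non-planted leaf pairs; null calibration
draws 300 random 74-gene queries from an independent-expression fixture and
requires the raw rejection fraction at 0.05 to lie in $0.05 \pm 0.02$ —
the discrete hypergeometric null is sub-uniform, so the analytic value at
these sizes is $\approx 0.036$, comfortably inside the band but below the
nominal rate, which is expected behaviour, not an error.

## Known limitations

* Guilt-by-association transfers annotation through correlation only;
  causal or physical involvement is not implied, and anti-correlated
  neighbours ($r < -0.9$) contribute to the query set without any sign
  distinction downstream.
* Corrected p-values depend on the family actually tested (which terms were
  loaded, namespace restriction), so they are comparable only within one
  configuration.
* The Pearson test's normality assumption is doubtful for raw FPKM; the
  log-transform flag mitigates but the package deliberately does not choose
  for the analyst.
* Single-cell matrices are accepted (conditions = cells or cluster
  averages) but the zero-inflation typical of such data weakens Pearson
  correlation; no imputation is provided.
* OBO parsing covers the subset of OBO 1.2 needed for GO releases (`id`,
  `name`, `namespace`, `is_a`, `relationship: part_of`, `is_obsolete`);
  cross-products, intersections and OWL-only constructs are ignored.
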
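---
title: "Methods and design of spongenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of spongenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongenet)
```

## The problem

A miRNA sponge (competing endogenous RNA, ceRNA) is a transcript that
sequesters shared miRNAs through multiple miRNA response elements (MREs),
thereby relieving the repression of other targets of those miRNAs. Two
signatures identify candidate sponge pairs in genomic data: a
significantly large set of *shared* miRNAs at the sequence level, and
*positive co-expression* that is attributable to that shared regulation.
`spongenet` implements the standard family of inference methods built on
these signatures, clusters the resulting interaction network into sponge
modules, and evaluates modules by gene-set over-representation and
patient survival.

## Inference methods

All methods start from the candidate screen (`candidate_pairs()`): every
unordered pair of targets sharing at least `min_shared` miRNAs is scored
with the hypergeometric upper tail on the shared count,

$$p \;=\; 1 - \sum_{x=0}^{n-1}
  \frac{\binom{K}{x}\binom{N-K}{M-x}}{\binom{N}{M}},$$

where $N$ is the miRNA universe, $K$ and $M$ the two degree counts and $n$
the shared count. P-values are Benjamini–Hochberg adjusted across all
tested pairs (per method, never across methods) and thresholded at 0.05 by
default. This alone is the **miRHomology** method.

* **pc** keeps candidates whose expression Pearson correlation is positive
  with BH-adjusted two-sided $p < 0.05$ (t transform, $n-2$ df).
* **sppc** computes the sensitivity correlation
  $SC = \rho_{ij} - \rho_{ij\mid \text{shared miRNAs}}$ and keeps pairs
  with $SC \ge 0.1$. A large drop means the co-expression runs through the
  shared miRNAs — the sponge signature. Both $\rho$ and the partial
  correlation are reported so users can filter further; no additional
  positivity test is applied.
* **hermes** and **ppc** test, per shared miRNA, the change in dependence
  between miRNA and RNA when the partner RNA is conditioned on:
  $\Delta I = I(\text{miR};\text{RNA}_i\mid\text{RNA}_j) -
  I(\text{miR};\text{RNA}_i)$ for hermes (mutual information) and the
  analogous change in absolute (partial) Pearson correlation for ppc.
  Each statistic is referred to a permutation null (the partner's
  expression permuted `m = 100` times); per-miRNA p-values are combined
  with Fisher's method ($X^2 = -2\sum\ln p_k$, $2n$ df); both conditioning
  directions are computed and the pair p-value is the larger of the two, a
  conservative AND-rule that makes the result symmetric in the pair.
* **muTaME** scores candidates from the MRE structure of their shared
  miRNAs: the fraction of shared miRNAs (s1), the MRE density per shared
  miRNA (s2), the positional spread of MREs in sites per kb (s3), and
  the MREs contributed per distinct miRNA (s4). The verbal definitions in
  the literature do not pin down formulas, so the concrete instantiations
  documented in `?mre_scores` are this package's own and each is
  unit-tested independently, which makes them swappable behind the same
  interface.
* **cernia** adds the mean absolute hybridization energy (s5), the
  DT-Hybrid bipartite recommendation score (s6) and the pair's expression
  correlation shifted to $r + 1$ (s7, floored at $10^{-6}$ so
  anticorrelated pairs remain in the log domain). Combined scores are the
  sum of the log component scores, min–max normalized over the candidate
  list; pairs at or above 0.5 are retained (a `top_fraction` rank mode is
  also provided because both retention rules circulate in the field; the
  normalized-score rule is the default).
* **integrate_methods** keeps the pairs supported by at least `k = 3`
  component methods (majority voting).

### Sidedness of the permutation test

For a genuine sponge pair the partner's expression carries information
about the shared miRNAs, so conditioning on it *absorbs* part of the
miRNA–RNA dependence: the planted signature under a linear-Gaussian
regulatory model is $\Delta$ *below* the permuted null (in the extreme,
conditioning on a copy of RNA$_i$ removes all information,
$\Delta I \approx -I$). The per-miRNA permutation test is therefore
lower-tailed, with the $+1$ pseudo-count
$p = (1 + \#\{\Delta_{\text{null}} \le \Delta_{\text{obs}}\})/(m+1)$ so
that Fisher combination never sees $p = 0$. `permutation_pvalue()` itself
exposes both tails.

### Estimators

The default (conditional) mutual information estimator is
Gaussian-parametric, $I = -\tfrac12\ln(1 - r^2)$ nats with $r$ the
(partial) Pearson correlation: it has a closed form that can be verified
exactly, is fast enough for permutation testing, and is the right model
for the linear coupling the generator produces. An equal-frequency
binning plug-in estimator (default $\lceil\sqrt{n}\rceil$ bins) is
available behind the same interface (`estimator = "binning"`) for
nonlinear couplings; note the plug-in estimator carries the usual
$(r-1)(c-1)/2n$ positive bias, which largely cancels in $\Delta$.

## Module identification

Four clustering algorithms are provided on the inferred network, with a
common module-size filter (default minimum 3):

* **FN** — greedy agglomerative modularity optimization (igraph's fast
  greedy implementation; the merge dendrogram is cut at the modularity
  maximum explicitly).
* **MCL** — Markov clustering: expansion (matrix squaring) alternating
  with inflation (elementwise power, column renormalization, default
  exponent 2) on the column-stochastic adjacency with unit self-loops;
  entries below $10^{-12}$ are pruned; clusters are the connected
  components of the limit matrix's attractor support, resolved to a
  partition (largest-then-lexicographic) because downstream survival
  analysis expects one module per gene per set.
* **LINKCOMM** — link communities: edges sharing a node are scored by the
  Jaccard similarity of the inclusive neighborhoods of their non-shared
  endpoints, single-linkage clustered, and cut where the partition
  density $D = \frac{2}{|E|}\sum_c \frac{m_c(m_c-n_c+1)}{(n_c-2)(n_c-1)}$
  is maximal (ties resolved toward the finer cut). Node modules induced by
  edge clusters may overlap.
* **MCODE** — vertex weights are core number × density of the highest
  k-core of each closed neighborhood; complexes grow outward from
  unassigned seeds over neighbors with weight $\ge (1 - vwp)$ × seed
  weight (default `vwp = 0.2`); the haircut (default on) trims each
  complex to its 2-core. The `fluff` flag is reserved and errors if set.

All four are deterministic; FN and MCL return partitions. Edge weights
are ignored (sponge networks from this package are unweighted).

## Validation, enrichment, survival

`validate_network()` intersects predictions with a curated pair list
under the canonical unordered representation. `method_overlap()` reports
UpSet-style exclusive intersection counts (which partition the union of
predictions) plus the pairwise Venn matrix. `enrich_modules()` runs
one-sided hypergeometric over-representation of user-supplied GMT sets
within each module — the same kernel as the candidate screen, against a
universe that defaults to the expression matrix's genes — with BH
adjustment across sets within each module.

`module_survival()` fits a multivariate Cox model on the standardized
module-member expression, computes per-sample risk scores, splits at the
median score (the quantile is exposed), tests the groups with the
log-rank test and reports the hazard ratio of high vs low risk with its
95% CI from a univariate Cox fit on the group indicator, so HR > 1 always
means the high-risk group fares worse. A module is flagged significant
when log-rank $p < 0.05$ and HR > 1.5.

Two design choices deserve emphasis:

* **Cross-validated risk scores (default).** Scoring and testing the same
  samples with a multi-gene Cox model is anti-conservative: with a 6-gene
  module on 150 samples the naive procedure flagged roughly 40% of
  null datasets in our simulations. By default each sample's risk score
  therefore comes from a model fitted without it (5 deterministic
  round-robin folds, held-out linear predictors median-centered per
  fold), which restores the log-rank test's null calibration (~2%
  false-flag rate) at a modest cost in estimated effect size.
  `risk_method = "full"` gives the naive variant.
* **Ridge fallback.** Modules with at least as many genes as fitting
  samples get a small fixed ridge penalty ($\lambda = 0.1$), with a
  message each time it is applied.

## The synthetic generator

`generate_sponge_data()` emulates a matched miRNA/mRNA study with known
ground truth. On the log2 expression scale, miRNA expression is Gaussian
$(\mu = 5, \sigma = 1)$; each planted group (10 disjoint pairs and one
6-RNA module by default) owns a dedicated set of 4 miRNAs, and each
member RNA is $8 - 0.8\,\bar z + \varepsilon$ with $\bar z$ the scaled
sum of its group's miRNA expression and $\varepsilon$ Gaussian with sd
0.3 — shared repression induces within-group correlation around 0.88
that vanishes when the miRNAs are partialled out, exactly the signature
the methods test. Decoy RNAs are independent noise with a couple of
sequence-level miRNA-target edges, so decoys can reach the candidate
screen but not the expression-based methods. MRE sites are 22 nt,
uniform in a 3 kb transcript, energies uniform in $[-30, -5]$ kcal/mol,
with 2–5 sites per planted interaction versus 1 per decoy interaction so
that MRE-density scores rank planted pairs higher. Positions and
energies exercise the scoring formulas; they are not biophysically
calibrated.

Survival times are exponential with hazard
$\lambda_0 e^{\beta z}$, $z$ the standardized mean expression of the
planted module and $\lambda_0 = 0.1$ per time unit. The coefficient is
$\beta = \log(\text{HR})/1.5958$, since $2\sqrt{2/\pi} \approx 1.5958$
is the expected high-minus-low gap of a median-split standard normal
score; the planted HR (default 2.5) is thus the asymptotic
high-vs-low-group contrast. Censoring is exponential with rate
$\lambda_0 c/(1-c)$, giving an expected censoring fraction near
$c = 0.3$.

What the generator does *not* emulate: count noise and
mean–variance coupling of sequencing data, miRNA-target edges that are
wrong or condition-specific, confounded co-expression (batch, copy
number), overlapping sponge groups, and nonlinear regulation (a
quadratic switch would exercise the binning estimator but is not the
default). Passing the planted-recovery tests therefore demonstrates
correctness of the algorithms under their own model assumptions, not
performance on real tumor data.

## Numerical choices and problem sizes

Identifiers are opaque case-sensitive strings; unordered pairs are
stored with lexicographically sorted endpoints everywhere. Readers
reject rather than coerce (missing expression values are a hard error;
imputation is upstream preprocessing). MRE coordinates are 1-based
inclusive; sites with positive hybridization energy are dropped on
load with a logged count. Zero-variance vectors are hard errors in every
correlation path, not NaN propagators. Whether expression enters on the
raw or log scale is a reader flag (`log_transform`), defaulting to the
log2(x+1) transform for raw FPKM-like input; the generator already
produces log-scale values.

The test suite runs the full pipeline at 60–200 samples with 24–60 RNAs,
100 permutations for the competition methods and 50 replicates for the
survival null — sizes chosen so the whole suite completes in a couple of
minutes while leaving the statistical checks enough resolution.
Deterministic seeds flow from a single configuration value through every
stage; reruns are checksum-identical.

## Known limitations

* The muTaME/cernia score formulas are explicit instantiations of verbal
  descriptions; other instantiations are defensible and would change the
  rankings.
* DT-Hybrid's domain similarity is the target–target Jaccard over miRNA
  neighborhoods; no external sequence similarity source is consulted.
* MCL's partition resolution and the linkcomm tie-break are documented
  conventions, not part of the original algorithms.
* hermes here is the Gaussian/binning-estimator variant; the adaptive
  partitioning estimator of the original implementation is out of scope.
* Enrichment requires user-supplied GMT collections; no ontology or
  pathway web service is queried.
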
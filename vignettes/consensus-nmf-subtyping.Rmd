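---
title: "Consensus NMF molecular subtyping: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus NMF molecular subtyping: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmfsubtypes)
```

## The problem

Bulk expression cohorts of a heterogeneous disease — the motivating case is
post-mortem brain RNA-seq from Alzheimer's patients — often mix molecularly
distinct patient subgroups. `nmfsubtypes` discovers such subgroups by
consensus non-negative matrix factorization, defines per-subtype signature
genes, transfers the subtypes to independent cohorts, and tests their
association with clinical covariates. Every stage runs on plain matrices and
tables, and the package ships a generative simulator so the whole chain is
testable without access to any cohort.

## Model and procedure

**Factorization.** Given a nonnegative expression matrix $A$ ($n$ genes
$\times$ $m$ samples) and a rank $k$, we minimize the generalized
Kullback–Leibler divergence

$$D(A \| WH) = \sum_{ij}\Big(A_{ij}\log\frac{A_{ij}}{(WH)_{ij}} -
A_{ij} + (WH)_{ij}\Big)$$

over nonnegative $W$ ($n \times k$) and $H$ ($k \times m$) with the
classical multiplicative updates, applied sequentially (the $H$ update, then
the $W$ update using the fresh $H$):

$$H_{au} \leftarrow H_{au}\frac{\sum_i W_{ia}\, A_{iu}/(WH)_{iu}}
{\sum_i W_{ia}},\qquad
W_{ia} \leftarrow W_{ia}\frac{\sum_u H_{au}\, A_{iu}/(WH)_{iu}}
{\sum_u H_{au}}.$$

These updates never increase $D$, and the package asserts that monotonicity
on every fitted trajectory. A sample's cluster is the argmax row of its
column of $H$ (ties to the smallest index; labels are 1-based).

**Consensus and model selection.** Because the optimum depends on the random
start, the factorization is repeated (default 40 runs per candidate $k$)
and the co-clustering frequency of every sample pair is collected in a
consensus matrix $C$. The candidate $k$ is scored by the cophenetic
correlation $\rho_k$: the Pearson correlation between the consensus
distances $1 - C$ (off-diagonal pairs) and the cophenetic distances of
their average-linkage dendrogram. The selected $k$ is the smallest one
attaining the maximal $\rho_k$. Final sample labels come from cutting that
dendrogram into $k$ groups — a deterministic function of $C$ — rather than
from any single run; per-run argmax labels are kept for diagnostics.

**Core samples and signatures.** Each sample gets a silhouette width
$s(i) = (b(i) - a(i))/\max(a(i), b(i))$ with Euclidean distances in the
same selected-gene expression space used for factorization; samples with
$s(i) \le 0$ are excluded as outliers (the zero boundary is conservatively
treated as non-core). Pairwise differential expression between core samples
of each subtype uses a Welch t-test per gene on $\log_2(\mathrm{CPM}+1)$
with Benjamini–Hochberg correction; signature genes must pass a linear
fold-change of 1.5 and FDR 0.05, and each is assigned to the subtype with
the highest mean CPM over core samples, making the per-subtype lists
disjoint. For $k > 2$, a gene qualifies if it passes any pairwise
comparison.

**Transfer.** To validate subtypes in an independent cohort, the signature
genes are projected onto the new (normalized) matrix, the consensus
machinery is re-run on the projected matrix, and each resulting cluster is
named after the subtype whose signature genes are most elevated in it: the
score of (cluster, subtype) is the mean over the cluster's samples of the
mean per-gene z-scored expression of the subtype's signature genes, and
clusters are matched to subtypes greedily on that score matrix (ties by
subtype order). The score matrix is reported so the call is auditable. The
source study does not spell out how identity was assigned; this rule is
this package's own explicit operationalization.

**Associations.** Categorical covariates are tested against the subtype
label with the Freeman–Halton exact test (probability-ordering two-sided
rule with the customary $1+10^{-7}$ float tolerance), enumerated exactly by
depth-first iteration over margin-compatible tables when the table space is
small (bound $10^7$), and otherwise estimated from $10^6$ margin-preserving
Monte-Carlo draws with a reported standard error. Continuous covariates use
a pooled-variance (Student) t-test; this is deliberately distinct from the
Welch test used for differential expression, matching the respective
conventions. Missing metadata values are excluded pairwise per test.
Gene-set over-representation is the upper hypergeometric tail on
user-supplied GMT sets, with BH adjustment across sets.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cpm_threshold` | 5 CPM | expression floor defining a "non-expressed" observation |
| `nonexpressed_fraction` | 0.8 | gene dropped when below the floor in at least this fraction of samples (count rule: $\ge \lceil f m \rceil$ samples) |
| `iqr_top_fraction` | 0.2 | fraction of genes kept by IQR of $\log_2(\mathrm{CPM}+1)$; kept count is $\lfloor f n \rfloor$ |
| `k_candidates` | 2–4 | candidate subtype counts |
| `n_nmf_runs` | 40 | runs per candidate $k$ for the consensus matrix |
| `max_iter`, `tol` | 2000, $10^{-6}$ | stop when the relative drop of $D$ over 10 consecutive iterations falls below `tol` |
| `fc_cutoff`, `fdr_cutoff` | 1.5, 0.05 | signature gates (fold change on the linear CPM scale) |
| `base_seed` | 1 | run $r$ at rank $k$ uses seed `base_seed + k*1e6 + r` |

The floor convention for the IQR cutoff is fixed by the three printed gene
counts it must reproduce from a 12,281-gene pool: 1228, 2456 and 4912 genes
at fractions 0.10, 0.20 and 0.40.

## Numerical choices

* **Initialization.** $W$ and $H$ entries are i.i.d. uniform$(0,1)$ scaled
  by $\mathrm{mean}(A)/k$, from a per-run seeded generator; the first $H$
  update immediately rescales the factors, so only the direction of the
  start matters.
* **Zero protection.** $(WH)_{ij}$ and the update denominators are clamped
  at $10^{-12} \times \mathrm{mean}(A)$; terms with $A_{ij} = 0$ contribute
  $(WH)_{ij}$ to $D$.
* **Matrix scale.** NMF consumes CPM values of the selected genes by
  default (nonnegativity is required by the model); $\log_2(\mathrm{CPM}+1)$
  is available via `log_transform` and the choice is logged. Heatmaps
  display per-gene standardized values only — never the factorized scale.
* **Quantiles.** IQRs use the linear-interpolation quantile convention
  (type 7); selection ties break by original gene order.
* **Degenerate inputs.** All-zero $H$ columns make membership undefined and
  raise an error; a constant consensus distance makes $\rho_k$ undefined
  (`NA`, excluded from selection with a warning); zero-variance genes in
  both DE groups give $p = 1$ (equal means) or a flagged $p = 0$; min-shift
  (not clipping) restores nonnegativity of log-ratio microarray inputs,
  preserving within-gene rank order.

## The simulator

`simulation_spec()` describes a negative-binomial cohort: per-gene baseline
means uniform on a log2 grid (default $2^1$–$2^8$ counts), lognormal
library-size factors (default sd 0.2 on the log scale), NB dispersion 0.2,
and disjoint per-subtype signature blocks whose means are multiplied by
$2^{\mathrm{log2fc}}$ in samples of that subtype — up-regulation only,
matching the definition of a signature as the genes highest in their own
subtype. The default cohort (2,000 genes $\times$ 200 samples, two equal
subtypes, 100 signature genes each at log2 fold-change 2) is a scaled-down
caricature of a ~12,000-gene, ~200-sample bulk brain cohort, chosen so the
full pipeline runs in minutes on one CPU; the vignette-scale examples and
tests state their sizes explicitly. Covariates are drawn independently
given the true subtype.

What the simulator deliberately omits: gene–gene correlation networks,
batch effects, platform differences, and down-regulation-defined subtypes.
Passing recovery tests on this generative caricature demonstrates that the
machinery is implemented correctly — not that real cohorts of this size
always contain recoverable subtypes, nor that the silhouette/consensus
heuristics are immune to the pseudo-structure a single noisy realization
can present (at small sample sizes even structureless data can yield a
crisp consensus; the dispersal diagnostic is most informative at realistic
$m$).

## Design decisions that were genuinely open

* **DE engine.** The differential-expression step is a documented Welch
  t-test on $\log_2(\mathrm{CPM}+1)$ behind a narrow `de_table` interface,
  so a negative-binomial engine can be substituted; the test suite
  cross-checks effect directions against edgeR's exact NB test on planted
  data. Consequently no specific published DEG count is a target of this
  package.
* **Consensus labels.** Taken from the hierarchical cut of $1 - C$ rather
  than any single NMF run, making the reported clustering deterministic
  given the consensus matrix.
* **Linkage.** Average linkage for both the cophenetic computation and the
  consensus cut — the standard choice in consensus-NMF practice.
* **Silhouette space.** Euclidean distance over the selected-gene
  expression matrix (the same matrix that was factorized), per the explicit
  Euclidean definition of $d(i,j)$; consensus-distance space would be a
  defensible alternative.
* **Fold change.** Read on the linear scale ("fold change of 1.5"
  $\Rightarrow |\log_2 FC| \ge \log_2 1.5$).
* **Exact-test convention.** Probability-ordering (minlike) two-sided rule;
  for $2\times 2$ tables this reproduces the standard Fisher test to
  $10^{-10}$.

## Known limitations

* KL-NMF multiplicative updates converge to a local optimum; stability is
  addressed by the consensus layer, not by global optimization.
* The cophenetic criterion compares candidate $k$ values but is not a test
  against the no-structure null; use the null-consensus dispersal
  diagnostic alongside it.
* Associations are unadjusted single-covariate tests; no confounder
  control is attempted.
* Transfer assumes a shared gene-identifier namespace and comparable
  normalization; no cross-platform batch correction is performed.
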
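---
title: "GWGENet methods: network identification, principal network projection and signature-reversal drug design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GWGENet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GWGENet)
```

## The problem

A genome-wide genetic and epigenetic network (GWGEN) is the union of an
undirected protein–protein interaction network (PPIN) over protein-like
nodes (proteins, receptors, transcription factors) and a directed gene
regulatory network (GRN) in which TFs, lncRNAs and miRNAs regulate genes,
lncRNAs and miRNAs.  Database mining yields a *candidate* GWGEN — a Boolean
hypothesis network full of false positives accumulated across heterogeneous
experimental conditions.  GWGENet identifies, for each node, which candidate
regulators are actually supported by expression data in a given condition
(e.g. a breast-cancer subtype), extracts the *core* of the identified
network by a spectral ranking, compares two conditions into common and
distinctive core structure, and filters a drug catalog for compounds that
reverse the expression signature of selected biomarkers without undue
toxicity.

## The static network models

Expression levels are treated as static per-sample measurements.  For
protein $i$ in sample $n$, with interaction partners $j$:

$$p_i[n] \;=\; \sum_{j \ne i} \lambda_{ij}\, p_i[n]\, p_j[n] \;+\; \psi_i
\;+\; \theta_i[n],$$

where $\lambda_{ij}$ is the (signed, dimensionless) interaction ability,
$\psi_i$ the basal level — the constant term that absorbs epigenetic and
microenvironment effects not driven by the modelled regulators — and
$\theta_i[n]$ Gaussian noise.  For a gene $x$ with TFs $u$, lncRNAs $k$ and
miRNAs $v$:

$$g_x[n] \;=\; \sum_u \alpha_{xu}\, t_u[n] \;+\; \sum_k \beta_{xk}\, l_k[n]
\;-\; \sum_v \gamma_{xv}\, m_v[n]\, g_x[n] \;+\; \psi_x \;+\; \theta_x[n],$$

with $\gamma_{xv} \ge 0$: miRNAs act post-transcriptionally and can only
repress, which is why the bilinear miRNA term carries a sign-constrained
coefficient.  lncRNA targets and miRNA targets follow the same form with
their own symbol sets.  All expression values are on a microarray-style
log-intensity scale; miRNA levels are non-negative so the bilinear term is
a genuine repression.

## Identification by constrained least squares

Each node's equation is rewritten as a linear regression with constructed
regressors: the protein model regresses $p_i$ on the products
$p_i \cdot p_j$ plus a ones column for $\psi$; the gene model regresses
$g_x$ on the blocks (TF series, lncRNA series, $g_x \cdot m_v$ products,
ones), in that order.  PPI problems are ordinary least squares; GRN
problems are solved subject to non-positivity of the miRNA-slot
coefficients.  The constrained minimiser is computed by an active-set
method (Lawson–Hanson with free variables): the sign-free coordinates stay
permanently passive, constrained coordinates enter the passive set only
while their coefficient is negative.  The unit tests check the solver
against two independent oracles — normal equations for the unconstrained
case and exhaustive enumeration of active sets plus a KKT certificate for
the constrained case.

Rank-deficient designs fall back to the minimum-norm (pseudoinverse)
solution and are flagged.  Because the response appears inside the
bilinear regressors, the regression is taken at face value, exactly as the
model equations are written; no errors-in-variables correction is applied.

### Degree cap

With $N$ samples a regression with $k$ regulators and a basal term is only
identifiable when $k + 1 < N$.  `applyDegreeCap()` enforces this per
equation *before* identification: if a node has more candidates than
$N - 2$, candidates are ranked by the absolute Pearson correlation of the
constructed regressor with the response and only the top $N - 2$ are kept
(ties broken by node id).  The cap is per target equation, so a symmetric
PPI edge can remain a candidate in one endpoint's equation while being
dropped from the other's.  The correlation ranking is this package's
choice; any deterministic, data-driven ranking would serve.

### AIC order selection

For each node the full candidate model is fitted, regressors are ranked by
standardised influence $|\hat\omega_j| \cdot \mathrm{sd}(\text{regressor}_j)$
(ties by node id), and the nested family $k = 0, \dots, K$ is refitted.
The selected order minimises

$$\mathrm{AIC}(k) \;=\; \log_{10}\!\Big(\max\big(\mathrm{RSS}_k/N,\;
10^{-12}\big)\Big) \;+\; \frac{2\,(k+1)}{N},$$

ties going to the smaller $k$; regulators outside the selected order are
pruned from the network.  Three numerical choices deserve a note:

* **Log base.**  The criterion is used with the common logarithm by
  default (`base = 10`, configurable).  On the $\chi^2$ scale this makes
  the entry threshold for one extra parameter $2\ln 10 \approx 4.6$ rather
  than $2$, i.e. a deliberately conservative criterion.  This is the
  setting under which the package's stated guarantees hold: on pure-noise
  responses with three candidates and $N = 100$, order 0 is selected in
  well over 90% of replicates, and under 10% relative noise the planted
  networks of the synthetic study are recovered with mean F1 around 0.98.
  With the natural log the criterion admits roughly one spurious regressor
  per three candidates under the null (the classical AIC overselection),
  which is measurably too liberal for pruning a decoy-heavy candidate
  network.
* **Zero-residual floor.**  Perfect fits (noiseless data) would give
  $\log 0$; flooring $\mathrm{RSS}/N$ at $10^{-12}$ keeps all perfect fits
  finite and equal on the fit term, so the parsimony penalty alone decides
  among them — the minimal exactly-fitting model wins.
* **Search strategy.**  The nested ranked family costs $K + 1$ refits per
  node instead of $2^K$; on noiseless planted problems its minimum
  coincides with the exhaustive-subset minimum essentially always (the
  acceptance suite requires at least 95% agreement on random
  ≤ 5-candidate instances).

Per-kind selected orders (how many TFs, lncRNAs, miRNAs survived) are read
off the globally ranked selection rather than searched on a per-kind grid.

## Principal network projection (PNP)

The estimated abilities of the identified network are assembled into a
combined matrix $W$: rows are target nodes (proteins, genes, lncRNA
targets, miRNA targets), columns are regulator-capable nodes (proteins,
receptors, TFs, lncRNAs, miRNAs), and entry $(r, c)$ is the selected
ability of edge $c \to r$, zero otherwise.  The PPI block occupies the
protein-like columns of its own rows; writing the column space as the
union of all regulator-capable nodes keeps every estimated parameter in
one matrix with a consistent shape.

With the SVD $W = T D H^\top$ (singular values descending, each right
singular vector sign-fixed so its largest-magnitude entry is positive),
the eigenexpression fraction of component $s$ is
$E_s = d_s^2 / \sum_r d_r^2$.  The principal network structure is the
smallest rank $S$ whose cumulative energy reaches the threshold (default
0.85).  Node scores are 2-norm projections onto the top-$S$ subspace,
written so the dimensions match: a column (regulator role) is projected
onto the top-$S$ *left* singular vectors,
$Q_\downarrow(c) = \big(\sum_{r \le S} (u_r^\top w_{:,c})^2\big)^{1/2}$,
and a row (target role) onto the top-$S$ *right* singular vectors.  At
full rank this reduces to the column/row 2-norms (Parseval), which the
tests assert; a near-zero score marks a node nearly independent of the
principal structure.  A node active in both roles is ranked by the larger
of its two scores, and the top-$K$ nodes (default 2000) with their induced
edges form the core GWGEN.  Both the 0.85 threshold and the top-2000 cut
are exposed as parameters.

The SVD is computed densely via LAPACK; the desk-scale problems this
package targets (thousands of nodes) are comfortably within that range.

## Comparing two conditions

Two cores over the same node namespace are split into common and
distinctive node and edge sets.  Overlap percentages are reported per node
kind with each condition's own core as denominator:
$\mathrm{overlap}_A(\text{kind}) = 100\,|A_\text{kind} \cap B| /
|A_\text{kind}|$, and a kind absent from a core yields `NA` (undefined)
rather than 0.  Expression direction per node is `up` when the case mean
exceeds the control mean and `down` otherwise — ties deterministically
`down`; an optional minimum absolute difference makes the labelling
stricter.  No significance test is attached to the direction call; it is a
visualisation-style annotation, not an inference.

## Drug design

The drug table carries, per (drug, target) pair, a connectivity score in
$[-1, 1]$ — the similarity between the drug's perturbation profile and a
query signature, negative meaning reversal — and a predicted LD50 in
mg/kg.  Two filters apply:

1. **Regulation ability.**  An upregulated biomarker keeps drugs with
   score $\le -s$, a downregulated one drugs with score $\ge +s$
   (default $s = 0.5$; the direction rule is the method, the numeric
   threshold is a configurable package default).
2. **Toxicity.**  Keep drugs with predicted LD50 at least the bound
   (default 500 mg/kg, closed bound); higher LD50 means lower acute
   toxicity.

A minimal multi-molecule proposal is then assembled by greedy weighted set
cover: repeatedly take the drug covering the most uncovered biomarkers,
ties broken by larger summed |score|, then larger LD50, then name.  Greedy
set cover carries the usual $H_n$ approximation guarantee and the tests
compare it against brute-force optima on small instances; biomarkers no
surviving drug covers are reported, not errored.  The biomarker list
itself is an input (from the comparison stage or a user file) — reading
biomarkers off pathway diagrams is judgment work the software does not
automate.

## The synthetic study

Real studies of this design start from microarray series with hundreds of
samples and a database-mined candidate network; neither is reproducible
offline, so the package ships a generator whose output provably satisfies
the model equations, making recovery of planted structure a meaningful
test of the whole chain.

* **Roles.**  The models are mutually coupled ($p_i$ appears on both sides
  of the protein equation), so the generator uses a two-layer scheme:
  *source* nodes (TFs, receptors, half of the miRNAs and lncRNAs) are
  drawn i.i.d. log-normal (location 0, log-sd 0.5) and act only as
  regressors; *target* nodes (proteins, genes, the remaining miRNAs and
  lncRNAs) are computed from the rearranged closed forms, e.g.
  $g = (\sum \alpha t + \sum \beta l + \psi + \theta)/(1 + \sum \gamma m)$.
  Every target equation therefore holds exactly with the drawn noise term,
  which is what identification needs; the price is that source nodes obey
  no equation, mirroring ligands and constitutive regulators whose own
  regulation is outside the modelled system.  The protein count is split
  40% TF / 20% receptor / 40% protein so that PPI target equations draw
  partners from regulator-only kinds.
* **Edges.**  Every kind-legal regulator→target pair becomes a true edge
  with probability `trueDensity` (default 0.05, giving a sparse network
  with a mean in-degree of one to two like the identified networks this
  emulates); decoys are sampled from the remaining legal pairs at
  `decoyRatio` per true edge (default 2, a candidate network two-thirds
  false).
* **Abilities.**  Regulatory abilities are drawn $\pm U(0.2, 1)$ (bounded
  away from zero so order selection is well-posed); miRNA-slot
  coefficients are $-U(0.2, 1)$.  PPI abilities are additionally rescaled
  per protein so that $|\sum_j \lambda_{ij} p_j| \le 0.85$ for every
  admissible source draw: source draws are truncated at 4.5 (the upper
  ~0.1% tail of the log-normal), and $\lambda_i$ is scaled by
  $\min(1,\, 0.85/(4.5 \sum_j |\lambda_{ij}|))$.  This keeps the
  rearranged protein denominator $1 - \sum \lambda p$ off zero
  deterministically — a per-draw rejection rule cannot work here, because
  with unscaled abilities some sample crosses the singularity with
  probability near one at realistic sample counts.
* **Basal levels and noise.**  Basal levels are positive
  ($U(1,3)$ for proteins; $U(0.5, 1.5)$ plus a bound on the regulator term
  for Eq.-2-type targets, which keeps miRNA targets non-negative).  Noise
  is Gaussian, added to the basal level inside the rearranged numerator,
  so the generating equation still holds exactly with the drawn noise; the
  level can be absolute or calibrated per target relative to the noiseless
  signal sd (`signalSd()`).  The rare noise draw that would push a miRNA
  target negative is resampled.
* **Condition pairs** share one candidate network; a chosen fraction of
  condition A's true edges is planted in B as well, the rest redrawn, so
  the comparison stage can be validated against an exactly known
  common/distinctive split.

What the generator does **not** emulate: probe-level noise structure,
batch effects, correlated regulators, unmodelled confounders, or the
distributional quirks of real microarray series.  Passing the recovery
tests shows the estimator chain is correct and well-conditioned under its
own model assumptions — not that real candidate networks are pruned with
this accuracy.

## Problem sizes used by the tests

The reference synthetic study uses 50 proteins, 100 genes, 20 miRNAs and 5
lncRNAs (175 nodes, ~250 planted edges, ~740 candidate edges after
decoys), 80 samples for noiseless checks and 100 for noisy ones; the full
two-condition pipeline on this study runs in a few seconds on one CPU.
These sizes were chosen as the smallest study on which every stage
(capping, per-kind regression blocks, spectral ranking, comparison, cover
assembly) is exercised with non-trivial multiplicity.

## Known limitations

* The identified abilities inherit the bilinear regression's
  endogeneity: with noisy data, regressors containing the response are
  correlated with the residual, slightly biasing estimates; the noiseless
  limit is exact, and the effect at 10% relative noise is within the
  tolerances the tests assert.
* AIC order selection is greedy over a ranked nested family; adversarial
  collinear candidates could make it miss the exhaustive optimum.
* The degree-cap ranking (marginal |correlation|) can in principle drop a
  true regulator that is only conditionally informative.
* Scores, LD50 values and the drug catalog are consumed as given; the
  package performs no dose modelling, interaction checking, or catalog
  curation.
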
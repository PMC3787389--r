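---
title: "Receptor-optimized descriptor screening: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-optimized descriptor screening: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orscreen)
```

## The problem

An odorant receptor's response profile is measured as spike-rate changes
(spikes/s above spontaneous activity) of the olfactory neuron expressing
it, across a panel of on the order of a hundred odorants. The chemical
space of plausible volatiles is orders of magnitude larger. `orscreen`
works from the *similarity property principle* — structurally similar
molecules tend to share activity — but instead of a fixed notion of
structural similarity it learns, per receptor, which molecular descriptors
matter, and then uses those descriptors to rank untested compounds by
proximity to the receptor's known activators.

The pipeline assumes:

* a **complete** activity panel (odors × receptors, spikes/s; negative
  values allowed for below-baseline responses; missing cells are an
  error, not imputed);
* a numeric compound-by-descriptor table for the training odors and for
  any screening library, computed elsewhere (descriptor software is
  deliberately out of scope; tables are exchanged as CSV);
* that activation is driven by proximity in some low-dimensional
  projection of descriptor space. Inhibition is not modeled: descriptor
  profiles of inverse agonists overlap those of agonists too strongly for
  this distance-based approach to separate them.

## Classifying a receptor's actives

Odors are clustered by the one-dimensional activity distance
|aᵢ − aⱼ| with complete linkage. Among *all* nodes of the dendrogram
(leaves included), the selected branch is the one containing the most
strong activators — responses strictly above `strong_cutoff`, default
50 spikes/s, the conventional activator threshold for this type of
recording. Ties go to the node with fewer leaves, then to the deeper
(lower) node, then to lexicographic member order; odors are canonicalized
to id order before clustering so input order is irrelevant. The
receptor's activity threshold is the minimum response inside the selected
branch, and every odor at or above it is active (the threshold is itself
an observed activity, hence ≥). A receptor with no response above the
cutoff raises a typed `no_actives_error` so batch drivers can skip it, as
one does for receptors known only from a single weak agonist.

This branch heuristic presumes a response *gap* between the activating
group and the rest. Real panels usually have one (most odors are silent);
smooth synthetic tuning curves need not — see *Limits of the generator*.

## The selection objective

For a candidate multiset $M$ (descriptor ids with repetition), the
weighted descriptor distance is
$$\mathrm{CbCD}(i,j) = \Big(\sum_{k} m(k)\,(X_{ik}-X_{jk})^2\Big)^{1/2},$$
with $m(k)$ the multiplicity of $k$ in $M$ and $X$ the z-scored
descriptor table. Re-selection therefore acts exactly like physically
duplicating a column — that column-duplication equivalence is the
defining semantics of the weights and is asserted to 1e-12 in the tests.

The objective extracts, for every active compound $i$, the row of
distances to all other compounds $j \ne i$ (self-distances are excluded —
they are identically zero and would only dilute the signal), concatenates
the rows in fixed (sorted active id) × (sorted compound id) order, and
computes a single Pearson correlation against the identically indexed
activity distances. Design choices worth stating:

* **Pearson**, because both vectors are continuous distances and the
  greedy criterion is a linear-association score; the alternative (rank
  correlation) is a one-line swap inside `objective_correlation()`.
* **One pooled correlation** over the concatenated rows rather than a
  mean of per-row correlations: the simplest reading of comparing "the
  rows corresponding to activating compounds", and it weights every
  compound pair equally.
* A zero-variance vector (e.g. all activities identical) makes the
  correlation undefined; the objective returns the sentinel `-Inf`, which
  the optimizer treats as "worse than anything".

## Sequential forward selection

Iteration 1 scores every single descriptor (baseline −∞, so one is always
chosen); iteration $t$ scores $M \cup \{k\}$ for *every* descriptor $k$,
including those already selected. The best candidate is kept only if it
**strictly** improves the objective; equality halts (this is what stops
immediately after a perfect score, since re-selecting a descriptor only
rescales distances and leaves the correlation unchanged). Ties among
candidates go to the smallest descriptor id in sorted order, making the
result invariant to column order. There is no default cap on multiset
size (`max_iter = Inf`); published selections average around thirty per
receptor, and the cross-validation and command-line drivers expose
`max_iter` for bounding the per-fold work.

The objective sequence is strictly increasing and bounded by 1, so the
algorithm terminates.

## APoA enrichment

For each active query $c$, the other $N-1$ compounds are ranked by
distance from $c$ (ascending; ties broken by compound id so curves are
deterministic), and $\mathrm{APoA}_c(m)$ is the fraction of actives among
the $m$ nearest. Curves are averaged over the active queries. The query
is excluded from its own ranking — its self-distance of zero would
trivially occupy rank 1 — so the final-rank value is exactly
$(|A|-1)/(N-1)$, an identity asserted per curve. APoA depends only on
distance ranks, hence is invariant under monotone transforms of the
distances.

The AUC integrates the curve by the trapezoid rule over the normalized
rank axis $x = m/(N-1) \in (0,1]$, treating the leading interval
$(0, 1/(N-1)]$ as constant at the rank-1 value. That convention makes a
constant curve at value $c$ integrate to exactly $c$, so AUCs of methods
with different $N$ remain comparable; only relative comparisons between
methods on the same instance are interpreted.

## Cross-validated ROC

`crossvalidate()` runs `trials` independent `folds`-fold
cross-validations. Per trial, compounds are randomly partitioned into
folds whose sizes differ by at most one (109 compounds → 22/22/22/22/21);
every compound is tested exactly once per trial. Per fold, *everything*
is refit on the training split alone — normalization statistics, active
classification, descriptor selection — and each withheld compound is
scored by its weighted distance to the nearest training active; no test
information leaks into training. Eligibility requires at least one odor
above 150 spikes/s and at least five above 100 spikes/s (the very strong
one counts among the five), so that every fold can retain a training
active; a fold that still ends up without training actives is skipped
with a warning.

Scores are pooled across folds *and* receptors within a trial (every
score/label pair weighted equally). ROC curves use score = −distance
against positive labels from the full-data active classification — a
fixed ground truth chosen deliberately so test labels do not depend on
the training procedure. The step construction moves tied scores together;
AUC is trapezoidal; the mean ROC averages the trial curves vertically on
a fixed 101-point false-positive-rate grid. Identical seeds reproduce the
result bit for bit (the only randomness is the fold assignment, drawn in
a fixed order from one seed).

## Screening and breadth of tuning

Screening ranks each library compound by its **nearest-active** distance
(minimum over the receptor's actives) in the training coordinate frame:
the library is projected through the *training* mean/SD, not pooled
statistics, so library distances are commensurate with training
distances. Ties break by compound id; the default report depth is the top
500 per receptor.

The breadth-of-tuning profile instead measures distance from the single
**strongest** activating compound — a deliberately different reference
reflecting its different question (how densely does chemical space
populate the receptor's best-ligand neighborhood?). Two trimming stages
precede binning: extreme outliers above mean + 6·SD (a handful of
compounds in a large library; multiplier configurable), then outliers
above mean + 3·SD of the remaining distances. The 3·SD rule is read as a
z-score cut (mean + 3·SD); a literal "distance > 3·SD" cut would, on a
uniform 1..100 grid, discard 13% of perfectly regular compounds, which
contradicts the rule's outlier-removal purpose. Retained distances are
expressed as percent of the maximum retained distance and the compounds
within the top 15% are binned at 1% resolution (bin width is otherwise
unspecified; 1% is the finest resolution that keeps a >10⁵-compound
histogram readable).

## Receptor maps and the interaction network

Three receptor-by-feature matrices feed complete-linkage Euclidean
clustering: binary presence/absence of each receptor's first 20 selection
*events* (duplicates collapse to presence; receptors with fewer
selections contribute what they have, with a warning); raw response
vectors; and the matrix of pairwise top-500 overlap percentages (each
receptor's feature vector is its overlap with every receptor, self = 100%).
Trees export as Newick. The interaction network joins known interactions
(responses strictly above 50 spikes/s) and predicted ones (top-N lists);
a pair that is both is a single edge with evidence `known` — the network
distinguishes evidence, it does not duplicate edges. Receptor and
compound id namespaces must be disjoint. Exports are SIF and GraphML with
an `evidence` edge attribute; edge color semantics are left to the viewer.

## The synthetic study generator

`generate_panel()` draws descriptor values i.i.d. standard normal and
computes each receptor's response as a Gaussian kernel of the compound's
Euclidean distance $d$ from a receptor prototype within a planted
3-descriptor subspace:
$$a = A_\mathrm{max}\, e^{-d^2/(2\tau^2)} + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma),\ \text{clipped at } 0 .$$
The kernel (rather than a linear map) makes structurally different
compounds with similar activity, and similar compounds with different
activity, arise naturally at moderate $\tau$ — the phenomenology that
motivates receptor-specific descriptor selection in the first place.
Inhibition is not simulated. All randomness flows from one integer seed
through R's default generator in a documented draw order, so identical
configs are bit-identical; the library uses seed + 1.

Default study conditions: 109 training odors, 200 descriptors (a
desk-scale stand-in for the several-thousand-descriptor commercial sets),
a 1000-compound background library with 2% planted near-prototype
compounds per receptor (jitter SD 0.1), and four receptors with disjoint
planted subspaces. Prototypes are anchored at the planted coordinates of
a training compound — the receptor's "best known ligand". Two receptors
are broadly tuned ($A_\mathrm{max}$ 250/200 spikes/s, $\tau$ 1.0/0.8,
giving roughly 20–30 activators, typical of strongly responding antennal
receptors); two are narrowly tuned ($A_\mathrm{max} = 51$ spikes/s,
$\tau = 2.2$), responding marginally to a compact clique of compounds
around the prototype.

### Limits of the generator — and why two receptors are narrow

The compact-clique regime is where planted-subspace **recovery** is
identifiable. The selection objective compares pairwise compound
distances with pairwise activity differences; even with noise-free
kernel responses these are not isometric — for two compounds both away
from the prototype, $|a_i - a_j|$ says little about their mutual
distance. With i.i.d. training compounds and a broad active set, the
per-descriptor signal is weak enough that greedy selection can chain
noise descriptors (their apparent correlations are inflated by the strong
dependence among concatenated row entries). When the active set is a
tight clique at the prototype, every active row is approximately the
monotone kernel of prototype distance, the planted descriptors dominate
every candidate pool, and selection halts after picking (a subset of)
them. The attainable objective is then limited only by the kernel's
curvature and the clique's spread — about 0.95–0.996 depending on the
draw, approaching 1 only when the clique degenerates to a single
prototype compound. A narrow ceiling of 51 spikes/s with $\tau = 2.2$
(the scale of typical planted-subspace inter-compound distances, which
maximizes the kernel's linearity over the sampled range) produces exactly
this regime under the activator cutoff of 50 spikes/s.

Conversely, the generator's smooth kernel gives broad receptors a
*continuum* of intermediate responses with no gap below the activator
cutoff, and the dendrogram branch selection then tends to select the root
— every odor becomes "active" at a near-zero threshold. Real panels are
sparser and gappier (most odors are genuinely silent), which is why the
heuristic works there. Passing tests on the synthetic panels therefore
demonstrate the machinery — recovery, ranking, enrichment, validation —
not that the branch heuristic is robust on arbitrarily smooth tuning
curves; that robustness is a property of real data the generator
deliberately does not guarantee.

For validating the cross-validation machinery the package ships a
separable benchmark (`synthetic_separable_panel()`): actives sit exactly
at the prototype along one signal descriptor and every inactive keeps a
margin of at least 2 z-score units in that coordinate, so a correct
pipeline must achieve per-trial AUC 1.0. The matching null instance draws
responses independently of the descriptors for six receptors; pooling six
receptors per trial (as the real analysis pools twelve) is what
concentrates the null AUC near 0.5 — a single receptor's permutation
null has conditional spread of roughly ±0.07 that five trials on the same
permutation cannot average away.

The compounds in all synthetic libraries are statistical stand-ins, not
molecules; the toy molecular weights and element sets attached to library
records exist to exercise admission filters, nothing more.

## Numerical conventions and degenerate inputs

* Standard deviations use the sample (n−1) denominator everywhere
  (normalization and its validation alike).
* Zero-variance means raw SD < 1e-12; such descriptors are dropped with
  a message, and a table that loses every descriptor is an error.
* Non-finite descriptor values are rejected at ingestion, never imputed.
* Distance matrices must be symmetric to 1e-9 with a zero diagonal and no
  negative entries.
* Molecular-weight admission is strict (< 200 u); element comparison is
  by symbol set, counts and isotopes ignored, implicit hydrogens counted.
* All tabular I/O is CSV (UTF-8, first row column ids, first column row
  ids) written at 17 significant digits so round-trips are bit-exact;
  multisets, active sets and traces serialize as JSON.

## Problem sizes used by the tests

The shipped tests and the acceptance script run at deliberately modest
scale, chosen so the full pipeline — including twenty-five refits per
cross-validation — re-runs comfortably on a laptop: recovery at 100
compounds × 200 descriptors, cross-validation at 100–109 compounds × 20–50
descriptors, screening at a 1080-compound library, oracle comparisons at
8–12 compounds. All oracle checks (brute-force objective, exhaustive
greedy step, APoA enumeration, column duplication) agree with the
implementation to 1e-12.
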
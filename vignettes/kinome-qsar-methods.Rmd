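---
title: "KinomeQSAR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KinomeQSAR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KinomeQSAR)
```

## The problem

Small-molecule kinase inhibitors are rarely selective: most target the
conserved ATP pocket, so a compound optimized against one kinase usually
binds tens of others. Panel profiling (competition binding assays reporting
a Kd for every compound x kinase pair) measures this directly but is
expensive, so a computational stand-in is useful early in hit-to-lead
work. KinomeQSAR implements a quantitative structure--activity relationship
(QSAR) pipeline for this setting: a molecule is encoded as a fixed-length
numeric descriptor vector, and one multi-task feed-forward network maps
that vector to a binary activity call for every kinase in the panel at a
chosen Kd cutoff.

## Molecular descriptors

Every molecule, whether read from SDF V2000 or from SMILES (via OpenBabel),
is reduced to its heavy-atom graph with implicit hydrogens folded onto
their heavy atoms; a flag can keep explicit hydrogens instead. Four
families of descriptors are computed, all sums over atoms or atom pairs
and therefore invariant to atom reordering, and for the geometric blocks
to rigid rotations and translations (only interatomic distances
$d_{ij}$ enter):

* **Scalar 1D** (formula level): molecular weight, total formal charge,
  heavy-atom count.
* **Scalar 2D** (connectivity level): hydrogen-bond donors (N/O with at
  least one hydrogen), acceptors (N/O), ring count (cyclomatic number of
  the heavy-atom graph, which equals the size of the smallest set of
  smallest rings), and additive surface-area/volume approximations from
  per-element van der Waals radii.
* **Topological autocorrelation** over a per-atom property $p$:
  bin $k$ holds $\sum p_i p_j$ over pairs at shortest bond-path distance
  $k$; bin 0 holds $\sum_i p_i^2$.
* **Geometric encodings** of a property over 3D structure:
  the radial distribution function
  $\mathrm{RDF}_k = \sum_{i<j} p_i p_j \exp(-B (r_k - d_{ij})^2)$ with
  $r_k = k\,\Delta r$, and the 3D autocorrelation
  $A_k = \sum_{i<j} p_i p_j \,\mathbf{1}[k\Delta \le d_{ij} < (k+1)\Delta]$.
  Bins are half-open and start at distance zero; self-pairs are excluded.

The per-atom properties are `identity` (1 for every atom), element-lookup
electronegativity (Pauling) and polarizability (A^3) from a versioned
table shipped with the package, and a PEOE-style partial charge: iterative
electronegativity equalization over the sigma framework with damping
$(1/2)^k$ and six iterations. Implicit hydrogens participate as explicit
nodes during the iteration and their charge is folded back onto the parent
heavy atom, so charges sum exactly to the molecular formal charge and
topologically equivalent atoms receive identical values. Partial charges
are used signed; RDF/3DA blocks over charge may therefore be negative,
which preserves information at the cost of exact numeric compatibility
with implementations that rectify.

**The 400-feature default layout.** The network input width is fixed at
400, but the composition of the original descriptor set behind that number
is unpublished, so the package defines (and documents) its own default and
makes it fully config-overridable: 8 scalars (3 x 1D + 5 x 2D), an 8-bin
topological autocorrelation over identity, and for each of four properties
(identity, partial charge, electronegativity, polarizability) a 48-bin RDF
($\Delta r = 0.25$ A, $B = 100$ A$^{-2}$) and a 48-bin 3DA
($\Delta = 0.25$ A): $8 + 8 + 192 + 192 = 400$, spanning distances to
12 A, ample for drug-sized molecules. Two closed-form identities pin the
numerics and are enforced in the tests:
$\sum_k \mathrm{RDF}_k \Delta r \to \sqrt{\pi/B} \sum_{i<j} p_i p_j$ when
the grid covers all distances with margin $5/\sqrt B$, and
$\sum_k A_k = \sum_{i<j} p_i p_j$ exactly once $K\Delta$ exceeds the
molecular diameter.

## Activity data and labels

An activity matrix holds Kd in uM (rows compounds, columns kinases,
blank = not measured). Binarization is strict — active means
$K_d < \mathrm{cutoff}$ — on the canonical cutoff grid 0.1, 0.5, 1, 3,
10 uM, and an unmeasured pair is inactive at every cutoff. The latter
convention mirrors dense published panels, where every compound x kinase
pair carries a label and non-binders simply have no reported Kd; it also
makes the active sets nested across cutoffs, which the tests assert.

## The network and its training

The model is a one-hidden-layer sigmoid network, 400 inputs, 32 hidden
units, one output per kinase, all outputs sharing the hidden layer
(multi-task). Inputs are standardized feature columns (population sd;
constant columns map to zero and are flagged). Weights start uniform in
$[-1/\sqrt{\mathrm{fan~in}}, +1/\sqrt{\mathrm{fan~in}}]$, biases at zero,
deterministically from a seed.

Training is classic online back-propagation with momentum: per presented
example, $\Delta w(t) = -\eta\, \partial E/\partial w + \alpha\, \Delta
w(t-1)$ with $\eta = 0.1$, $\alpha = 0.5$ and sum-of-squares error
$E = \tfrac12 \sum (y - t)^2$ on the sigmoid outputs (cross-entropy is
available behind a config switch). Examples are presented in a freshly
shuffled order each epoch (seeded), for at most 500 epochs, keeping the
weights of the epoch with the lowest loss on a 20% monitoring split and
stopping after 50 epochs without improvement. The epoch/stopping recipe is
a package default — the original protocol does not state one — and every
run records it. The inner update loop is compiled (RcppArmadillo) and is
pinned, step for step, against the pure-R reference implementation
`annBackpropStep()` in the tests; gradient correctness is checked against
central finite differences. If a label mask is supplied, masked outputs
contribute zero gradient.

Validation is compound-level 5-fold cross-validation (a compound's entire
kinase profile is held out together — cell-level splitting would leak a
molecule's descriptor vector into its own test set). Normalizers and
monitoring splits are refit inside each training fold.

## Evaluation

Pooling TP/FP/TN/FN across all kinases and compounds gives sensitivity
SEN = TP/(TP+FN), selectivity SEL = TN/(TN+FP), accuracy, positive and
negative predictive values, and the Matthews correlation coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.$$

A metric with a zero denominator is reported `NA` and flagged, except MCC,
which is flagged and set to 0 (a never-varying classifier carries no
correlation signal). ACC/SEN/SEL are reported in percent, MCC/PPV/NPV as
fractions, matching the usual table layout.

ROC curves sweep thresholds over distinct score values descending with
ties grouped; the trapezoidal AUC then equals the Mann--Whitney
U-statistic scaled to $[0,1]$ with tied pairs counted one half, and the
tests verify this against brute-force pair counting. Per-kinase AUC
distributions are summarized by quartiles with 1.5 x IQR whiskers.
Per-kinase decision thresholds are chosen among midpoints of consecutive
distinct scores to maximize MCC, ties broken toward the higher (more
conservative) threshold.

Two model-comparison tests are provided. The per-kinase AUC vectors of two
models are compared with the Wilcoxon signed-rank test — the paired
analog of the Mann--Whitney test, pairing by kinase; zero differences are
dropped, the two-sided p comes from exact enumeration of all $2^n$ sign
patterns for up to 12 non-zero pairs (valid under tied rank magnitudes)
and from the tie-corrected, continuity-corrected normal approximation
above that. The exact branch is cross-checked against `wilcox.test`; the
two branches agree to about 0.01 on average at the branch point, with
worst cases near 0.014 — a limit of the normal approximation itself, not
of the implementation. An unpaired Mann--Whitney U wrapper is included
for completeness. Second, a model is compared against a random caller
that labels 50% of cases positive: the 2x2 table rows {model, random} x
columns {correct, incorrect} — the random row being (total/2, total/2) —
is tested with Fisher's exact test. Such comparisons are often reported
without stating the table construction; the one used here is recorded in
every report.

The difference map classifies each cell of experimental-vs-predicted
binary matrices as correct / false positive / false negative; counts
always sum to the number of cells, and correct = TP + TN by construction.

## The synthetic panel generator

Because the original assay panel is external data, the package carries a
planted-signal generator that makes every stage testable offline — and
the defaults of that generator are the package's study conditions, not
tuning knobs. Fixture molecules are a curated base set (short alkane
chains, six-rings, N/O variants) plus seeded decorated variants with a
small coordinate jitter; 120 molecules yield well over 50 distinct
400-feature vectors. For each of 20 kinases (5 carrying signal), log
activity follows

$$\log_{10} K_d(\mathrm{uM}) = a_k - \beta\, z_k + \varepsilon, \qquad
\varepsilon \sim N(0, \sigma),$$

where $z_k$ is the standardized mean of that kinase's 5 randomly chosen
descriptor columns, $\beta = 2$, $\sigma = 0.3$ (log-units, a realistic
assay-noise scale), and $a_k$ places the Kd < 10 uM fraction at the
prevalence target 0.25 — the active fraction of a dense inhibitor panel
at the permissive 10 uM cutoff. Kd is floored at $10^{-4}$ uM. Noise
kinases draw activity independent of the features. The signal enters
through descriptor values rather than raw structure deliberately: recovery
then isolates the learner from descriptor fidelity, so a failure
diagnoses cleanly.

What passing recovery shows — and what it does not. On this panel,
compound-level 5-fold CV with the default network reaches mean held-out
AUC above 0.8 on signal kinases and near 0.5 on noise kinases across
seeds (the tests run 10 seeds at 120 x 20). That demonstrates the
descriptor -> network -> evaluation chain is wired correctly and can
recover a planted monotone structure--activity signal at realistic noise.
It does not certify performance on real kinase panels: real inhibitors
share scaffolds, signals are not linear in single descriptor columns, and
panel activity is far sparser and more correlated than independent noise.
Reproducing the published real-data AUCs would additionally require the
external panel and the original (closed) descriptor implementation.

## Numerical and design choices, in one place

* Distance bins half-open, $[k\Delta, (k+1)\Delta)$, starting at zero.
* Feature standardization uses population sd (a two-point column (0, 2)
  maps exactly to (-1, 1)).
* Threshold ties break toward the higher threshold; MCC with degenerate
  denominator is 0 and flagged.
* PEOE: 6 iterations, damping $(1/2)^k$, sigma framework only, synchronous
  updates within an iteration; hydrogen's cation electronegativity uses
  the conventional 20.02.
* V2000 only; V3000 records are rejected with a clear error. Coordinates
  round-trip at the format's 4-decimal precision. `M CHG` property lines
  override atom-block charge codes, as the format prescribes.
* Kd floored at 1e-4 uM; prevalence calibration places the threshold
  between order statistics, so the realized active fraction is exact at
  the generated sample size.
* Model JSON serializes weights at 17 significant digits, so reload is
  bit-stable.
* Problem sizes in the shipped tests: 120 compounds x 20 kinases, 5-fold
  CV, 10 seeds for the recovery study; 100 random instances for each
  evaluation oracle; 100 rigid transforms and permutations per fixture
  molecule for the invariance suite.

## Known limitations

* Aromaticity handling is limited to ring detection and bond orders as
  given; no tautomer or protonation-state enumeration.
* The default descriptor layout is this package's own reconstruction of
  an unpublished 400-input composition; numeric compatibility with the
  original implementation is explicitly not a goal.
* Conformer quality is taken as given: descriptors use whatever 3D
  coordinates the input provides.
* The trainer is CPU-only and single-architecture (one hidden layer), by
  design.
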
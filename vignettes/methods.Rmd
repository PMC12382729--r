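---
title: "Dual-modality brain network analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modality brain network analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsweep)
```

## What the package computes

netsweep implements a case-control analysis of paired brain connectivity
networks. Each subject contributes two weighted, undirected 90-node graphs:

* a **functional connectivity network (FCN)** whose edges are Pearson
  correlations between cleaned regional BOLD time series, and
* a **structural connectivity network (SCN)** whose edges are the elementwise
  product of a fractional anisotropy (FA) matrix and a fiber-count (FN)
  matrix, so an edge reflects both the integrity and the quantity of the
  white-matter tracts linking two regions.

Because raw weighted networks of different subjects differ in density, every
graph metric is computed across a **proportional sparsity sweep**: at
sparsity $s$ the $k = \lfloor s\,N(N-1)/2 + 0.5 \rfloor$ strongest edges are
retained with their weights. The default grid runs from 0.05 to 0.45 in steps
of 0.01 (41 thresholds). Each metric curve is then summarized by its **area
under the curve (AUC)** over the grid, giving one threshold-free number per
subject and metric; group statistics consume only these AUC values.

### Graph metrics

Global: clustering coefficient $C_p$, characteristic path length $L_p$,
global efficiency $E_g$, local efficiency $E_{loc}$; with null-model
normalized $\gamma = C_p / \langle C_p^{rand}\rangle$,
$\lambda = L_p / \langle L_p^{rand}\rangle$ and small-worldness
$\sigma = \gamma / \lambda$. Nodal: degree centrality (strength) $D_c$,
betweenness $B_c$, nodal efficiency $N_e$, nodal local efficiency $N_{le}$,
and nodal clustering $NC_p$.

Conventions the source description leaves open, fixed here:

* **Weighted clustering** is Onnela's geometric-mean-of-triangles form with
  weights normalized by the network maximum; it is scale invariant and has
  closed-form values on small graphs, which makes it exactly testable.
* **Edge length** for all path-based metrics is the reciprocal edge weight.
* **$L_p$ on disconnected graphs** averages over reachable pairs only; the
  fraction of unreachable pairs is reported alongside (`disconnected`).
  Efficiency-type metrics count unreachable pairs as zero contribution.
* **$D_c$ is node strength** (summed weights), not binary degree: the
  magnitudes reported for structural networks in this literature are only
  plausible under summed weights.
* **$B_c$ is unnormalized** (raw shortest-path counts).
* **Edge-count rounding** in proportional thresholding is round-half-up, and
  ties are broken by weight (descending) then node-pair index, so edge sets
  are nested across the grid and identical across platforms.
* **Negative functional correlations** are excluded before ranking by
  default (`negative_fc_policy = "zero"`); mixing signs under proportional
  thresholding is ill-defined. An `"absolute"` policy (rank and retain
  $|r|$) is available.

### Null model

Small-world normalization uses degree-preserving Maslov–Sneppen rewiring of
the binary topology ($10\,|E|$ double-edge-swap trials via igraph, exact
degree preservation on every draw) followed by random reassignment of the
original weight multiset onto the rewired edges. $C_p$ and $L_p$ of each
null are recorded and averaged. The literature default of 1000 nulls is the
package default (`n_null`); the validation suite and the acceptance script
use 100 nulls per network, which changes $\sigma$ estimates by far less than
the between-subject spread. Saturated thresholds (those retaining every
available edge) share one network and therefore one null ensemble.

### Structure–function coupling

Per subject, the non-zero edges of the *unthresholded* SC matrix are
selected, their weights rescaled to a Gaussian shape by the van der Waerden
rank-based inverse-normal transform $\Phi^{-1}(r_i/(n+1))$ (average ranks on
ties), and Pearson-correlated with the FC values at the same edges. Edges
are selected on the full matrix rather than the sparsity sweep because
coupling is defined on the subject's connectivity matrix, not on any
particular threshold. FC values enter signed and untransformed; coupling is
therefore exactly invariant to monotone transforms of the structural weights
but is a *Pearson* (not rank) correlation in the functional direction — an
FC that is a nonlinear monotone function of SC yields $r < 1$.

### Statistics

* Normality gate: one-sample Kolmogorov–Smirnov statistic against a normal
  with the sample mean/SD (an approximation to a Lilliefors test, used only
  to pick the t vs Mann–Whitney branch at $\alpha = 0.05$).
* Demographics: pooled-variance two-sided t or Mann–Whitney U for continuous
  variables; Pearson $\chi^2$ *without* continuity correction for the 2×2
  sex table — the uncorrected form is the one that reproduces the printed
  demographic p-value (0.334) from the printed counts.
* Group contrasts on AUC values: ordinary least squares
  `value ~ group + age + sex + duration`, patients coded 1, controls 0, so a
  positive coefficient means patients > controls. Disease duration is 0 for
  controls (they have no illness to have a duration of); dropping the
  covariate instead is possible by passing a different covariate set.
* Nodal families: Bonferroni within each (network, metric) family of 90
  tests, adjusted threshold $0.05/90 = 0.0005556$ (reported to 7 decimals);
  no cross-family correction.
* Coupling contrast: permutation test on the group mean difference with the
  add-one rule $p = (1 + \#\{|d^{perm}| \ge |d^{obs}|\})/(n_{perm}+1)$
  (default 5000 permutations), so p is never exactly zero.
* Clinical correlations: partial Pearson correlations between patient-group
  AUC metrics and WISC/WMS/ADHD scores, controlling for age, sex and
  duration, with $t = r\sqrt{(n-2-k)/(1-r^2)}$ p-values at $\alpha = 0.05$.

## The synthetic cohort generator

No patient data are distributed with studies of this kind, so the package
ships a seeded generator whose defaults encode the study conditions all
validation runs under: 90 nodes, 36 patients (HS) and 36 controls (HC),
190 time points at TR = 2 s, ages truncated-normal $N(9.0, 2.2)$ on [6, 13]
years with one shared Bernoulli(0.6) sex vector (groups sex-matched by
construction), and patient disease duration truncated-normal
$N(4.89, 3.11)$ months at $\ge 0.5$.

* **Structural backbone**: one template per cohort — six modules at 15%
  overall density, within-module pairs filled first, each edge endpoint
  rewired with probability 0.1 (connectivity enforced with up to 100
  redraws). Template FA is uniform on [0.2, 0.9]; template fiber counts are
  lognormal with mean 50. Subjects jitter FA (sd 0.03, clipped) and FN
  (multiplicative lognormal, rounded, minimum 1), so FA and FN share zero
  patterns exactly.
* **Patient effect**: fiber counts of edges incident to eight designated hub
  nodes (stand-ins for the superior frontal, orbital frontal, superior
  occipital, superior parietal, precuneus and median cingulate regions) are
  multiplied by 0.6, and every patient edge is deleted independently with
  probability 0.08. Together these lengthen shortest paths and lower global
  and hub-level efficiency — the direction of the case-control differences
  the analysis is meant to detect — without tuning any metric directly.
* **Functional signals**: multivariate normal draws with covariance
  $\Sigma = D^{-1/2}(SC + cI)D^{-1/2}$, $D = \mathrm{diag}(SC + cI)$ and
  $c = 1.05\,|\lambda_{\min}(SC)| + 0.1$, plus independent observation noise
  (sd 1). $\Sigma$ is positive definite by construction, has unit diagonal,
  and its off-diagonal entries are proportional to the structural weights,
  so empirical FC is positively coupled to SC and the strongest structural
  edge carries the largest expected correlation.
* **Clinical scores**: generated from the *generator-side* structural
  metrics (path-length AUC, efficiency AUC, precuneus-proxy nodal-efficiency
  AUC) so recovery tests have a defined truth. Scores are centered on the
  published patient means (WISC 73.64, WMS 75.08, ADHD 24.61) with slopes on
  within-group z-scores and noise chosen so marginal SDs land near the
  published ones; WISC decreases and ADHD increases with path length, WMS
  increases with precuneus efficiency. A null configuration (attenuation 1,
  no edge deletion, zero slopes) makes the groups exchangeable for
  calibration studies.

What the generator does **not** emulate: hemodynamics (no balloon-model
BOLD), head motion, scanner drift beyond what the preprocessing tests inject
explicitly, tractography biases, or spatial autocorrelation of the
parcellation. Passing tests therefore demonstrate that the pipeline
recovers planted effects under a linear-Gaussian world with a small-world
structural prior — not that it is robust to every artifact of real MRI data.

## Preprocessing

Only the signal-domain cleaning steps are in scope (image-domain steps need
the original scans): per-node linear detrending (OLS), nuisance regression
against an arbitrary confound table (constant columns dropped, rank checked),
and an ideal discrete-Fourier band-pass over 0.01–0.08 Hz at TR = 2 s. The
ideal mask was chosen over a Butterworth filter because only the band is
specified and a mask makes pass/stop behaviour exactly testable (in-band
tones preserved to 1e-10, out-of-band removed, idempotent). The zero
frequency bin is always removed. Fixed order: detrend → confounds →
band-pass.

## Numerical choices and degenerate inputs

* Matrices are symmetrized by averaging on read, with a warning above a
  1e-8 asymmetry; diagonals are forced to zero; values round-trip through
  the text format to 1e-12 (17 significant digits).
* Zero-variance nodes get zero FC rows with a warning, so they simply never
  win a threshold rank.
* An empty thresholded network reports all metrics as 0 with a warning;
  $k = 0$ sparsities are an error.
* Undefined small-world indices (zero null means on degenerate networks)
  are reported missing, and the pipeline excludes those curves from AUC
  summarization with a log entry.
* Every stochastic stage derives a substream seed from the run seed, so a
  fixed seed reproduces numeric outputs byte for byte.

## Problem sizes used in validation

The shipped test suite validates metric correctness against brute-force
references (scalar Floyd–Warshall, exhaustive triangle enumeration,
shortest-path counting) on 200 random graphs of up to 12 nodes at 1e-10;
runs the small-world sweep on one full 72-subject synthetic cohort at 100
nulls per network; checks effect-direction recovery and null calibration
over 50 + 50 simulated cohorts of 36 + 36 subjects; and exercises the full
pipeline end to end at a reduced smoke scale (30 nodes, 8 subjects). These
sizes keep the whole suite within a coffee break on one CPU while leaving
every scientific claim tested at the cohort dimensions the analysis targets.

## Known limitations

* The exact weighted-clustering variant, disconnection convention and
  strength-vs-degree choice of the original GRETNA-based analyses are not
  documented; the conventions above are declared, tested alternatives.
* The KS normality gate uses estimated parameters without the Lilliefors
  correction and is mildly conservative.
* The rectangle AUC rule is provided for comparability with step-sum
  conventions but the trapezoid rule is the default and the one used in all
  shipped results.
* Functional small-world indices on correlation networks can legitimately
  fall below 1; small-world assertions in the validation suite apply to
  structural networks only.
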
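---
title: "Voxel-level functional networks versus activation maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-level functional networks versus activation maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

A recurring finding in psychiatric neuroimaging — most prominently in
schizophrenia research, where it is known as the disconnection hypothesis —
is that group differences live in the *interactions* between brain regions
rather than in local task responses. netfmri implements the full analysis
chain needed to make that claim quantitative on task fMRI: conventional GLM
activation mapping, voxel-level functional-network construction with
topological feature extraction, corrected mass-univariate group statistics,
and predictive modelling under leave-one-subject-out cross-validation
(LOSOCV). A classifier that generalizes to unseen subjects from network
features but not from activation features is direct evidence that the
discriminative signal is relational, not local.

Because raw clinical fMRI cohorts are rarely shareable, the package ships a
generative cohort simulator whose *design goal* is the dissociation itself:
two groups with identical activation statistics that differ only in
long-range, inter-hemispheric inter-voxel coupling. Everything downstream is
exercised end-to-end against this synthetic cohort.

## The generative model

Each masked voxel's signal in one run is

$$y_v(t) = \mu_0 + a_v\,(s \ast h)(t) + \sum_f L_{v,f}\, z_f(t) +
\sigma\,\varepsilon_v(t)$$

* $\mu_0 = 100$ — baseline intensity (strictly positive so mask
  auto-detection works on exported NIfTI volumes);
* $s$ — the indicator train of the two auditory conditions
  (`FrenchNative`, `Foreign`), convolved with the canonical HRF $h$;
  `Silence` trials evoke no response;
* $a_v$ — per-voxel activation amplitudes inside a bilateral "auditory"
  blob, drawn once per subject from $\mathcal N(\mu_a, 0.1\mu_a)$ with
  $\mu_a = 1$ **identically in both groups** — the activation-null premise;
* $z_f$ — unit-variance AR(1) latent series (coefficient 0.3: smooth,
  fMRI-like autocorrelation that keeps the factor-model correlation
  $r = L^2/(L^2+\sigma^2)$ exact), shared by all voxels in factor $f$'s
  spatial support;
* $\varepsilon$ — white Gaussian noise, $\sigma = 1$.

### Where the group difference lives

The default factor set is *variance-matched*:

| factor | support | control loading | patient loading |
|---|---|---|---|
| bilateral | both auditory spheres (88 voxels) | 2.0 | 0 |
| left-, right-local | one auditory sphere each | 0 | 2.0 |
| left-, right-background | one 96-voxel posterior sphere each | 2.0 | 2.0 |

Within a hemisphere, every coupled pair has time-series correlation
$\approx 4/5 = 0.8$ in *both* groups; across hemispheres only controls are
coupled. Marginal voxel variance is identical across groups, so no
univariate statistic can separate them — only the coupling pattern can.
With the graph threshold at 0.7, coupled pairs reliably form edges at
$T = 200$ volumes (sampling noise on $r \approx 0.8$ has standard deviation
about 0.025).

The shared background factors serve a subtle purpose: degree maps are
spatially normalized per sample (division by the maximum), and in a design
without a group-invariant high-degree region the normalization itself would
cancel the group difference (each group's map would be rescaled by its own
support degree). The background component is larger (96 voxels per
hemisphere) than the bilateral component (88 voxels in total), sets the
maximum degree for every sample in both groups, and thereby preserves the
group contrast inside the bilateral support after normalization.

### Keeping the coupling invisible to activation statistics

The latent processes model *ongoing* activity that is independent of the
stimulus. A finite realization of such a process still overlaps the design
subspace by chance, and that overlap leaks into condition betas (directly
and through the drift and motion columns) and into the shared residual
variance of all voxels in a factor's support. The leak does not bias any
single voxel, but it makes the group-test p-values of coupled voxels move
as a block, which ruins distributional calibration checks that treat voxels
as exchangeable. The generator therefore realizes every latent series
orthogonal to the run's full design subspace (intercept, three condition
regressors, cosine drifts below 1/128 Hz, six motion parameters) and
rescales it to unit variance. This implements stimulus-independence exactly
rather than in expectation; activation t-maps of a default cohort are
empirically indistinguishable from group-null (Kolmogorov–Smirnov against
uniform, zero-to-one FDR survivor out of 1200 voxels).

### Scale, seeding, and what the simulator does not model

The default grid is 16×16×12 voxels (10 mm isotropic) with two ellipsoidal
"hemisphere" lobes separated at $x = 0$ — 1200 masked voxels, small enough
for full $V \times V$ correlation matrices at interactive speed yet large
enough for meaningful graph statistics. Runs have 200 volumes at TR 2 s
with a 60-trial balanced paradigm; a paper-scale run (416 volumes, 96
trials) is one argument away (`n_volumes = 416, n_per_condition = 32`).
These sizes were chosen so the complete study — simulation, GLM, networks,
statistics, cross-validation — finishes in a few minutes on one core.

All randomness flows from one master seed through a documented Lehmer-hash
child-seed scheme keyed by (subject, run, component), so cohorts are
byte-reproducible and adding subjects never perturbs existing ones. Motion
traces draw from their own stream and are independent of every BOLD
component by construction.

Not modelled: scanner physics, spatial smoothing, susceptibility artifacts,
motion-induced signal corruption, symptom time courses. Passing tests on
this cohort therefore demonstrate the *pipeline's* correctness and the
*logical* soundness of the dissociation argument — not that real
schizophrenia data behave this way.

## GLM choices

* **HRF**: canonical double-gamma — response gamma(shape 6, rate 1) minus
  undershoot gamma(16, 1)/6, scaled to unit peak (maximum near 5 s).
* **Design**: condition regressors are built on a 0.1 s grid and sampled at
  volume onsets; drift columns are the unit-norm DCT-II components with
  frequencies up to the cutoff, $K = \lfloor 2\,T\,\mathrm{TR}\,f_c\rfloor$
  (13 columns at $T = 416$, TR 2 s, $f_c = 1/128$ Hz; the component at
  exactly the cutoff frequency is included); six motion columns when
  available; one intercept. All-zero condition columns (a paradigm missing
  a condition) are permitted at construction; collinearity among nonzero
  columns is an error naming the offending columns.
* **Contrasts**: the eight standard maps. Maps 1–5 are condition
  differences; maps 6–8 are the single-condition amplitudes, i.e. the
  condition beta itself — since the regressors measure response above the
  modelled intercept, "condition versus baseline" is the unit contrast on
  that beta.
* **Degenerate voxels**: zero residual variance with a nonzero contrast
  gives a signed-infinity sentinel that downstream ranking and averaging
  exclude; zero over zero gives 0.
* **Spatial normalization** divides by the maximum *absolute* value so
  signed t-maps land in $[-1, 1]$; for nonnegative degree maps this equals
  division by the maximum.
* **ROI analysis**: spheres defined in mm through the affine, boundary
  included; series are spatial means residualized against the drift basis
  plus intercept (an orthogonal projection, hence idempotent). PPI weights
  are the HRF-convolved condition regressor clipped at zero and normalized
  to sum one — clipping keeps the weighted-correlation formula well defined.

## Network choices

* **Edges**: strict inequality, $r > 0.7$ by default. Degree, strength,
  global and distance analyses threshold the *raw* correlations; clustering
  and local efficiency threshold the *absolute* correlations. Both modes
  are exposed; the split default mirrors the two conventions' respective
  uses in the field.
* **Long-distance degree** counts neighbours at Euclidean distance ≥ 5 in
  voxel-index units (a mm-space alternative is an argument).
* **Hemisphere labels** follow the sign of the mm x-coordinate; $x = 0$
  voxels are midline and never count toward inter-hemispheric numerators.
* **Strengths** are computed on the unthresholded correlation matrix
  (signed, absolute, positive variants).
* **Mean geodesic** averages over *connected* ordered pairs only: these
  graphs are deliberately sparse and disconnected, and infinite distances
  would otherwise dominate. The empty graph reports `NA`.
* **Distance profiles** use 5 mm bins from 0; the power-law
  $p(d) = a\,d^{-\gamma}$ is fitted by least squares in log–log space over
  positive bins with centres in [10, 150] mm.
* **Constant voxel series** get correlation 0 to all partners and a flag,
  instead of undefined Pearson values.
* Path-based metrics (components, geodesics, neighbourhood subgraphs) are
  computed through igraph; the test suite checks every graph feature
  against independent brute-force oracles (Floyd–Warshall, triangle
  counting) on random graphs.

## Statistical choices

* The mass-univariate test is the unpaired pooled-variance two-sample t
  (df $= n_1 + n_2 - 2$). The 44 samples (two runs per subject) are treated
  as independent observations, matching the study design this pipeline
  reproduces; the violation (within-subject correlation) is real and is the
  reason all predictive claims rest on *subject-level* cross-validation
  instead.
* FDR selection is Benjamini–Hochberg step-up (via `p.adjust`), Bonferroni
  is $p \le \alpha/N$; both are oracle-tested, and the empirical false
  discovery proportion on pure-null simulations stays below the nominal 5%.
* Ranking ties break by ascending feature index everywhere, so selections
  are bit-reproducible.
* The ROI-level group test is the two-sided Wilcoxon rank-sum with
  Bonferroni correction across measures: the groups are disjoint subjects,
  so a signed-rank (paired) test would be inappropriate; it remains
  available via `paired = TRUE` for genuinely paired designs.
* The motion-confound check correlates each feature with a per-sample
  motion summary (mean absolute framewise displacement of the translations)
  and FDR-corrects the resulting p-values; on the synthetic cohort the
  selection is empty, as designed.

## The sparse Gaussian MRF classifier

Per class, features are centred and the maximum-likelihood ($1/n$)
covariance $S$ is formed; the precision matrix solves

$$\max_{C \succ 0}\ \log\det C - \mathrm{tr}(SC) - \lambda \lVert C\rVert_1$$

with the elementwise $\ell_1$ norm over **all** entries (the Laplace-prior
reading of the penalty; a diagonal-unpenalized variant sits behind
`penalize_diag = FALSE`). The solver is proximal gradient (ISTA) with
backtracking that maintains positive definiteness; soft-thresholding yields
exact zeros. Convergence is certified by an explicit duality gap: the dual
value $\log\det W + p$ is evaluated at the entrywise box projection of
$C^{-1}$ onto $\{W : |W - S|_\infty \le \lambda\}$, and iteration stops at
gap $\le 10^{-5}$. An early shortcut-gap formulation (the gap expression
evaluated without projecting onto the feasible box) certified a
far-from-optimal iterate at $\lambda = 0$ and was replaced; the test suite
now cross-checks the solver's objective against an independent ADMM
implementation and the closed-form $2\times 2$ inverse.

Classification is most-likely-class under the per-class Gaussian densities
with equal priors (the cohort is balanced by design). $\lambda$ is swept
and reported per value, never tuned inside folds — tuning would multiply
the compute by the grid size and is deliberately omitted. The Gaussian
naive Bayes classifier uses a variance floor of $10^{-9}$ times the
largest feature variance so constant-in-fold features cannot produce
degenerate densities; the linear max-margin classifier is libsvm's linear
kernel at its default cost with no input scaling.

## Cross-validation design

Folds are leave-one-subject-out: the held-out subject's two runs form the
test set, and *feature selection runs inside each fold* on training rows
only. The package's null-calibration test shows why this matters: on pure
noise, in-fold selection gives 50% error, while selection on the full table
before splitting would look dramatically (and spuriously) accurate. Errors
are pooled over all held-out predictions (equivalent to fold-averaging
here, since every test set has size two). "Patient" is the positive class:
FP is the fraction of control samples called patient, FN the reverse.

One empirical note: on activation features — which carry *no* group signal
in this cohort — cross-validated error often lands visibly above 50%.
This anti-learning is a known small-sample artifact of selecting
significance-ranked null features: voxels chosen for spurious training-set
separation tend to reverse on held-out subjects. It does not affect the
degree-versus-activation comparison, which is driven by the degree
features' genuine signal.

## Known limitations

* The synthetic coupling is block-structured, so degree differences are
  sharper and classifiers far more accurate (0% error) than any real
  cohort would allow; magnitudes are not comparable to clinical data, only
  directions and orderings are.
* Correlation estimates use no temporal prewhitening; the AR(1) latent
  autocorrelation is mild and identical across groups, so group contrasts
  are unaffected, but absolute correlation values inherit it.
* The full correlation form is capped (default 5000 voxels); beyond that,
  edge features must go through the fixed sampled-pair path.
* Graphs are undirected and unweighted past the threshold; no effective
  or directed connectivity is attempted.
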
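---
title: "Methods: from intact-Fab LC-MS runs to clonal repertoire profiles"
author: "fabprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from intact-Fab LC-MS runs to clonal repertoire profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabprofiler)
```

## The problem

Circulating IgG1 antibodies form a clonal repertoire: each B-cell clone
secretes one antibody species with a unique protein sequence and therefore a
unique intact mass. Digesting serum IgG1 above the hinge releases Fab
fragments of roughly 46-51 kDa, and an MS1-only LC-MS run of these Fabs
encodes the repertoire as a collection of co-eluting electrospray charge
envelopes. `fabprofiler` turns such a run into a *clonal profile* — a table
of clones, each a unique (mass, retention time) pair with an intensity — and
compares profiles across samples and instrument platforms with a
tolerance-matched cosine similarity.

The pipeline has five stages, applied in a fixed order per slice:
**average → baseline subtract → smooth → deconvolute → pick peaks**, followed
by merging the per-slice mass lists into one clone list.

## Sliding-window slicing and spectrum conditioning

The run's region of interest (default 10-50 min) is cut into overlapping
retention-time windows: width 0.3 min with 0.05 min overlap, so window $k$
starts at $t_0 + 0.25k$ and the last window is clipped to end exactly at the
ROI end. Under the defaults this yields 160 windows. All scans inside a
window (half-open $[t_s, t_e)$; the final window is closed so a scan at the
ROI boundary belongs to it alone) are resampled onto one uniform m/z grid
(0.1 Th by default, linear interpolation) and averaged point-wise. Windows
with no scans are flagged empty and skipped rather than interpolated.

**Baseline.** Denatured-Fab runs show an elevated unresolved background,
broadest in the 1000-2000 Th range. We estimate it with asymmetric least
squares (Whittaker smoother with asymmetric weights): minimise
$\sum_i w_i (y_i - b_i)^2 + \lambda \sum_i (\Delta^2 b)_i^2$ with
$w_i = 0.05$ above the current baseline and $1$ below, iterated 10 times.
The user-facing knob is a *flatness* $f \in (0, 1]$, mapped log-linearly to
a length scale $L = 10^{1 + 2f}$ Th (10-1000 Th) that we interpret as the
smoother's cutoff wavelength, $\lambda = (L / (4\pi d))^4$ for grid spacing
$d$. Higher flatness therefore gives a stiffer, flatter baseline; the
mapping is tested for monotonicity, for full removal of constant offsets,
and for preserving narrow peaks (FWHM 0.2 Th on an 800 Th hump) to within
5% of their height. It makes no claim of equivalence with any vendor
implementation of a "flatness" parameter.

**Smoothing.** One pass of Gaussian smoothing with FWHM 0.2 Th
($\sigma =$ width$/2.3548$), kernel normalised to unit sum so total
intensity is conserved away from the grid edges.

## Charge-state deconvolution

Each conditioned slice spectrum $y$ is inverted to a zero-charge mass
spectrum $x$ on a uniform mass grid (45000-52000 Da, 0.1 Da spacing). The
forward model is
$$\hat y(\mu) = \sum_m \sum_{z=z_{\min}}^{z_{\max}} x(m)\, g\!\left(\mu;\ \tfrac{m + z\,m_p}{z},\ \mathrm{FWHM} = \mu / R\right),$$
with unit-sum Gaussian peaks, a uniform prior over charges (12-60 by
default; no charge weighting is assumed), proton mass $m_p = 1.007276$ Da
and instrument resolving power $R = 10000$. Charge peaks whose support
leaves the acquired m/z range are dropped. The operator is a sparse matrix
(~19 million non-zeros at the default settings) built once per
configuration and cached.

The inversion uses multiplicative Richardson-Lucy-type updates
$$x \leftarrow x \odot \frac{A^\top (y / A x)}{A^\top \mathbf 1},$$
initialised uniformly and stopped when the relative $L_1$ change of $x$
falls below $10^{-4}$ or after 100 iterations (both exposed in the
configuration). These updates preserve non-negativity and scale, and masses
whose envelope receives no observed intensity are exactly zero after one
update, so they are excluded up front — on sparse spectra this shrinks the
problem by orders of magnitude. The solver is a contract-equivalent
replacement for proprietary maximum-entropy deconvolution: what is
guaranteed (and tested, against an independent brute-force charge-summation
scorer) is the contract — on a noiseless single species the dominant peak
centroid lands within 5 ppm of the true mass (in practice well below 0.1
ppm) and carries at least 90% of the output intensity — not the vendor's
internals.

One modelling subtlety: the published stage order smooths *before*
deconvolution, which widens the observed peaks beyond $\mu / R$. The
pipeline therefore builds its operator with the smoothing width added in
quadrature (`extra_fwhm`), so the model matches the spectrum it actually
inverts. Direct calls to `deconvolute()` default to the pure instrument
model.

**Peak picking.** Local maxima with apex intensity at or above the absolute
threshold (500) become peaks; each is centroided by the intensity-weighted
mean mass over a window of width mass$/6500$ (the peak resolving power)
centred on the apex, and maxima closer than one window to a taller apex are
merged into it. Peak intensity is apex height, matching the height-like
semantics of an absolute intensity threshold; this is a documented choice,
as is reading the published "data point spacing of 0.1 m/z" as the mass-grid
spacing of the deconvolution output.

## Clone merging

Per-slice peaks are merged into clones by greedy intensity-ordered
clustering at a relative tolerance of 50 ppm (Orbitrap-style merging uses 30
ppm with a 2 min maximum retention-time gap; both are configuration keys,
and the gap is unbounded by default because it is only defined for that
variant). The most intense unassigned peak seeds a clone, which absorbs the
most intense eligible peak until none remains; eligibility requires (a)
lying within the ppm tolerance of the running intensity-weighted mean mass,
also after the absorption for every existing member, which guarantees the
emitted clone is ppm-consistent, (b) lying within the retention-time gap of
the nearest member, and (c) coming from a slice not yet represented — two
masses resolved within one deconvoluted slice are distinct species by
construction. Ties in intensity break by lower mass, then lower slice
index, making the merge deterministic and independent of input order.

A clone reports the intensity-weighted mean mass of its members, the
retention time and intensity of its apex (most intense) slice — apex
aggregation is robust to how many slices a clone happens to span — and the
number of contributing slices. No minimum-slice filter is applied.

## Similarity scoring

Profiles are reduced to their 100 most intense clones, aligned by greedy
one-to-one nearest-mass matching within 1.5 Da (candidate pairs sorted by
ascending mass difference; ties by lower mass), with unmatched clones
contributing zero-partner entries, and scored by the cosine of the aligned
intensity vectors. Intensities enter as-is — no square-root, rank or floor
transformation. Self-similarity is 1; profiles sharing no clone within
tolerance score 0; an empty or all-zero side scores 0 by convention. The
cited scoring tradition bins spectra rather than matching peaks one-to-one;
one-to-one matching was chosen because it is symmetric and deterministic,
with identical tolerance semantics.

## The synthetic-run generator

Because donor serum raw data are not redistributable, every end-to-end test
runs on synthetic ground truth. `make_repertoire()` draws clones with
masses uniform over 45-52 kDa (optionally with a minimum pairwise gap),
elution centres uniform over a retention window, Gaussian elution peaks,
and log-uniform abundances. `render_run()` is the forward model of the
acquisition: for each clone, a truncated discrete Gaussian charge envelope
(centre 32, sd 4, bounds 22-42, the charge range observed for denatured
Fabs) places Gaussian peaks of FWHM $= \mu/R$ at $(m + z m_p)/z$, modulated
by the elution profile; a broad Gaussian baseline hump (centre 1500 Th,
FWHM 800 Th) and additive half-normal noise complete each scan. Average
(not monoisotopic) masses are used throughout: at ~48 kDa and $R \le 10^4$
isotopes are unresolved, so each charge state is a single Gaussian.

Defaults, chosen once as plausible study conditions and then left alone:

| parameter | default | rationale |
|---|---|---|
| elution window | 10-20 min | a desk-scale elution region inside the 10-50 min ROI |
| `rt_sigma` | 0.1 min | peaks a few slices wide, as in sliding-window processing |
| abundances | $10^6$-$10^8$, log-uniform | two orders of magnitude of clonal dynamic range |
| `noise_sigma` | 1000 | weakest-clone m/z-domain SNR ~100, well above threshold-limited detection |
| baseline amplitude | 2000 | an elevated but unresolved background |
| scan rate | 1 Hz | the acquisition rate of the profiled runs |

The abundance scale deserves a note: the pipeline's absolute intensity
threshold (500) lives in *deconvoluted* units, where a clone's intensity is
its envelope total divided by the number of modelled charges. The defaults
put the weakest clone's deconvoluted apex a few-fold above the threshold,
so — as in the real workflow — the threshold trims noise, not clones.

What the generator does *not* emulate: isotope fine structure, adducts,
chromatographic tailing, in-source fragmentation, ion mobility, and
intensity-dependent (shot) noise. Passing tests therefore demonstrate that
the pipeline inverts its own generative model accurately and behaves
lawfully (linearity, determinism, partition properties); they do not certify
vendor-level performance on real serum data.

`perturb_profile()` complements the renderer for statistical studies of
profile *comparison*: it emulates run-to-run variability directly at the
profile level (Gaussian mass jitter, log-normal intensity noise, small
random dropout), which makes hundred-trial similarity experiments feasible
in seconds where a hundred full renders would not be.

## Numerical choices and degenerate inputs

* Scans are resampled to one uniform grid before averaging (the vendor
  behaviour is unstated; profile-space averaging is assumed).
* The m/z range restriction (500-3000 Th) is applied at read time, before
  baseline subtraction.
* All-zero spectra deconvolute to all-zero mass spectra without iterating;
  non-finite intensities are rejected.
* Empty windows are skipped; an ROI containing no scans yields an empty
  profile and a warning, not an error.
* Retention times are minutes everywhere.
* Convergence tolerance $10^{-4}$ and the 100-iteration cap are exposed in
  the configuration; looser caps mainly sharpen already-resolved clusters.
* Ties are broken deterministically everywhere (documented per operation),
  so identical inputs give byte-identical clone tables.

## Problem sizes used in the shipped tests

The test suite exercises the full published configuration where the claim
depends on it (the three-Fab purity scenario on a 2 min acquisition; 20
single-species deconvolution fixtures; a 50-clone repertoire over a 6 min
elution window) and a narrowed configuration (46-48 kDa, 1000-2500 Th,
charges 22-42) for per-operation unit tests, where the physics is identical
but operator construction is a few hundred times cheaper. Similarity
statistics (100 seeded trials) run on `perturb_profile()` output. These
sizes are the package's choice of desk-scale study conditions; the
acceptance checks they support are described in the README.

## Known limitations

* The baseline and peak-picking stages are contract-matched, documented
  substitutes for vendor algorithms; parameter values carry over in spirit
  (and in name) but not bit-for-bit.
* Clone intensities are apex heights, not areas; workflows that need
  area-based quantitation should integrate the deconvoluted spectra.
* No cross-run alignment: clones are matched across samples only at scoring
  time, by mass tolerance.
* The uniform charge prior ignores any charge-state preference; strongly
  non-Gaussian envelopes would bias relative intensities, not masses.
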
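# fabprofiler

Clonal Fab repertoire profiling from intact-mass LC-MS runs.

Serum IgG1 antibodies are a clonal mixture: each B-cell clone contributes
one antibody species with a unique protein mass. After hinge-directed
digestion, the released Fab fragments (~46–51 kDa) can be profiled by
MS1-only LC-MS, where every clone appears as an electrospray charge-state
envelope riding on the chromatogram. `fabprofiler` converts such runs into
**clonal profiles** — tables of clones, each a unique (mass, retention
time) pair with an intensity — and compares repertoires across samples and
instrument platforms.

The pipeline, per sliding retention-time window (0.3 min wide, 0.05 min
overlap across a 10–50 min region of interest):

1. **average** the window's profile MS1 scans on a common m/z grid,
2. **subtract** the unresolved baseline (asymmetric least squares, stiffness
   set by a flatness parameter in (0, 1]),
3. **smooth** (Gaussian, FWHM 0.2 Th),
4. **deconvolute** to a zero-charge mass spectrum on a 45 000–52 000 Da grid
   (0.1 Da spacing) by multiplicative Richardson–Lucy updates
   `x ← x ⊙ Aᵀ(y/Ax) / Aᵀ1` under the charge-envelope forward model
   `m/z(z) = (M + z·1.007276)/z`, peak FWHM = (m/z)/10000, charges 12–60,
5. **pick** centroided mass peaks (resolving power 6500, absolute intensity
   threshold 500),

then **merge** the per-slice mass lists into clones at 50 ppm (clone mass =
intensity-weighted mean, retention time and intensity from the apex slice).
Profiles are compared by reducing each to its top 100 most intense clones,
greedily matching clone masses within 1.5 Da, and taking the cosine of the
aligned intensity vectors: 1 = identical repertoires, 0 = no shared clones.

A synthetic-run generator (`make_repertoire()`, `render_run()`) produces
mzML-serialisable runs with known ground truth — co-eluting 45–52 kDa
species with 22+–42+ charge envelopes, an elevated 1000–2000 Th baseline
hump, and additive noise — so the whole pipeline is testable at desk scale.

## Worked example

```r
library(fabprofiler)

cfg  <- fab_config(roi_start = 10, roi_end = 12)        # published settings, short ROI
rep3 <- make_repertoire(3, rt_window = c(10.2, 11.8),   # equimolar three-Fab mixture
                        abundance_range = c(1e8, 1e8),
                        min_gap_ppm = 500, seed = 11)
run  <- render_run(rep3, cfg, rt_range = c(10, 12), seed = 12)
prof <- profile_run(run, cfg)
tidy(prof)
#>   clone_id  mass_da rt_min intensity n_slices
#> 1        1 48574.26  11.65  94969.51        3
#> 2        2 46940.75  10.15  93445.15        2
#> 3        3 45003.62  10.40  87078.16        3

sort(rep3$true_mass)
#> 45003.63 46940.75 48574.26
```

The three simulated Fabs are recovered as exactly three clones — masses
match the simulated truth to well under a ppm, intensities are comparable
(the mixture is equimolar; residual spread reflects where each elution peak
falls relative to the window grid), and `n_slices` counts the sliding
windows in which each clone was seen. `write_clone_table()` saves the
profile as TSV with a manifest (`write_manifest()`) recording the
configuration hash; `cosine_score()` / `similarity_matrix()` compare
profiles, and `autoplot()` draws the repertoire stem plot or the similarity
heatmap.

A thin command-line front end with `simulate`, `profile` and `compare`
subcommands ships in `inst/cli/fabprofiler.R`.

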
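# stormreg

Channel registration for multi-color STORM/SMLM, operating directly on
localization tables.

Multi-color single-molecule localization microscopy is usually acquired one
channel at a time. Within-channel drift can be corrected with standard
tools, but the drift accumulating *between* sequential channel acquisitions
cannot — it leaves the channels misaligned by hundreds of nanometres to
micrometres, an order of magnitude above the ~20 nm resolution of the
technique. stormreg removes this inter-channel misalignment:

1. **Fiducial detection.** Fiducial beads (100 nm multi-color microspheres)
   emit constantly, unlike blinking fluorophores. Candidates seeded from
   the densest frame are scored by two per-frame neighborhood statistics
   over the *n* analyzed frames — the mean tolerance
   MT = (1/n) Σ<sub>f</sub> |N<sub>f</sub>| and the variance limit
   VL = (1/n) Σ<sub>f</sub> (|N<sub>f</sub>| − MT)², where N<sub>f</sub> is
   the set of frame-*f* localizations within strict distance *r* (the bead
   diameter, 100 nm) of the candidate. Beads pass MT ≥ 0.5 and VL ≤ 0.25;
   blinking structures fail one or the other.
2. **Rigid estimation.** Per moving channel, an Iterative Closest Point
   loop (nearest-neighbor matching, mean + 1 SD outlier trimming,
   closed-form SVD rigid fit, 1 nm convergence tolerance) estimates the
   rotation + translation mapping the moving landmarks onto the reference
   landmarks, initialized by a displacement-vector vote so large shifts do
   not mis-correspond.
3. **Application and evaluation.** The transform is applied to every
   localization (frames, intensities and order untouched) and written back
   as ThunderSTORM-dialect CSV. Quality is quantified by the Target
   Registration Error on annotated landmark pairs and the Normalized
   Cross-Correlation of rendered images, with a paired two-sided Wilcoxon
   signed-rank test on the before/after TRE.

A fiducial-free **cluster mode** registers recordings of multi-labeled
point-like targets (e.g. cargo-loaded lipid nanoparticles): the 25
localizations with the most neighbors within r<sub>c</sub> = 750 nm,
spread over distinct clusters, serve as landmarks instead.

The package is aimed at microscopists processing ThunderSTORM-style
localization exports; everything runs on plain data frames and is fully
scriptable (a YAML batch job runner and an `exec/stormreg` command-line
front-end are included).

## Worked example

Simulate a two-channel acquisition with 8 shared beads and a known
misalignment (0.008 rad, (900, −600) nm), then register:

```r
library(stormreg)

cfg <- simulation_config(n_frames = 1000, n_fiducials = 8, seed = 11,
                         fiducial_on_prob = 0.95, fiducial_jitter = 10)
truth <- rigid_transform(theta = 0.008, tx = 900, ty = -600)
ref <- simulate_channel(cfg, "642", seed = 11)
mov <- simulate_channel(cfg, "488", transform = truth,
                        fiducial_positions = ref$truth$fiducials, seed = 12)

detect_fiducials(ref$table, detection_params())
#> Landmark set: channel '642', 8 landmark(s)
#>           x          y    mt       vl support   source
#> 1  2588.146 31322.8178 0.959 0.039319     959 fiducial
#> 2  6152.842 14726.8395 0.953 0.044791     953 fiducial
#> 3 29783.889 27971.5923 0.952 0.045696     952 fiducial
#> ...

run <- register_channels(ref$table, mov$table)
run$channels[["488"]]$result
#> ICP registration: 3 iteration(s), converged, mean inlier distance 0.197 nm, 4 matched pair(s)
#> Rigid transform: theta = -0.00798933 rad, t = (-895, 606.8) nm

tre(mov$truth$fiducials_mapped, ref$truth$fiducials)           # before
#> TRE: 928.6 +/- 92.4 nm (mean +/- SD, n = 8)
tre(transform_points(run$channels[["488"]]$result$transform,
                     mov$truth$fiducials_mapped),
    ref$truth$fiducials)                                        # after
#> TRE: 0.2 +/- 0.1 nm (mean +/- SD, n = 8)
```

Each detected landmark reports its position (the centroid of its in-radius
localizations), MT, VL and support (total supporting localizations: here
~950 of 1000 frames, i.e. MT ≈ 0.95, and VL ≈ 0.05 ≪ 0.25). The recovered
transform is the inverse of the simulated misalignment to sub-nanometre
translation and ~10⁻⁵ rad accuracy, and the mean TRE at the true bead
positions drops from 929 nm to 0.2 nm. On real recordings, annotate
corresponding beads per channel, `snap_annotations()` them to the
localizations, and feed both sets to `tre()` / `paired_wilcoxon()`.

Batch processing mirrors the interactive flow: `run_jobs("jobs.yaml")`
executes a list of jobs (one reference + N moving channels each, optional
intensity/frame filters, fiducial or cluster mode, optional bead removal
via `remove_fiducials`), writing corrected CSVs plus a JSON transform
sidecar per channel, and isolating failures per job.

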
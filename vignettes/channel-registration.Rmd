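---
title: "Fiducial-based channel registration for multi-color SMLM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiducial-based channel registration for multi-color SMLM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stormreg)
```

## The problem

Multi-color STORM/SMLM recordings are usually acquired channel by channel:
tens of minutes per channel, with filter changes in between. Within-channel
drift can be corrected by cross-correlation or bead tracking, but the drift
that accumulates *between* the channel acquisitions survives those
corrections and misaligns the channels by hundreds of nanometres to
micrometres — an order of magnitude above the resolution the technique
otherwise delivers. stormreg removes this inter-channel misalignment by
registering the channels directly on the localization tables, never on
rendered images, so the full coordinate precision is retained.

The pipeline has three stages: landmark detection per channel, rigid
transform estimation per moving channel, and application of the transform to
every localization of that channel.

## Fiducial detection: mean tolerance and variance limit

Fiducial beads (100 nm multi-color TetraSpeck-type markers) differ from the
sample's fluorophores in one robust way: they do not blink. A bead yields
roughly one localization in nearly every frame at a fixed position, while a
dye blinks rarely, and a densely labeled structure produces a per-frame
localization count that fluctuates strongly.

Detection seeds one candidate per localization of the densest frame — a
frame in which every bead is guaranteed to appear. For a candidate $c$, let
$N_f$ be the set of localizations of frame $f$ within strict Euclidean
distance $r$ of $c$, over the $n$ analyzed frames. Two statistics decide:

$$\mathrm{MT} = \frac{1}{n}\sum_{f=1}^{n} |N_f|, \qquad
  \mathrm{VL} = \frac{1}{n}\sum_{f=1}^{n}\left(|N_f| - \mathrm{MT}\right)^2 .$$

A candidate is kept when $\mathrm{MT} \ge \mathrm{mt\_min}$ **and**
$\mathrm{VL} \le \mathrm{vl\_max}$. MT finds persistently emitting
neighborhoods; VL rejects the blinking ones, whose count variance is high.
Note VL is the *population* variance (divisor $n$), and frames with zero
nearby localizations count: a bead localized in half the frames has
$\mathrm{MT} = 0.5$, $\mathrm{VL} = 0.25$ — exactly the default thresholds,
which in practice separate beads from labeled structures well across imaging
conditions.

Parameters, units and defaults:

| parameter | default | meaning |
|---|---|---|
| `r` | 100 nm | neighborhood tolerance = fiducial diameter; strict $d < r$ |
| `mt_min` | 0.5 | bead must be localized in at least half the frames |
| `vl_max` | 0.25 | rejects fluctuating (blinking) neighborhoods |
| `frame_first`, `frame_last` | all frames | analysis window; see below |

Two refinements are deliberate design choices, since seeding one candidate
per localization means one physical bead spawns many passing candidates:

* **Deduplication.** Passing candidates within `r` of each other are merged,
  keeping the one with highest MT (ties: lowest VL, then lowest x). ICP
  needs one landmark per bead, not a clump of near-duplicates.
* **Centroid refinement.** The reported landmark is the centroid of all
  in-radius localizations pooled over the analyzed frames, not the raw seed
  coordinate. With $k$ supporting localizations of precision $\sigma$, the
  landmark position improves from $\sigma$ to roughly $\sigma/\sqrt{k}$ —
  on typical data, nanometre-scale.

Bead emission can bleach during the acquisition, especially in the bluer
channels. When late frames carry little bead signal, MT computed over the
full range drops below threshold; restricting detection to an early frame
window (`frame_first`/`frame_last`, which renormalizes $n$ to the window
length) restores it. The optimal window is sample- and channel-specific.

## Cluster mode

When no beads are present, multi-labeled point-like targets (for instance
cargo-loaded lipid nanoparticles imaged in both channels) produce dense
localization clusters that can serve as landmarks. Cluster mode skips MT/VL
entirely: for every localization the number of neighbors within `r_c`
(default 750 nm) is counted with all frames pooled, and the `k` = 25
highest-count localizations are retained.

Taken literally, the top 25 would all come from the single densest cluster,
which cannot anchor a rotation. By default stormreg therefore suppresses
candidates within `r_c` of an already selected, higher-ranked one, spreading
the landmarks across distinct physical clusters; `suppress = FALSE` restores
the literal behavior. A cluster-mode landmark is a raw localization, so its
position carries the cluster spread (tens of nm), not a $\sqrt{n}$-averaged
centroid — adequate, because ICP averages over landmarks.

## Rigid estimation by trimmed, vote-initialized ICP

Registration estimates, per moving channel, the rigid map
$p' = R(\theta)\,p + t$ (rotation about the coordinate origin, then
translation; $\det R = +1$, no reflection or scaling) that aligns the
moving landmarks with the reference landmarks. The Iterative Closest Point
loop alternates:

1. match each moving landmark to its nearest reference landmark;
2. discard outlier pairs (below);
3. fit the least-squares rigid transform on the inliers in closed form
   (centroid subtraction, SVD of the 2×2 cross-covariance with the
   reflection branch corrected);
4. accumulate the fit into the running transform.

Iteration stops when the mean inlier distance changes by less than
`convergence_tol` (default 1 nm) between consecutive iterations, or at
`max_iterations` (default 100, with a warning and `converged = FALSE`).

Two robustness choices required care, and are this package's own design:

* **Initialization by displacement voting.** Plain ICP starts from the
  identity, which works only while the misalignment is well below half the
  landmark spacing; beyond that the first nearest-neighbor matching pairs
  the wrong beads and the loop converges to a false optimum. stormreg
  instead estimates a starting translation as the mode of all pairwise
  displacement vectors (reference minus moving): each bead present in both
  channels votes once for the true translation, while unrelated pairs
  scatter over the field. The densest vote cluster (tolerance `vote_tol`,
  default 750 nm — chosen to exceed the displacement spread a field-scale
  rotation of a few hundredths of a radian causes) is averaged and used as
  the initial translation. `init = "identity"` remains available.
* **Trimmed outlier rejection.** Pairs with distance above
  $\text{mean} + \texttt{outlier\_sd}\cdot\text{SD}$ of the current pair
  distances are discarded each iteration. A single application of this rule
  fails when a substantial fraction of landmarks exists in only one channel
  (spurious detections, undetected beads): a compromise fit can homogenize
  the wrong-pair distances with the right ones, so nothing exceeds one SD
  and the loop settles on a biased transform. stormreg re-applies the rule
  on the surviving pairs until no pair is removed, with a floor of half the
  pairs, so contamination up to 50% cannot exhaust the inliers. On clean
  data the repeated rule reduces to the single-pass one within an iteration
  or two.

Convergence bookkeeping: the mean distance driving the stopping rule is
computed over the *inliers* of the current iteration, and outlier statistics
are recomputed every iteration from the current distances. On noiseless
input the recorded mean is non-increasing; with landmark noise, re-matching
can grow the inlier set and nudge the recorded mean up by less than the
convergence tolerance — which is then precisely what stops the loop.

The returned transform maps original moving coordinates into reference
space (rotations add, translations compose through the rotation; nothing is
re-fit from scratch), and `apply_transform()` maps every localization while
leaving frames, intensities and row order untouched.

Failure modes worth knowing: fewer than two landmarks per channel is an
error, as is an inlier set trimmed below two pairs; with all beads nearly
collinear the rotation is weakly constrained; and if the misalignment
exceeds both half the landmark spacing *and* the vote tolerance regime
(multi-micrometre shifts with very few, tightly clustered beads), no
landmark-based method can disambiguate correspondence.

## Quantifying the result

* **Target Registration Error** — the per-pair Euclidean distance between
  index-matched annotated landmarks across channels, summarized as
  mean ± SD (sample SD, divisor $n-1$, matching how such results are
  conventionally reported). Manual annotations are first snapped to the
  nearest localization of their channel (`snap_annotations()`), removing
  the click-precision component.
* **Normalized Cross-Correlation** — the Pearson correlation of pixel
  intensities of two rendered images,
  $\mathrm{NCC} = \sum_{ij}(I_{1,ij}-\bar I_1)(I_{2,ij}-\bar I_2) /
  (NM\sigma_1\sigma_2)$ with population $\sigma$; in $[-1,1]$ and invariant
  under affine intensity rescaling. Rendering (`render()`) deposits a
  unit-integral Gaussian per localization (default $\sigma$ = 20 nm, a
  typical localization uncertainty, used as a fixed width because
  per-localization uncertainties may be absent), truncated at $6\sigma$ so
  interior mass is conserved to better than $10^{-6}$; `sigma = 0` gives a
  histogram. Perfect NCC is unreachable on real two-color data even after
  perfect registration — competing labels and differing dye photophysics
  decorrelate the channels — so NCC is read as a relative
  before-versus-after score.
* **Paired two-sided Wilcoxon signed-rank test** (`paired_wilcoxon()`) on
  the before/after TRE distances, significance level 0.05.

## The synthetic-data generator

`simulate_channel()` generates what the registration problem depends on and
nothing more: stable fiducial emitters (per-frame Bernoulli emission with
probability `fiducial_on_prob` = 0.95, isotropic Gaussian localization
jitter `fiducial_jitter` = 10 nm), blinking structured signal (filaments as
Poisson blinks along a segment; clusters as Gaussian scatters), a known
rigid inter-channel transform, and log-normal intensities (bright beads,
dimmer blinks). Defaults emulate a common acquisition geometry: a 256-pixel
square field at 130 nm/pixel (33 280 nm) and 2000 frames of an
~30 000-frame acquisition. Beads are placed by Poisson-disc sampling
(minimum spacing 1000 nm = 10 bead diameters) so that test correspondences
are unambiguous by construction. `emulate_bleaching()` thins localizations
with retention $2^{-f/\text{half-life}}$ to model emission decay.

What is deliberately *not* modeled: dye photophysics (duty cycles, state
kinetics), camera noise, PSF-fitting bias, within-channel drift, chromatic
aberration (assumed corrected upstream), and axial structure. Passing tests
therefore demonstrate the geometric and statistical correctness of
detection, estimation and evaluation under realistic densities and noise —
they do not certify performance against photophysical artifacts real
recordings may add.

Test and acceptance runs shrink the frame count (typically 200–1000 frames,
300 for the 50-run transform-recovery study) because the MT/VL statistics
are per-frame normalized and hence scale-free in $n$; field size, bead
counts (5–20), jitter (0–30 nm) and misalignments (up to 2 µm translation,
0.02 rad rotation) stay at data scale.

## Numerical and convention choices

* All coordinates are nanometres throughout; no pixel↔nm conversion.
* Strict inequalities everywhere a radius is compared ($d < r$, $d < r_c$,
  removal $d <$ diameter); the intensity filter keeps values equal to its
  threshold (strictly-lower values are dropped).
* Frame restriction is inclusive on both ends and re-indexes frames to
  `1..(last-first+1)`, so the MT/VL denominator counts only analyzed frames.
* Densest-frame ties break to the lowest frame index; nearest-neighbor ties
  to the lowest row index — determinism over elegance.
* CSV export writes coordinates with ten decimal places, a fixed point of
  the write–read cycle (byte-identical on re-export).
* Fiducial removal interprets "within one fiducial diameter" as a removal
  radius equal to the full diameter (100 nm), not half of it.
* The fixed-radius neighbor search is a spatial-grid bucket index (cell
  side = the query radius, 3×3 block scan), equivalent to a KD-tree query
  and verified against brute force in the tests.

## Limitations

* Rigid transforms only — no affine, spline or per-frame drift models; 2D
  only.
* Landmark-starved or nearly collinear bead layouts limit rotational
  accuracy; the per-job log (landmark counts, iterations, final mean
  distance) is the user's trustworthiness check.
* Cluster mode assumes the clustered targets are co-localized across
  channels; targets present in one channel only act as spurious landmarks
  and consume outlier-rejection budget.
* TRE depends on annotation quality; snapping mitigates but cannot remove
  annotation bias, and beads spaced closer than the misalignment can snap
  ambiguously.
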
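---
title: "Quantifying membrane-label expansion microscopy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-label expansion microscopy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memquant)
```

# Scope

Dense amphiphilic membrane probes combined with ~4x hydrogel expansion make it
possible to image membranous ultrastructure — axons, dendrites, cilia, myelin —
on an ordinary confocal microscope. Validating such data raises a recurring set
of quantitative questions: what is the effective resolution, is the expansion
isotropic, how continuous is the membrane label along a structure, how strong
is the signal over background through a tissue volume, how well do
membrane-guided segmentations agree with an independent reference, and how much
extra resolution does fluctuation imaging buy. `memquant` implements each of
these quantifications as a tested, reusable function, together with a synthetic
phantom generator so that every stage can be exercised against known ground
truth without microscope data.

Throughout the package, physical lengths refer to the expanded gel in nm and
are reported in **biological units**: physical length divided by the linear
expansion factor. Coordinates are 0-based, pixel-centered, in `(z, y, x)`
order. For example a confocal axial resolution of ~500 nm corresponds, at 4x
expansion, to `to_bio_units(500, 4)` = 125 nm in the original tissue.

# The synthetic phantom

`phantom_spec()` / `make_tube_phantom()` rasterize tubes (membrane shells of
100–1500 nm diameter with a finite shell thickness) by signed distance to a
polyline centerline: a voxel at distance $d$ from the centerline belongs to the
shell when $|d - r| \le t/2$, antialiased by a linear falloff over one lateral
voxel; the optional lumen "fill" channel emulates a cytosolic marker. The
imaging model in `render_image()` is a separable anisotropic Gaussian PSF
(defaults: 250 nm lateral / 500 nm axial FWHM in *physical* units, the scale of
a high-NA confocal; dividing by the expansion factor gives the biological-unit
blur), photon scaling, Poisson shot noise, additive Gaussian read noise, and a
constant background. Rendering is bit-reproducible given `(spec, seed)`, and
`n_realizations = 2` produces the paired-acquisition design needed for
resolution analysis: identical signal, independent noise.

`insert_gaps()` carves labeling gaps of a known total fraction $g$ into each
path: interval lengths are drawn uniformly in $[\ell_{\min}, 3\ell_{\min}]$ and
placed by rejection sampling without overlap; the final interval is trimmed to
hit $gL$ exactly whenever the remainder is at least $\ell_{\min}$, so the truth
total overshoots by less than one minimum interval. `make_fluctuation_series()`
gives every shell voxel an independent two-state (Bernoulli) blinking time
course. `make_distorted_pair()` produces a pre-/post-expansion image pair: the
post image lives on the fine grid and is warped by a band-limited random
displacement field normalized to an exact RMS amplitude; the pre image is the
block-average downsampling by the (integer) expansion factor; bead-like puncta
serve as matched landmarks, mimicking the punctate organelle markers used for
distortion analysis in practice.

What the generator deliberately does *not* emulate: spatially varying
(neuropil) background — background is constant; optical aberrations beyond a
Gaussian PSF; membrane geometries beyond tubes (no vesicles, cristae, or
sheets); probe-density variation along a membrane. Passing tests on phantoms
therefore demonstrate correctness of the estimators under a known forward
model, not performance on tissue: real data add structured background and
non-Gaussian blur that can only degrade, for example, block-matching
registration or gap detection near the threshold.

# Resolution by Fourier ring correlation

`frc_curve()` computes, per integer-radius frequency ring,

$$\mathrm{FRC}(f) = \frac{\operatorname{Re}\sum_{k \in f} F_a(k)\,\overline{F_b(k)}}
{\sqrt{\sum_{k \in f} |F_a(k)|^2 \sum_{k \in f} |F_b(k)|^2}},$$

on two independent acquisitions of the same field. Numerical choices: each
image's mean is subtracted before apodization (otherwise the Hann window leaks
the large DC component into the lowest rings), the 2-D Hann window is on by
default, rings are one frequency sample wide, and values are clipped to
$[-1, 1]$. Frequencies are expressed in 1/nm of biological units, i.e. the
pixel size is normalized by the expansion factor, so the derived resolution
reads directly in original-tissue terms. `frc_resolution()` takes the fixed
threshold 1/7 — the standard fixed-threshold criterion in the FRC ecosystem —
and interpolates linearly between the rings bracketing the first downward
crossing; a curve that never crosses is reported at the Nyquist bound
$2 \cdot \text{pixel}$ and flagged `"limit"`, and a curve that starts below
threshold is a no-signal error rather than a number.

`blockwise_frc()` tiles the pair, gates tiles on content, and reports the
per-block map plus a single summary value. Two genuinely open choices are
declared here. First, "best value across blocks" is interpreted as the
*minimum* (finest) resolution among scored blocks; the per-block map is always
available for users who prefer a median. Second, block eligibility uses a
global Otsu threshold on the average of the two acquisitions, and a tile is
scored when at least `min_block_content` (default 0.2) of its pixels exceed
that threshold. An earlier candidate rule — background statistics from the
image's lowest-decile pixels — was rejected because under Poisson noise the
spread of a dim background exceeds the within-decile spread, so essentially
every pixel counts as "above background" and the gate never rejects a tile.
The Otsu gate requires bimodality, which is exactly what distinguishes a tile
with structure from one without. For sparse phantoms whose membrane occupies
only ~10–15% of a tile the gate should be lowered accordingly; the acceptance
analyses use 0.1 for such scenes.

`split_frames()` implements the odd/even split of a fluctuation series (e.g.
40 frames into two independent sets of 20) so that a single acquisition can
feed the two-input FRC after reconstruction.

# Expansion factor and distortion

`estimate_expansion_factor()` forms all $\binom{n}{2}$ inter-landmark
distances in the pre- and post-expansion images (physical units, anisotropic
pixel sizes respected) and reports the mean post/pre ratio with SD and a 95%
t-interval. Coincident pre-expansion landmarks are an error, not a dropped
pair.

The distortion pipeline follows the conventional two-stage design.
`register_rigid()` first brings the post image into pre coordinates (scaling
by $1/\text{factor}$, block-averaging when the factor is an integer to avoid
aliasing), then searches rotations on a ±10° grid in 0.25° steps with
translation per angle from phase correlation (3-point parabolic subpixel
refinement). Scoring uses normalized cross-correlation on mildly prefiltered
(σ = 0.75 px) images over the central region: without the prefilter, angles
whose resampling smooths the candidate image win spuriously. Failure to reach
a correlation of 0.2 is an explicit registration error.

`register_nonrigid()` estimates the residual smooth field by multiresolution
(2-level) local-NCC block matching on a regular node grid with parabolic
subpixel refinement; low-confidence nodes (NCC < 0.3 or structureless windows)
are filled from neighbors, the node lattice is lightly smoothed, and node
displacements are interpolated bilinearly to the full grid. The field is
expressed in biological nm and is trusted only over the matched node hull (the
registered overlap), which is what the returned mask marks. A B-spline
free-form deformation would be the other natural parameterization; local NCC
block matching with smooth interpolation optimizes the same local-correlation
objective with fewer moving parts, and its truth-field recovery is tested
directly on `make_distorted_pair()` phantoms. One caveat found during
development and worth keeping in mind for real data: along straight,
feature-poor membranes the along-structure displacement component is
unobservable (the aperture problem), so distortion fields should be estimated
on texture-rich channels (e.g. punctate organelle markers), which is also how
the measurement is done in practice.

Because the rigid stage absorbs rotation and mean translation,
`compose_rigid_nonrigid()` reassembles the total pre-to-post displacement for
comparison against a ground-truth field.

`rms_error_curve()` turns a displacement field into the standard isotropy
statistic: for each measurement length $L$ (default 10 log-spaced bins from
1 µm to half the masked extent, 1000 sampled point pairs per bin, seeded), the
error of a pair is $\bigl|\,\|p + u(p) - q - u(q)\| - L\,\bigr|$ and the bin
reports the RMS and SD. Shifts and rigid motions of the deformed frame leave
the curve invariant; a uniform relative misscaling $u(x) = \epsilon x$ gives
$\mathrm{rms}(L) = \epsilon L$ exactly, which the tests verify analytically.

# Membrane continuity and morphometry

`sample_path_intensity()` samples one channel by trilinear interpolation at
uniform arclength steps (default half the lateral biological pixel) along a
traced path; the profile's mean and SD — computed along that same path, not
over the image — are the reference statistics for gap detection.
`detect_gaps()` marks maximal runs of samples below
$\text{mean} - k\,\mathrm{SD}$ (default $k = 2$) whose extent exceeds the
minimum gap length (default 60 nm, tied to the effective image resolution;
callers should pass their own measured FRC value). Conventions that the
definition leaves open are fixed and recorded: run extent is measured from the
first to the last sub-threshold sample **plus one sampling step**; runs
interrupted by a single above-threshold sample are *not* merged (no
hysteresis); a zero-SD profile returns an empty gap set flagged degenerate
rather than an error. `percent_continuity()` is length-weighted:
$100\,(1 - \text{total gap length}/\text{path length})$, reported alongside
the raw gap count since "counting gaps" alone does not fix a denominator.

`transverse_profile()` samples an oriented box on a sub-pixel grid, averages
down the box's long axis, and normalizes the profile to its peak — the
standard presentation of a membrane cross-section, with twin wall peaks for a
tube. `diameter_from_profile()` takes the distance between the two wall peaks,
each refined by a 3-point parabolic fit; profiles with fewer than two maxima
(walls unresolved at the working resolution) raise an explicit
"unresolved-walls" error instead of returning a misleading width.

The continuity recovery study (tests and acceptance script) uses 20 seeded
cilium phantoms per gap fraction $g \in \{0, 0.02, 0.05, 0.10\}$, each a
20 µm tube at 25 nm biological pixels with gaps of at least 200 nm (~3 PSF
FWHM, so a gap is not erased by blur), and requires the mean measured
continuity to sit within 2 percentage points of $100(1-g)$.

# Signal-to-background depth profiles

`background_level()` is the pixel-weighted grand mean over one or more
empty-gel reference images; `sbr_depth_profile()` divides each XY plane's mean
over *all* pixels (no tissue mask, matching how such profiles are defined for
uniformity checks; a mask can be supplied upstream by cropping) by that single
scalar. Matched acquisition settings between signal and background images are
the caller's contract — the function records only the arithmetic. The
statistic is jointly scale-invariant and linear in the signal, and both laws
are property-tested.

# Segmentation and tracing agreement

`rand_score()` computes the pair-counting Rand index from label-contingency
sums in $O(\text{voxels} + \text{labels}^2)$ — never enumerating the
$\binom{n}{2}$ voxel pairs — and equals exhaustive enumeration on random
labelings by construction (a property the suite checks on 200 seeded cases).
With `foreground_restricted = TRUE` only voxels labeled foreground in the
designated ground truth enter the count, which is the headline variant when
one segmentation serves as reference. The adapted-Rand F-score used in
connectomics (harmonic mean of pair precision and recall,
$2\sum n_{ij}^2 / (\sum a_i^2 + \sum b_j^2)$) is available as
`variant = "adapted"` because the plain index and the adapted score answer
slightly different questions and published pipelines disagree on which is
meant; both are reported by the CLI. `trace_to_labels()` converts centroid
tracings into comparable label volumes by rasterizing each trace as a tube of
the annotation brush radius (default 4 px, i.e. brush size 8), with later
labels winning on overlap and the overlap fraction reported.

`colocalization_fraction()` thresholds the probe channel (Otsu by default, or
a fixed percentile) and returns the fraction of reference-marker pixels that
carry probe signal; it is monotone non-increasing in the threshold.

# Fluctuation reconstruction (simplified SACD)

`sacd_reconstruct()` implements a compact autocorrelation-cumulant
reconstruction: per-frame Richardson–Lucy deconvolution (`n1 = 10` iterations
with a Gaussian PSF, $\sigma = 0.21\,\lambda/\mathrm{NA}$ in pixels), Fourier
(sinc) upsampling by `fourier_scale = 2`, the per-pixel **lag-0 second-order
temporal cumulant** (the variance of the mean-subtracted time course —
well-defined for 20-frame series, whereas lag-1 estimates get noisy), clipping
of negative cumulant noise at 0, and a second Richardson–Lucy pass
(`n2 = 10`) with the PSF rescaled to the upsampled grid and narrowed by
$1/\sqrt{\text{order}}$, since the cumulant image's effective PSF is the
square of the optical one. The stage order (deconvolve at native grid, then
upsample) bounds cost and is fixed so runs are comparable. Fourier upsampling
splits the Nyquist bin symmetrically for even sizes, which keeps the padded
spectrum Hermitian and the output exactly real and mean-preserving;
Richardson–Lucy uses FFT (circular) convolutions, adequate for fields that do
not touch the frame edge. No contrast manipulation (e.g. CLAHE) enters the
quantitative path.

Two behavioral guarantees are tested rather than assumed: a temporally
constant series reconstructs to (numerically) zero, and on blinking two-point
emitters at 0.7 PSF FWHM separation the reconstruction shows two local maxima
where the frame average shows one. The resolution claim is tested end to end:
on seeded blinking tube phantoms, 40 frames are split odd/even, each half is
reconstructed, and the FRC resolution of the reconstruction pair must beat the
FRC resolution of the frame-average pair in at least 4 of 5 seeds.

# Problem sizes and runtime

The test and acceptance workloads are sized for a desk run: 2-D phantom planes
of 64–256 px, 20 phantoms per continuity condition, 200 random labelings for
the Rand cross-check, 200-frame two-emitter series, and 5 seeds for the SACD
resolution comparison. These sizes give stable statistics for every check
while keeping the full suite under a minute; all of them scale up linearly if
finer sampling is wanted.

# Known limitations

* Resolution is per-plane (ring correlation); no 3-D Fourier shell variant.
* The deformation model is 2-D, matching the planar reference images used for
  distortion analysis; volumetric distortion is out of scope.
* Temporal cumulants are implemented at order 2 only; higher orders would need
  balancing to be usable and are an explicit extension point.
* The ImageJ `.roi` reader covers line/polyline/freeline types (integer or
  sub-pixel coordinates); the canonical annotation format is the documented
  JSON polyline schema.
* Whether quantification should run on raw or deconvolved stacks is a data
  decision, not a package one: every analysis consumes the stack it is given
  and the provenance belongs in the caller's records.
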
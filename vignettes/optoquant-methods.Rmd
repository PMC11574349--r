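---
title: "Quantifying optogenetic perturbations of a nuclear morphogen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying optogenetic perturbations of a nuclear morphogen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoquant)
```

## The scientific setting

During early *Drosophila* embryogenesis the transcription factor Dorsal (DL)
forms a nuclear concentration gradient along the dorsal-ventral (DV) axis.
High-threshold target genes such as *snail* (*sna*) are expressed ventrally
where nuclear DL is highest; low-threshold targets such as *short
gastrulation* (*sog*) are expressed more laterally. Two optogenetic tags make
it possible to perturb nuclear DL acutely under blue light: a light-exposed
nuclear export sequence (LEXY-type) drives DL out of the nucleus reversibly,
while a light-uncaged degron (BLID-type) destroys it irreversibly.

`optoquant` implements the complete quantification chain for such
experiments: detection and counting of MS2/MCP transcription-site foci in
time-lapse movies; nuclei segmentation, tracking and mean-intensity traces;
single-exponential recovery fits for FRAP and for nuclear re-import after
light-off; convex-hull expression areas; Gaussian fits of the DV gradient
in fixed cross-sections; arc-length domain widths; and the accompanying
statistics. Because the original microscopy data are not redistributable,
the package ships a synthetic-embryo generator that emulates each
acquisition regime with exact ground truth, and the entire test suite runs
against it.

## The synthetic embryo generator

`simConfig()` describes an acquisition. Defaults mirror the live-imaging
regime: 512 x 512 px frames at 0.29 um/px, one frame per ~25 s;
`frapConfig()` switches to the high-zoom FRAP regime (0.100 um/px, one frame
per 2 s). Nuclei are rendered as soft-edged disks (error-function edge,
width 0.5 px) on a hexagonal lattice with positional jitter (s.d. 10% of
the spacing); the soft edge exists so that edge-based segmentation behaves
realistically rather than trivially. Nuclear levels follow a DV Gaussian
profile `offset + amplitude * exp(-(dv - peak)^2 / (2 sigma^2))`.

### The nuclear-level model

`nuclearLevelModel()` is the piecewise closed form that drives every movie:

* **none** — constant baseline.
* **export** — during light the nuclear level decays exponentially at the
  export rate toward a floor of 10% of baseline (nuclear signal never
  reaches zero in export experiments; the floor is configurable). After
  light-off it recovers as `I(t) = I_ss - alpha * exp(-beta * t)` with
  `I_ss` equal to the pre-light baseline and `alpha` fixed by continuity.
  Cytoplasmic signal rises so that total embryo signal is conserved.
* **degrade** — both compartments decay exponentially during light and for
  a short delay after light-off (default 2 frames, encoding the observed
  lag in switching degradation off), then hold with no recovery.

The functional form of export *during* light is a modelling decision: only
the recovery is ever fitted in the analysis chain, and an exponential
approach to a floor is the simplest shape consistent with the imaging
phenomenology. It is flagged as such here and configurable.

### Transcription foci

Each nucleus inside the configured gene domain (a set of DV intervals;
`snaDomain()` is a single ventral band, `sogDomain()` two lateral stripes)
is active with probability 0.9 and carries one diffraction-limited Gaussian
spot (sigma 0.35 um) at a fixed intranuclear offset, uniform within half
the nuclear radius. During perturbations a spot switches off two frames
after its nucleus's simulated level falls below an absolute activation
threshold (50% of the peak nuclear level by default, so dimmer, more dorsal
nuclei cross it earlier and domain boundaries retract), and back
on (export only) when the level recovers; threshold and delay are
simulation parameters with no claimed mechanistic content — the underlying
biology is a phenomenological on/off observation.

### What the generator does not emulate

No optical PSF beyond the isotropic Gaussian spot, no z-dimension, no
photobleaching outside the FRAP ROI, no nuclear divisions, no
embryo-to-embryo variability in staging. Passing tests therefore
demonstrate correctness of the quantification algorithms under controlled
conditions, not robustness to every artefact of real microscopy.

## Focus detection

`detectFociFrame()` follows a two-threshold scheme: a small median filter
(3 px) removes salt-and-pepper pixels; a large median filter (51 px,
much larger than a spot) estimates background, which is subtracted; a
Gaussian blur (sigma 1 px) suppresses residual noise; the result is
thresholded at the *low* threshold; 1-px objects, border-touching objects
and objects whose centroid falls outside the embryo mask are dropped; and a
second pass keeps only objects containing at least one **raw** pixel above
the *high* threshold. The low pass finds everything including noise, the
high pass removes the noise — an object must be found by both. The second
threshold is applied to the unprocessed image; the overlap rule (at least
one raw pixel above threshold inside the pass-1 object) is the simplest
monotone correspondence.

Nuclear background rises over nc14, so the low threshold can increase
logarithmically from the nc14 start frame:
`thr(f) = thrLow * (1 + coeff * log(1 + (f - start) / n))`. The coefficient
is user-set (0 disables it); the multiplicative-log form is this package's
definition of "increases logarithmically" and is recorded in output
metadata via the run log.

The embryo mask comes from a temporal max projection, Gaussian blur,
threshold (Otsu's value halved by default, so the cut lands between dark
background and dim cytoplasm rather than between cytoplasm and bright
nuclei), morphological closing, discarding of components below 100 px and
keeping the largest — exactly one object, the embryo.

Default thresholds (500 a.u. low on the processed image, 2000 a.u. high on
the raw image) were chosen for the default synthetic movie's intensity
scale, the analogue of the empirical per-imaging-condition threshold choice
any user of such a pipeline must make; comparable conditions must be
analysed with identical thresholds.

Counting is instantaneous (not cumulative); `countSeries()` divides by the
starting count to normalize per embryo before cross-embryo averaging.

## Expression area

`deltaArea()` pools detected centroids over an nc13 window and an early-nc14
window, removes outliers per axis at two unscaled median absolute
deviations from the median (strict inequality; an axis with zero MAD
removes nothing), takes the convex-hull area of what remains, and reports
area(nc14) − area(nc13). Subtracting the nc13 area controls for embryo
orientation and field placement. The MAD rule is deliberately conservative:
it discards isolated, transient detections that were likely noise.
Duplicate centroids from persistent foci are *not* de-duplicated before
filtering — the hull is insensitive to duplicates but the MAD is not, and
the pooled-concatenation convention is retained. The per-axis (rather than
Euclidean-distance) MAD rule is this package's reading of a 2-D MAD filter;
it is monotone in each coordinate and configurable in principle via the
exported `madFilter()`.

## Nuclei segmentation and tracking

Nuclei are segmented by a Laplacian-of-Gaussian at sigma 4 px (population
view) or 10 px (high zoom). The implementation thresholds the LoG response
at −0.5 standard deviations of the response, which selects the interior of
the zero-crossing ring that classical edge detection would trace, then
fills holes, opens morphologically at the LoG scale (removing thin
edge-bands such as the embryo outline), splits touching nuclei by watershed
on the distance map, and gates object sizes to [0.25, 4] x the median area
of the first frame (the gate is frozen there so it cannot drift with
intensity). A frame yielding zero objects reuses the previous frame's
labels with intensities re-measured on the current frame — this
carry-forward covers the frames lost when the blue light switches.

The embryo outline is fitted from the temporal *mean* projection (robust to
noise extremes, unlike a max projection over a hundred frames): blur,
normalize to [0, 1], threshold at 0.005, open/close, and a direct
least-squares conic fit to the boundary of the largest component. The
midline is the major-axis line of that ellipse; analyses keep nuclei whose
centroid lies within 100 px of it (inclusive), measured as signed
perpendicular distance.

`linkTracks()` matches objects between consecutive frames greedily by
ascending centroid distance with cutoff equal to the nuclear radius
(median `sqrt(area/pi)` of the first frame); ties resolve to the lower
track id by stable ordering. Unmatched detections then search open track
heads up to 10 time points back (gap closing from the last known centroid,
with no motion extrapolation). Tracks missing *any* of the first ten
frames, *any* of the last ten, or covering fewer than half of all frames
are removed — the stricter "any" reading of the first/last-ten rule is
used (configurable), guaranteeing the recovery fits downstream have
anchored baselines. Divisions are not tracked; the analysis operates within
single interphases.

## Recovery kinetics

`fitSingleExponential()` fits `I(t) = I_ss - alpha * exp(-beta * (t - t0))`
by Levenberg-Marquardt least squares with an analytic Jacobian, bounds
`I_ss, alpha, beta >= 0`, parameter/function tolerances of 1e-12 and at
most 1000 iterations. `t0` is the first window point: the first post-bleach
frame for FRAP, the light-off frame for re-import fits — the model's time
origin is made explicit here. Initialization: `I_ss` from the mean of the
final 10% of the window, `alpha` from the first window value (floored at
0), `beta = 2 / window duration`. Fits are unweighted. A window whose
variance is below `1e-12 * mean^2` is rejected as flat (beta is
unidentifiable); non-convergence is reported, not hidden. Beta is always
reported in 1/min: fitting against time in seconds simply divides beta by
60, and the tests pin that exactness.

FRAP analysis tracks the nucleus nearest the bleach-ROI centre at the first
frame. When segmentation fails mid-movie — immediately after the bleach the
nucleus is *dimmer than the cytoplasm* and edge-based segmentation cannot
see it — the trace is measured over the nucleus's last known pixel mask on
the current frame, which preserves the early recovery points that anchor
beta. Fitting uses only the recovery period, from the first post-bleach
frame. No attempt is made to decompose beta into separate import and export
rate constants.

`compareRates()` applies the pooled-variance two-sided unpaired t-test.
Pooled (Student) rather than Welch variance is a deliberate choice: with
three recovery rates per condition the pooled test is the standard
small-sample comparison, and the package's worked example
(`ttestPooled(c(0.23, 0.25, 0.17), c(0.84, 0.80, 1.14))`) yields
p = 0.003, whereas the unequal-variance form would give a much larger
value.

## Fixed-image geometry

`dvProfile()` bins mean intensity of the peripheral band (elliptical radius
0.75-1.05) by normalized angular position, with 0 at the ventral-most
point. `fitGaussianGradient()` fits `A exp(-(x - mu)^2 / (2 sigma^2)) + B`
after rotating the circular profile so its empirical maximum sits at 0.5,
avoiding wrap bias at the ventral point; `mu` is mapped back afterwards.
The additive offset `B` absorbs background staining. Note that when the
profile is measured from rendered images, `A` is the *profile* amplitude —
the generator's nuclear amplitude scaled by the fraction of the band that
nuclei occupy — so image-level tests check the shape parameters (`mu`,
`sigma`) and profile-level tests check all four.

`segmentNuclearRings()` applies the LoG at sigma 20 px (the scale of the
ring of peripheral nuclei), closes the per-nucleus responses into an
annulus, and takes the two largest filled objects — the filled outer disk
and the enclosed interior. An ellipse is fitted to each boundary by the
direct least-squares conic method and the mid ellipse is the parameter-wise
average (orientations averaged on the doubled angle). A bright enclosed
interior is rejected: that is a solid object, not a ring.

`ellipseArcLength()` integrates `sqrt(a^2 sin^2 t + b^2 cos^2 t)` by
adaptive quadrature to ~1e-9 relative accuracy; the circle closed form and
additivity are pinned in the tests, as is the a = 2, b = 1 perimeter
9.688448. `domainWidths()` thresholds an expression channel, keeps
components at least 25% the area of the largest (background removal; the
cutoff is this package's choice), samples the mid ellipse at 4096 angles
(~0.09 degrees), converts maximal angular runs inside the mask to arc
lengths with crossing angles at the midpoint between the last-outside and
first-inside samples, and normalizes by the perimeter. Patterns with two
domains report both widths; pooling across domains happens downstream when
averaging. Areas and widths are reported in pixel units and dimensionless
fractions respectively; like-for-like acquisitions compare directly, and
physical conversion is a multiplication by the pixel size the caller can
apply.

## Statistics

`ttestPooled()` (Student, pooled variance, df = n_a + n_b − 2) handles
degenerate zero-variance input explicitly. `anovaTukey()` wraps `aov()` and
`TukeyHSD()`; at k = 2 the Tukey-adjusted p equals the pooled t-test p, a
known identity the tests verify to 1e-9. `sampleSizeTwoT()` searches for
the smallest per-group n whose exact noncentral-t power (noncentrality
`|mu0 - mu1|/sd * sqrt(n/2)`, df = 2n − 2) reaches the target; both means
must be supplied, since a single predicted mean does not define an effect
size. `makima()` implements modified Akima cubic Hermite interpolation
(slope weights `|d2 - d1| + |d2 + d1|/2`), which does not overshoot on
step-like data the way natural cubic splines do; `akimaAverage()` resamples
several embryos' series onto a common grid restricted to the interval all
series cover (step: median frame interval) and reports mean and s.e.m.

## Conventions and problem sizes

All coordinates are 1-based `(y, x)` row/column pixel indices, the R
convention; stacks are Y x X x T arrays written as one 16-bit TIFF page per
frame with a YAML sidecar for pixel size and frame interval. Centroids are
unweighted pixel means. "Border objects" touch the image border, not the
embryo boundary.

The test and acceptance simulations use a 256 x 256 px field (a cropped
trunk field of view at the standard 0.29 um/px and 25 s/frame) with ~60
nuclei in the sna-like domain at spot SNR 10, a 192 x 192 px field for
tracking and FRAP studies, and 384 x 384 px fixed cross-sections; these
sizes preserve the packing, SNR and kinetic regimes of the acquisitions
while keeping the suite practical to run routinely. Trace-level
parameter-recovery studies use the published FRAP amplitudes, 2 s sampling
over 19 min, and read noise of 100 a.u.

## Known limitations

* Segmentation accuracy degrades for nuclei at the extreme gradient tails
  (contrast approaches the cytoplasm level) and within ~1 nuclear radius of
  the embryo boundary; the midline band and track filters remove most such
  objects in practice.
* Two transcription sites closer than ~2 spot diameters merge into one
  detection; counts are correspondingly conservative in dense domains.
* The exponential-to-floor export model and the spot on/off threshold rule
  are phenomenological; only the recovery branch of the model is ever
  fitted against data.
* `anovaTukey()` assumes balanced-ish small groups as used here; no effort
  is made to generalize to unbalanced designs beyond what `TukeyHSD()`
  provides.
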
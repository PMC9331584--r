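---
title: "Quantifying maize ear organization from multi-view grain masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying maize ear organization from multi-view grain masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earmetrics)
```

## The measurement problem

A maize ear is a cylinder-like inflorescence whose grains are organized as a
lattice: rings of synchronously initiated ovaries (*cohorts*) stacked from
the base to the apex, crossed by vertical files (*rows*). Because cohorts are
initiated sequentially and fertilized in the order of silk emergence, the
spatial pattern of set versus aborted grains records the plant's history
around flowering: abiotic stress at flowering aborts the youngest, apical
cohorts first, then basal ones, while pollination failure leaves erratic,
scattered patterns. Standard yield components (grain number, grain size) are
therefore only part of the picture; the *distribution* of grain presence and
grain dimensions along and around the ear is the trait of interest.

`earmetrics` computes these spatial traits from per-view raster masks of
ears imaged while rotating on motorized rollers: a binary ear silhouette and
a labeled grain instance mask per view (typically six views per ear). The
package deliberately takes label masks as its contract input — any instance
segmenter can produce them — and provides a simple watershed baseline
(`segment_grains()`) so the chain also runs from photographic-style
pseudo-RGB and infrared renders.

## Acquisition geometry

An ear of diameter $d$ resting on rollers of diameter $d_r$ turns by
$\alpha_{ear} = \alpha_{roller} \, d_r / d$ degrees when the rollers turn by
$\alpha_{roller}$ (no-slip rolling contact). With $n$ views, each capturing
a fixed arc $w$ of the circumference, the cumulative coverage is the measure
of the union of $n$ arcs of width $w$ centred at $k \alpha_{ear}$,
$k = 0, \dots, n-1$, reduced modulo 360°. `circumference_coverage()`
evaluates this union analytically by interval merging — exact, with no
discretization artifact — and `coverage_map()` tabulates it over grids of
step angles and diameters. Under the production settings (5.2 cm rollers,
58° steps, six 120° views) coverage is 100% for every ear diameter between
2 and 6 cm, which is what makes the per-view traits averageable into
ear-scale traits. The first image is taken before any rotation, and
coverage is invariant to a global rotation offset, so this convention is
innocuous.

## From masks to traits

**Ear morphometry.** The silhouette is reduced to one centre point per
raster row (midpoint of the outermost contour pixels); ear length is the
Euclidean path length along these centres, which follows bowed ears instead
of under-reporting them, and the per-row contour distance gives the diameter
profile. One numerical choice matters here: raw row midpoints inherit
half-pixel quantization jitter from the rasterized contour, and every
spurious half-pixel lateral flip adds $\sqrt{1.25}-1 \approx 0.118$ px of
path — a bias that does *not* vanish with resolution and reaches 1–3% on
tapered or bowed silhouettes. `central_axis()` therefore denoises the centre
sequence with a short (5-row) truncated running mean before integration; a
straight ear is unaffected and the raw midpoints are kept alongside.

**Grain geometry.** Each labeled region yields a barycentre and an
axis-aligned bounding rectangle (axis-aligned, because height and width are
defined relative to the vertical ear axis after orientation). Widths
measured horizontally on the image are chords of the ear's circular
cross-section, so they shrink towards the limb. `arc_correct()` projects the
chord back onto the circle: for signed offsets $x_1, x_2$ from the
centreline and section radius $R$, the arc is
$R\,|\arcsin(x_2/R) - \arcsin(x_1/R)|$, with offsets beyond the limb clamped
to $R$ and flagged. Offsets are measured from the central axis *at the
grain's barycentre row*, so bowed ears are handled without a global
centreline. The signed-offset formulation is the only one consistent for
grains straddling the centreline.

**Cohorts and grain counts.** Cohort membership is assigned bottom-up: the
lowest unassigned barycentre seeds a cohort that absorbs every grain within
half the mean grain width above it (ties inclusive), and the scan repeats.
Two one-dimensional reductions then summarize the lattice: collapsing each
grain to a one-pixel horizontal segment and counting crossings per column
gives the cohort-count profile, whose maximum estimates the number of
cohorts visible in a view (cohorts are incomplete at the limb, so the
maximum, not the mean, is the per-view count); collapsing to one-pixel
vertical segments gives, per row $i$, the mean arc-corrected gap $Dist_i$
between neighbouring grains and the estimate
$\pi \cdot Diameter_i / Dist_i$ of grains per cohort — the ratio of the
section perimeter to the typical spacing, which extrapolates the visible arc
to the full circle. The wrap-around gap is excluded from the mean; the ratio
itself supplies the full-circle extrapolation.

The per-ear grain number averages two composite indicators per view: an
*over-estimator* (mean grains-per-cohort over the median third of ear rows,
times the maximum cohort count) and an *under-estimator* combining the
grains-per-cohort and cohort counts of each third (basal, median, apical) of
the ear. Two readings of the under-estimator are implemented.
`"zonal_max"` (default) multiplies each zone's mean grains-per-cohort by the
zone's maximum crossing count: on a perfect fully set lattice both
indicators then equal cohorts × grains-per-cohort, and the composite is
asymptotically unbiased. `"zonal_mean"` uses the mean per-column crossing
count over the columns a zone's grains span; it discounts incomplete limb
coverage by roughly the circumferential fill factor (~0.85) and is therefore
a strict under-estimate — useful as a conservative bound, and the reading
under which "over ≥ under" holds on every view.

**Abortion profiling.** The grain-set ratio (GSR) at each one-pixel ear
section is the ratio of grain pixels to silhouette-diameter pixels, smoothed
by a running mean over 2% of the ear rows (truncated, not reflected, at the
ends — no data are invented beyond the ear). The fertile zone is the
envelope from the first to the last row with smoothed GSR strictly above
50%; interior dips remain inside it, matching the single
fertile-zone-between-aborted-zones summary used downstream. When no row
exceeds the threshold the fertile length is 0 and each aborted zone takes
half the ear length, exactly. Zone lengths are computed per view and
averaged (the alternative — segmenting the side-averaged profile — is
available by composing the building blocks).

**Profile clustering.** Smoothed profiles are interpolated onto 100 relative
positions on $[0,1]$ (positions divided by ear length), averaged over the
views of each ear, and clustered on Euclidean distances with Ward linkage
(`ward.D2`; k-means with a fixed seed is the alternative backend). Because
backend labels are arbitrary, clusters are relabelled by decreasing mean
profile integral, so cluster 1 is always the least aborted. Per-cluster
summaries report treatment composition (normalized within treatment), mean
ear length, and a one-way ANOVA of ear length across clusters.

## The synthetic ear generator

`generate_ear()` renders a parametric ear so every stage above can be tested
against known answers. Grains sit on a cylinder at angles $2\pi j/K$ and
cohort heights, with a diameter profile (cylinder, tapered, or barrel), an
optional sinusoidal centreline bow, and a small vertical position jitter
(default 0.02 cm). Views are orthographic: a grain at angular distance
$\Delta\theta$ from the view direction appears at offset
$R\sin\Delta\theta$ from the centreline with width foreshortened by
$\cos\Delta\theta$; only grains with $|\Delta\theta|$ below half the view
arc are rendered. This matches the arc-correction model exactly, which is
what makes that correction testable. Instances are drawn as filled ellipses
with a one-pixel background gap enforced between neighbours (label masks are
the contract input; segmentation difficulty is the baseline's concern), and
footprints are inset accordingly, so rendered bounding boxes under-read
nominal grain size by about one pixel.

Abortion models: `none`, `apical`, `apical_basal`, `full` (barren), and
`scattered` (independent per-grain set probability with positional jitter).
Soft zone edges use a logistic set-probability transition whose 10–90% span
covers `edge_cohorts` cohorts (default 2), mimicking the developmental
gradient of stress-induced abortion; the quantitative shape of the real
gradient is not established, so this is a modelling choice, kept explicit
and adjustable. Five archetypes of increasing severity (fully set; apical;
apical+basal; wide apical+basal; barren) have fertile fractions 1.00, 0.70,
0.60, 0.40, 0.00 of ear length. `archetype_panel()` draws reproducible
multi-ear panels spanning realistic ranges (length 8–16 cm, diameter 3–5 cm,
18–30 cohorts, 10–16 grains per cohort, bow up to 0.3 cm), optionally tying
ear length to archetype severity (12 down to 8 cm, 0.3 cm noise) to emulate
stressed plants.

The ground truth records every grain's cohort, file, angle, height and set
flag, the true centreline arc length, diameter profile, zone extents, and a
per-row *expected* GSR computed from the continuous footprint geometry
(the expected pixel count of an interval of length $\ell$ is $\ell$), so the
raster-measured profile can be checked against an analytic reference rather
than against itself.

**What the generator does not emulate** — and hence what green tests do not
show about real images: segmentation errors (merged, split, or missed
grains), husk or silk debris, fungus, perspective and lens distortion,
lighting gradients, grain shape variability within an ear, and the true
biological abortion gradient. Results on the synthetic material validate the
*measurement* chain downstream of instance masks, not any segmenter.

## Numerical and resolution choices

- Default raster resolution is 20 px/cm; at that scale a grain
  foreshortened to 45° is ~10 px wide, so single-pixel rasterization effects
  are ~10% of such a grain's width. Geometric recovery checks (width within
  5%, angular position within 2°) are therefore asserted at 40 px/cm, where
  rasterization is subordinate to the geometry being tested.
- The arc correction clamps offsets to the limb and warns once per call
  site; grains within 2% of the limb are flagged `near_limb`.
- Smoothing windows are truncated at profile ends; a window of one row is
  the identity.
- The zone threshold comparison is strict (`> 0.5`), and the degenerate
  barren-ear rule is applied verbatim.
- With the default two-cohort soft abortion edge, the strict 50% crossing
  sits about half a transition width basal of the nominal boundary (the
  rendered GSR ceiling is ~0.75 under 120° visibility, so the crossing
  happens where the *set fraction* is ~0.67, not 0.50). Sharp-edged ears
  recover nominal zone extents within 2%; soft-edged ears within half the
  transition width. This is a property of thresholding soft gradients, not
  of the implementation.
- All randomness is seeded: the generator is a pure function of its spec,
  k-means uses a fixed seed, and two pipeline runs with identical
  configuration are byte-identical (run logs echo analysis parameters, not
  paths or timestamps).

## Validation problem sizes

The packaged tests validate ground-truth recovery on a 50-ear panel spanning
archetypes 1–4 (ear length within 2%, maximum diameter within 2 px, exact
cohort counts for fully set ears, grain number within 10% with $R^2 > 0.95$
against truth) and planted-archetype recovery by Ward clustering on a
50-ear, five-archetype panel with 0.05-SD profile noise (chance-adjusted
agreement ≥ 0.9, ear-length ANOVA p < 0.001). These sizes keep the full
suite under a minute while leaving the statistics well away from
small-sample artifacts.

## Known limitations

- Grain *height* under-reads the nominal lattice value by the enforced
  instance gap (~1 px); at the default resolution this is ~10% of a
  0.45 cm grain. Dimensions are reported as measured on the mask.
- The grains-per-cohort estimate is undefined on rows crossed by fewer than
  two vertical segments, and rows at cohort-band edges (where only part of
  a cohort's boxes reach) carry noisy low estimates; the median-third mean
  absorbs most, but not all, of this.
- Scattered ears violate the lattice assumptions by design; cohort counts
  and grain numbers remain defined but are best interpreted through the
  GSR profile, as for real scattered ears.
- Pixel-to-cm calibration is a required input (`pixel_scale`); nothing in
  the rasters encodes it.
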
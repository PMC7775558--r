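---
title: "Methods: coordinate-based synapse morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coordinate-based synapse morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmorph)
```

## The measurement problem

Synaptic ultrastructure is quantified from electron micrographs of 30–70 nm
sections, each showing one synaptic profile. Three families of parameters are
measured per profile: sizes of membrane-bound structures (vesicle diameters,
endosome areas), their numbers, and their minimum distances to reference
membranes — the plasma membrane, the active zone (the presynaptic release
site), and, where visible, the dense projection. Because synaptic vesicles
are only 30–50 nm across and docking involves nanometre-scale movements,
measurements are derived from annotated x,y-coordinates rather than read off
each image: once the contours and vesicle circles are recorded, every metric
is computed, re-computed, and extended *post hoc* from the coordinates.

`synmorph` consumes the tab-separated per-image annotation files exported by
ImageJ/Fiji tracing macros (one line per structure: tool number, structure
name, length/area, x list, y list, vesicle radius), validates them, and
computes the morphometry. It never touches image pixels.

## Units and coordinates

Annotation files store ImageJ pixel coordinates: origin top-left, y
increasing downward, 0-based. The nm-per-pixel scale is supplied at analysis
time and applied **exactly once**, at load; all geometry thereafter is in nm.
The y-orientation is irrelevant to Euclidean distances; it only matters for
3D export, where the y-axis is negated so rendered models are right-handed
(stated in the OBJ header).

## Distances: segment projection, not vertex sampling

The central primitive is the minimum distance from a point to a traced
membrane. The trace is a polyline; `synmorph` projects the point
perpendicularly onto every segment (clamped to segment ends) and takes the
minimum, i.e. the trace is treated as a continuous curve. This removes any
dependence on how densely the annotator traced: a vertex-only distance is
always an upper bound and is offered behind `vertex_only = TRUE` solely for
cross-validation against legacy outputs. Correctness is checked against a
brute-force oracle that resamples the polyline at 0.01 nm spacing; the two
agree within 0.01 nm over hundreds of random configurations.

Vesicle distances are **edge** distances: centre-to-trace minus the radius,
floored at zero. The floor matters: tracing has finite thickness, so a
vesicle drawn slightly overlapping the membrane would otherwise read as a
negative distance. An edge distance of exactly 0 defines geometric docking;
the docking tolerance is configurable (`docking_tol`, default 0 nm after
flooring). For irregular closed organelles (endosomes, multivesicular
bodies) the organelle-to-membrane distance is the minimum over all segment
pairs, which for non-crossing segments is always attained at a vertex of one
of the two traces — so the computation reduces to two directed
vertex-to-segment passes after an intersection test, and is exact, not
sampled.

## Vesicle pools

With threshold T (default 30 nm, roughly two vesicle rows, the conventional
readily-releasable-pool proxy; configurable as in the original
implementation):

* **docked** — edge distance 0 to the plasma membrane, or annotated docked;
* **active zone** — within T of the plasma membrane and within T of an
  active zone;
* **periactive** — within T of the plasma membrane but beyond T of every
  active zone (endocytic region);
* **cytoplasmic** — everything else.

These four pools partition each profile's vesicles. For reporting, the
near-AZ pool is *nested*: "vesicles within 30 nm of the active zone"
includes the docked ones, mirroring how such counts are reported (≈4 within
30 nm, of which ≈2 docked, in cultured hippocampal synapses). Both views are
emitted; the partition invariant is tested.

Manual annotation takes precedence over geometry for docked and tethered
vesicles: tethers are invisible to a coordinate trace, and the annotator may
see contact the trace cannot encode. Disagreements between the manual call
and the geometric rule are never auto-corrected; they are tallied by
`tether_override_report()` for quality control. Distance to the active zone
is the minimum over all active-zone records, since a profile may contain
several; `dist_az >= dist_pm` is *not* assumed (the two membranes are traced
independently).

## Pits

Pits (inward membrane deflections, exocytic or endocytic) are open
polylines. Their metrics are defined relative to the **base chord** joining
the trace endpoints: base width = chord length; depth = maximum
perpendicular distance from the chord; diameter at **full-width
half-maximum** = pit width parallel to the chord at half depth, linearly
interpolated between crossings (outermost pair if the profile crosses half
depth more than twice — a deliberate tie-break that keeps the metric
monotone in pit size); arc length = traced length. Measuring parallel to the
chord, not the image axes, makes all four metrics rotation invariant; all
are degree-1 homogeneous under scaling. A trace lying entirely on its chord
is rejected as a "flat pit". Closed forms validate the implementation: a
triangle pit has FWHM equal to half its base, a semicircular pit of radius r
has depth r, base 2r and FWHM r√3, reproduced to 0.1% at 1° sampling.

A pit is **inside the active zone** when its trace crosses the active-zone
trace at ≥2 points (the active zone is traced where the membrane would have
been, under the pit) or when both endpoints are within 5 nm of it
(`pit_endpoint_tol`); otherwise it is outside (periactive). With several
active zones, any one satisfying the rule suffices.

## Aggregation conventions

Vesicle diameters are reported in two aggregation orders: pooled over all
vesicles, and mean of per-profile means. The mean of means weights each
synapse equally and better represents the population; both are emitted with
SEM = SD/√n (n = vesicles pooled, or profiles). Per-profile counts and
active-zone lengths are summarized by median with a distribution-free 95% CI
(binomial rank method), the convention for skewed count data.

Distance distributions use half-open bins [kw, (k+1)w) (default w = 50 nm);
a distance exactly on a boundary falls in the upper bin, and the bin table
extends to cover the largest observed distance (no silent truncation). Three
curves are produced: each profile's normalized abundance (counts / profile
total, each row summing to 1), their across-profile mean, and the pooled
normalization (all structures combined, then normalized). The pooled curve
equals the count-weighted mean of the rows.

## Serial sections

A `serial_stack` orders profiles by slice index within a synapse;
z = slice_index × section thickness (default 33 nm). The z-assignment uses
the section index directly rather than centring structures within the
section (z = (i+0.5)·t); at 33 nm the difference is a constant half-section
offset that cancels in all within-stack distances. Aggregation is additive
and order-independent; the docked fraction per reconstructed synapse is
total docked / total vesicles over its sections. Structures spanning
sections are *not* linked automatically — that re-evaluation is inherently
manual — but endosome/MVB contours in adjacent sections whose x,y footprints
overlap are flagged (`overcount_flags`) for review.

## The synthetic generator: what it emulates, and what it does not

`synth_config()` + `generate_dataset()` build annotation files with analytic
ground truth. The plasma membrane is a circular arc (default radius 400 nm,
a ~0.8 µm bouton) traced at 2 nm vertex spacing; the active zone is a
concentric sub-arc (default 385 nm long). Vesicles are placed at exact
radial offsets, so the true edge distance of a vesicle at interior radius
r_c is R − r_c − r analytically; docked vesicles are placed tangent
(distance 0). Pits are semicircular bumps whose depth/base/FWHM are known in
closed form; endosomes are circular contours at known clearance. With 2 nm
vertex spacing the only recovery error is the chord sagitta, s²/8R ≈ 0.001
nm, far below the 0.05 nm recovery tolerance asserted in the tests —
`vertex_spacing` can be raised to stress-test coarse tracings.

Defaults describe a cultured hippocampal dataset: 10 profiles × 51 vesicles,
diameters ~ N(40, 4) nm, 2 docked per profile, edge distances to the plasma
membrane decaying exponentially (mean 75 nm, truncated to 0.5–300 nm,
a monotone-decaying shape typical of vesicle distributions), one pit inside
and one outside the active zone, one endosome. Distances are drawn away
from 0 (≥0.5 nm) so that "docked" is exactly the planted set.

What the generator does **not** emulate: tracing jitter and annotator
disagreement, non-convex membranes, vesicle exclusion volumes (generated
vesicles may overlap), partial-profile truncation at image borders, and
multi-section structures. Passing recovery tests therefore demonstrates the
*computational* pipeline is correct on idealized tracings, not that
segmentation of real micrographs is accurate — the latter is a property of
the annotator, which the blinding workflow exists to keep honest.

## Blinding

Files from all conditions of an experiment are pooled, copied (originals
untouched) under randomized zero-padded ids, and the id→name key is
persisted as JSON with the seed recorded, so the assignment is auditable and
reproducible; unblinding copies results back under the original stems and
rejects orphans and collisions loudly. The key format is deliberately plain
JSON rather than a binary workspace so it can be read anywhere.

## Numerical choices and degenerate inputs

* Consecutive duplicate vertices are collapsed; a single-point "polyline"
  yields a point distance with a warning.
* Segment intersection uses the standard parametric test with a relative
  tolerance of 1e-9; coincident crossing points are deduplicated at 1e-7
  relative tolerance, so a crossing exactly at a shared vertex counts once.
  Parallel overlaps are not counted as crossings (the pit rule's endpoint
  branch covers tangential contact).
* Self-intersecting closed contours still get a shoelace area, with a
  warning — annotators occasionally cross their own trace by a pixel, and
  refusing the record outright would silently bias counts.
* Coordinates are serialized at 10 significant digits; round-trips are
  identical to at least 6 significant digits.
* Problem sizes in the test-suite and the acceptance script (hundreds of
  random geometry configurations, 10×51-vesicle datasets, 2,000 permutation
  draws, 8-section stacks) were chosen to estimate every statistic stably
  in seconds on a single core.

## Worked example

```{r, eval = FALSE}
cfg <- synth_config(seed = 1)
g <- generate_dataset(cfg, "study")
key <- randomize_images(g$files, "blinded", seed = 2)
# ... annotate / re-evaluate the randomized copies ...
unblind_files(key, list.files("blinded/randomized", "[.]txt$",
                              full.names = TRUE), "blinded")
res <- cmd_analyze("blinded/unblinded",
                   analysis_config(pixel_size = 0.5), "results")
res$summary
```

## Known limitations

* 2D distances only within a profile; no across-section 3D distances.
* No automatic tether detection, curvature estimation, or trace smoothing.
* No hypothesis testing between conditions — `cmd_compare()` emits
  side-by-side effect tables for external statistics software.
* The canonical coordinate-list delimiter of the upstream macro output is
  auto-detected per file (comma or whitespace) rather than fixed; files are
  always written with commas.
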
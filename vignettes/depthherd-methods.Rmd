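---
title: "DepthHerd: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DepthHerd: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DepthHerd)
```

## The measurement problem

Lameness in dairy cattle shows in posture before it shows in milk yield: a
lame cow walks with a lowered head and an arched back. Seen from directly
above with a time-of-flight depth camera, this is a height signal — the
highest point along the dorsal (backbone) line of a lame cow sits lower than
that of a sound cow, with roughly 1.2 m above the floor separating the two
groups under a camera mounted 3 m over a flat concrete pathway. DepthHerd
turns a raw depth stream into that signal and a lame/sound call per animal,
and ships a simulator that makes every stage verifiable against an exact
analytic ground truth.

The package assumes: a fixed overhead camera over an approximately flat
floor; one walking corridor, so animals move essentially horizontally
through the 132 × 176 frame; no sustained occlusion between animals; and
depth in metres (the I/O layer never rescales — readers of raw sensor units
must convert first, and rescale the pixel-sum threshold accordingly).

## Pipeline stages and their parameters

### Detection and the pixel-sum noise filter

Detection is deliberately pluggable: any function mapping a frame to binary
masks can stand in, and externally produced mask rasters (e.g. from a
fine-tuned neural instance detector) are accepted via `masksDetector()`.
The built-in `referenceDetect()` thresholds height above the floor at
`fgDeltaM` (default 0.1 m — far above sensor noise, far below any animal)
and takes 8-connected components of at least `minArea` pixels (default 50,
suppressing speckle; both defaults are configuration keys). The package
does not train or bundle any learned detector: its own contribution starts
after instance masks exist.

Regions are then filtered by the sum of masked depth values. With
metre-scale depths, a visible cow footprint (thousands of pixels at ~1.5–3 m
depth) sums far above 4000 metre·pixels while a human footprint (a few
hundred pixels) stays far below, so the default threshold `Th = 4000`
cleanly separates them. The inequality is strict: a sum of exactly 4000 is
rejected. The masked depth region itself is extracted by plain element-wise
multiplication of mask and frame, so in-mask values are never altered.

### IOU tracking

Association is greedy on bounding-box IOU: candidate (track, detection)
pairs at or above `iouThreshold` are matched in descending IOU, one-to-one,
ties broken by lower track ID then leftmost detection — a fully
deterministic completion of pairwise IOU thresholding. The default
threshold 0.5 is the conventional multi-object-tracking choice; at the
simulator's default 8 px/frame displacement of a 176 px body, inter-frame
IOU stays near 0.9, so the threshold is not delicate. A matched track's
box becomes the matched detection's box (no motion model), unmatched
detections open sequential IDs in left-to-right order, and a track
unmatched for `patience` consecutive frames (default 1) closes — in a
single always-visible corridor a miss means the animal left. Archiving
writes one folder per ID containing the masked depth grids as one-frame
depth CSVs plus a manifest, and is exactly invertible (`loadTracks()`), up
to in-mask pixels whose depth is exactly 0 (dropouts), which cannot be
distinguished from background in a masked grid.

### Backbone-profile features

Only frames whose bounding box spans all 176 columns are featurised: they
are the frames in which the profile covers the whole body. Each masked
depth grid is transformed to height, `h = distance − depth`, clamped below
at 0 (heights are physically non-negative and the subsequent column maximum
would otherwise be noise-sensitive); smoothed with a normalised discrete
Gaussian (`sigma` default 1 px, kernel radius `ceiling(3·sigma)`,
reflective borders — the common defaults, all configurable); and reduced to
per-column maxima, giving one length-176 vector per frame. Smoothing is
applied to the masked height field (background fixed at 0); near the mask
boundary this shrinks heights slightly, which is irrelevant to the
column-max feature because the maximum sits on the dorsal midline, far
from the boundary.

The reference `distance` defaults to 2.8 m even though the nominal camera
mount is 3.0 m: the height-transform convention for the field data this
dialect comes from uses 2.8 m as the floor reference (plausibly a sensor
origin offset), and the package follows that convention while exposing
`distance` everywhere. For simulated scenes the true camera height is
known, so suite evaluation (`suiteDataset()`) uses the scene's camera
height as the reference — with the 2.8 m default the two conventions would
differ by a constant 0.2 m offset in every profile, which matters to the
fixed 1.2 m cutoff though not to the learned classifiers.

### Classification

Three classical models run on the profiles — random forest (100 trees),
k-nearest-neighbour (k = 5) and a decision tree grown to full depth (no
complexity pruning) — hyperparameters are unstated in the original setting,
so these conventional defaults are exposed and recorded in every report.
The transparent baseline predicts lame iff the profile maximum is below
1.2 m. Accuracy is per frame; per-cow majority voting is provided as a
clearly separate aggregation (`cowMajorityVote()`). Benchmark suites are
split **by cow**, never by frame, so no animal contributes to both splits —
frame-level splits would leak near-duplicate profiles of the same animal
into the test set.

### Evaluation

Detection accuracy is `100·(TP + TN)/(TP + FP + TN + FN)`; TN counts
correctly rejected non-cow regions, which is why it is almost always 0 in
detection-only sessions. Tracking uses CLEAR-MOT:
`MOTA = 100·(1 − (FN + FP + IDS)/GT)`, with an identity switch counted
whenever a ground-truth identity's matched track ID differs from its
previously matched ID. Session averages are the **unweighted mean of
per-session percentages**, not pooled counts — this is the convention under
which the bundled tracking table's printed average (99.92) is exactly the
mean of its rows. Reporting rounds half away from zero to two decimals.

One bundled detection session (4 September, PM: TP = 1836, TN = 1, FP = 4,
FN = 0) carries a reported accuracy of 99.95% that is inconsistent with its
own counts, which give 1837/1841 = 99.78%. A transposition of the TN and FP
entries would explain the reported figure. The package does not silently
"fix" the row: the recomputation suite asserts the 99.78% recomputed value
and keeps the reported one as data. The detection-table average (99.94) is
reproduced from the six *reported* per-session figures.

`scoreRun()` matches predictions to ground truth at IOU ≥ 0.5 (the standard
detection-matching convention; how true positives were judged originally is
unstated). Ground-truth objects with visible footprint fraction below
`minVisibility` (default 0.25) are **ignore regions**, as in the common MOT
benchmarks: they are not misses, and predictions matching only them are
neither false positives nor identity-switch candidates. This is the
principled way to score corridor traversals, where every animal is
necessarily half-visible at the frame edge while entering and leaving and
where the pixel-sum filter necessarily drops regions below roughly 16%
visibility under the default geometry.

## The simulator: what it emulates, and what it does not

A scene is a flat floor `cameraHeightM` (default 3 m) below the camera,
plus objects rendered as separable height surfaces: an along-body dorsal
curve times an elliptical cross-body factor. The dorsal curve is an
elliptical taper from nose to tail, multiplied by `1 − 0.25·arch·bump` with
a cosine mid-body bump, then normalised so its maximum equals
`peakHeightM` exactly — so the per-column maximum of the rendered surface
*is* the dorsal curve, analytically, which is the end-to-end oracle for
the feature extractor (verified to 10⁻⁶ m unsmoothed, 10⁻³ m through the
full pipeline with small smoothing). Lame templates draw dorsal peaks in
0.95–1.05 m with pronounced arch (0.4–0.8), sound templates 1.35–1.45 m
with near-straight backs (arch ≤ 0.15) — ±0.15 m margins around the 1.2 m
boundary that a clinician would call clearly lame and clearly sound —
with per-pixel Gaussian sensor noise of SD 0.01 m (moderate for
time-of-flight at 3 m) in benchmark suites and 0.005 m in tracking scenes.

Body size defaults (176 × 56 px for cows, so an adult spans the full frame
width when centred and full-width frames arise once per traversal; 30 × 16
px for humans, whose pixel sums then stay below 4000 by a wide margin) are
simulator constants chosen for internal consistency with the fixed frame
geometry — pixel pitch is not derivable from the original setting. Motion
is horizontal at constant integer speed (default 8 px/frame), entries and
lanes are configured per object, and configurations with simultaneous
spatial overlap are rejected unless explicitly allowed, keeping the
tracker's no-occlusion assumption true in fixtures by construction. One
seeded generator drives all stochastic draws, so scenes are reproducible
bit for bit.

What the simulator deliberately does **not** model: photorealistic cow
shapes, legs and gait kinematics, occlusion and multi-lane crossing,
uneven or dirty floors, depth dropouts and specular artefacts, and herd
social behaviour (stopping, crowding). Passing the synthetic benchmarks
therefore demonstrates the pipeline's correctness — that each stage
computes what it claims on data satisfying its assumptions — not field
accuracy on farm recordings, where the separation between lame and sound
backbone heights is much noisier. The simulator's perfectly separable
geometry is why synthetic classification accuracies saturate near 100%
while the same feature on real herds is reported far lower.

## Numerical and scale choices

Row-major flattening (all 176 columns of row 0, then row 1, …) defines the
CSV dialect in both directions; read∘write is the identity to 6 decimals.
Depth CSVs are validated row by row, with malformed-frame and parse errors
naming the offending row and field. The Gaussian kernel is the sampled
continuous kernel renormalised to sum to 1, applied separably; reflective
borders duplicate the edge pixel. Degenerate (zero-area) boxes are a
domain error for IOU. Test and benchmark problem sizes — 45-frame
single-cow traversals, a 200-frame five-cow tracking scene, a 76-cow
classification suite (31 lame / 45 sound, mirroring a realistic herd
imbalance) — were chosen as the smallest sizes at which every stage
(entry/exit edge effects, concurrent tracks in two lanes, class imbalance)
is actually exercised.

## Known limitations

* The reference detector assumes a flat floor; sloped or cluttered scenes
  need an external detector behind the pluggable interface.
* The tracker has no motion model or re-identification: a detector dropout
  longer than `patience` splits a track (scored as an identity switch
  against ground truth).
* The 1.2 m baseline is geometry-dependent: any change in camera height or
  height-transform reference shifts it by the same constant.
* Per-frame classification treats frames of one cow as independent, which
  overstates effective sample size; the by-cow split and the per-cow vote
  mitigate but do not remove this.
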
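# DepthHerd

Automated lameness screening for dairy cattle from an overhead time-of-flight
depth camera. Lame cows lower their head and arch their back while walking,
which shows up directly in a top-view height map: the highest point along the
backbone of a lame cow typically stays **below ~1.2 m**, while sound cows walk
with their dorsal line **above 1.2 m**. DepthHerd implements the full
monitoring pipeline around that signal, for researchers in precision livestock
farming and for anyone who wants a fully testable, deterministic reference
implementation of this class of depth-video pipeline:

1. **Depth I/O** — frame-per-row CSV streams of 132 × 176 rasters of
   camera-to-surface distance (metres), plus JSON-lines ground truth.
2. **Detection** — a pluggable instance-detector interface (external mask
   rasters are accepted), a reference depth-threshold / 8-connected-component
   detector, and a **pixel-sum noise filter**: a detected region is kept as a
   cow only if its masked depth sum exceeds `Th = 4000` metre·pixels, which
   rejects human-sized blobs on the pathway.
3. **Tracking** — greedy IOU association across frames with sequential IDs
   (1, 2, 3, …), miss patience, and per-ID folder archiving.
4. **Features** — per frame in which the cow spans the full 176-column field
   of view: height transform `h(x, y) = distance − depth(x, y)`, smoothing
   with a normalised discrete Gaussian
   `G(x, y) = exp(−(x² + y²)/2σ²) / 2πσ²`, then the backbone profile
   `backbone_j = max_i G(i, j)` — a length-176 feature vector of per-column
   maximum heights.
5. **Classification** — random forest, k-nearest-neighbour and decision-tree
   models on the backbone profiles, plus the transparent 1.2 m cutoff
   baseline.
6. **Evaluation** — detection accuracy
   `100 · (TP + TN)/(TP + FP + TN + FN)` and CLEAR-MOT tracking accuracy
   `MOTA = 100 · (1 − (FN + FP + IDS)/GT)`, per session and as unweighted
   session averages.
7. **Synthetic herd simulator** — seeded scenes of cow- and human-shaped
   height blobs over a flat floor under a 3 m camera, with exact ground-truth
   boxes, track IDs and labels, so every stage is testable without farm data.

## Worked example

Simulate a sound cow (dorsal peak 1.40 m), a lame cow (1.05 m, arched back)
and a human crossing the corridor, then run the full pipeline:

```r
library(DepthHerd)

scene <- renderScene(sceneConfig(
  nFrames = 120,
  cows = list(
    list(template = cowTemplate(peakHeightM = 1.40, arch = 0.0),
         entryFrame = 0,  laneRow = 40),
    list(template = cowTemplate(peakHeightM = 1.05, arch = 0.6),
         entryFrame = 40, laneRow = 92)),
  humans = list(list(entryFrame = 15, laneRow = 110)),
  noiseSdM = 0.005, seed = 42))

src <- file.path(tempdir(), "scene"); dir.create(src)
writeDepthCSV(scene$frames, file.path(src, "depth.csv"))
writeGroundTruth(scene$truth, file.path(src, "truth.jsonl"))

manifest <- runPipeline(pipelineConfig(
  input = file.path(src, "depth.csv"),
  outDir = file.path(src, "run"),
  groundTruth = file.path(src, "truth.jsonl"),
  distanceM = 3))
```

which logs:

```
[read] 120 frames
[detect] 119 regions
[filter] 74 kept / 45 rejected
[track] 2 tracks
[features] 2 full-width frames from 2 tracks
[score] detection 100.00%, MOTA 100.00%
```

The 45 rejected regions are the human blob (masked pixel sums far below
4000) and the partially visible cows at the frame edges; both cows are
tracked without an identity switch, so MOTA is 100%. The feature table holds
one full-width frame per cow, and the 1.2 m baseline separates them:

```
  track_id frame_index baseline_prediction label
1        1          22               sound sound
2        2          62                lame  lame
```

with backbone-profile maxima of 1.399 m and 1.051 m — the rendered dorsal
peaks recovered to a few millimetres despite sensor noise.

Classifier benchmarks are one call away:

```r
suite <- makeBenchmarkSuite(seed = 11, nLame = 31, nSound = 45)
ds <- suiteDataset(suite)
testAccuracy(trainEval(ds, "RF", seed = 11))   # 100 on this synthetic suite
testAccuracy(thresholdBaseline(ds))            # 100
```

A thin shell entry point wraps the same functions:

```sh
Rscript inst/cli/depthherd simulate --out scene --cows 3 --seed 1
Rscript inst/cli/depthherd run --input scene/depth.csv --ground-truth scene/truth.jsonl --out run
Rscript inst/cli/depthherd evaluate --counts counts.csv --metric mota
```

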
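# voxcyto

Volumetric histo-cytometry for cleared-tissue fluorescence microscopy, in R.

## The problem

Tissue clearing plus 3D microscopy makes it possible to image immune
cells in their anatomical context — for example MHC-II⁺
antigen-presenting cells around and inside kidney glomeruli during
glomerulonephritis. Turning such stacks into numbers is usually done with
a chain of proprietary tools: surface segmentation and per-object
statistics in one program, flow-cytometry-style gating of the exported
tables in another. `voxcyto` reimplements that analysis chain as an open,
tested pipeline, and ships a synthetic phantom generator with analytic
ground truth so every stage can be validated without access to raw
microscopy data.

It is aimed at imaging scientists and computational biologists who need:

* 3D segmentation of multi-channel stacks with **anisotropic voxels**
  (smoothing, global thresholds, per-slice hole filling, connected
  components, watershed splitting),
* per-object "surface" statistics: centroid, exact volume, mesh surface
  area, sphericity, median channel intensities,
* **signed shortest distances** from each cell to the nearest anatomical
  target structure, via an exact anisotropic Euclidean distance
  transform,
* distance-threshold population gating and frequency reports
  (flow-cytometry semantics: frequencies relative to a parent gate),
* group comparisons (exact/approximate two-tailed Mann–Whitney U,
  Welch's t),
* acquisition-throughput normalization of imaging metadata,
* reproducible end-to-end runs with config, per-stage seeds, materialized
  artifacts and digest manifests.

## The core statistic

Cells are classified by their signed shortest distance $d$ to the nearest
solid glomerulus (negative = infiltrating):
**within** ($d<0.5\,\mu m$), **surrounding** ($0.5\le d\le 20$),
**peripheral** ($d>20$). After gating on $d \le 20\,\mu m$ (so the first
two populations exactly compose the gate), the headline readout is

$$\text{within fraction} \;=\; \frac{\#\,\text{within}}{\#\,\text{gated}},$$

compared between groups together with a Mann–Whitney U test on
within-cell volumes. Sphericity, used to separate round glomeruli from
elongated vessels in the structural channel, is
$\Psi = \pi^{1/3}(6V)^{2/3}/A$.

## Worked example

Simulate a nephritic-kidney phantom ("KO" preset: 278 cells planted
inside the 20 µm gate, 97 of them within glomeruli → planted fraction
0.349) and analyze it end-to-end:

```r
library(voxcyto)

cfg <- pipeline_config(scenario = "KO", seed = 1, out_dir = "runs/ko1")
m <- run_pipeline(cfg, verbose = TRUE)
m$summary
```

```
simulate: scenario KO, 414 planted objects
segment: cells ('mhc2') -> 376 objects
segment: structures ('cd31') -> 6 objects
segment: deposits ('igg') -> 29 objects
stats: cells -> 376 records
distances: structures split into 4 glomeruli / 2 vessels
distances: 376 cells measured (95 within / 179 surrounding / 102 peripheral)
report: n_gated=274 within_fraction=0.3467

$n_gated
[1] 274

$within_fraction
[1] 0.3467153
```

The pipeline found all 376 planted cells, recovered the 4 glomeruli and 2
vessels from the single structural channel by shape, and measured a
within fraction of 0.347 against the planted 0.349. Comparing a control
("WT", planted 0.166) and a nephritic ("KO") run reproduces the group
analysis:

```r
wt <- run_pipeline(pipeline_config("WT", seed = 1, out_dir = "runs/wt1"))
compare_runs(wt, m)
```

```
<run_comparison>
  within fraction: A=0.1586 (n_gated=227)  B=0.3467 (n_gated=274)
  within volumes:  MWU U=228.5, p=2.2e-14 (normal; n=36 vs 95)
  B > A (within fraction): TRUE
```

The within-cells of the KO run are significantly larger (the preset
plants a 3.5 vs 3.0 µm mean radius), and the KO within-fraction exceeds
the WT one — the planted disease signal, recovered from pixels.

Acquisition-throughput normalization of imaging metadata
(seconds per acquisition sequence per nanoliter, 1 nL = 100³ µm³):

```r
rec <- acquisition_record("02:32:07.545", n_sequences = 5,
                          extent_um = c(581.25, 581.25, 263.24))
table_round(normalized_time(rec), 2)
#> [1] 20.53
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
$(Rscript -e 'cat(system.file("cli", "voxcyto", package = "voxcyto"))') run --scenario WT --seed 1 --out runs/wt
```

Subcommands: `run`, `compare`, `simulate`, `segment`, `stats`,
`distances`, `gate`/`report`, `metrics`.

## Scope

Synthetic phantoms emulate geometry, intensity contrast and shot/read
noise — not optics (no PSF, attenuation or bleed-through) and not
proprietary deconvolution. See `vignettes/methods.Rmd` for the model,
all stated-world parameter choices, numerical conventions and known
limitations.
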
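# lineprofiler

Automated, unbiased measurement of strand-to-strand distances and
protein-distribution widths in 2D super-resolution fluorescence images of
synaptonemal complexes (SCs) and similar twisted two-strand filaments.

## The problem

In spread preparations the SC's two lateral elements (labelled e.g. with
SYCP3) appear as two parallel strands that twist around each other. A
cross-sectional intensity profile taken perpendicular to the SC axis is
bimodal, and the peak-to-peak distance of that profile measures the strand
separation — the key readout for judging expansion-microscopy isotropy and
for protein mapping. Measuring it by hand is slow and biased: near helical
twists the 2D projection *underestimates* the true separation, and profile
placement is subjective.

`lineprofiler` automates the measurement:

1. **Guide-channel segmentation** — Gaussian blur, Otsu binarization,
   topology-preserving thinning (Zhang–Suen) to 1-px centerlines, line
   tracing with breakpoints at junctions and sharp (> 60°) turns, and a
   parametric smoothing spline giving positions and tangents of the SC
   axis. In *two-channel* mode a central-element channel (e.g. SYCE3)
   guides the spline; in *one-channel* mode the midline is estimated from
   the axis channel itself by merging the two strands with a large blur
   (transverse center of mass).
2. **In-plane region selection** — a flood fill from the image border marks
   the background regions enclosed by the axis signal; these lobes are the
   frontal views where the strand separation is maximal. Profile sources
   are the spline points inside those lobes.
3. **Profiling** — intensity profiles are sampled perpendicular to the
   spline (cubic interpolation, sub-pixel parabolic peak refinement) and
   each bimodal profile yields a peak-to-peak distance. Distances outside
   400–1200 nm (configurable) are discarded.
4. **Half-normal cutoff fit** — because projection can only underestimate,
   the kept distances pile up below the true separation `c` with a sharp
   cutoff at it. The histogram is fitted with

   ```
   y(x) = A exp(-(x - c)^2 / (2 sigma^2)) + n   for x <= c
   y(x) = 0                                     for x >  c
   ```

   by profiled least squares against bin-integrated model means. The
   fitted center `c` is the reported strand distance; its standard error
   comes from the profile-SSE curvature.
5. **Averaging and widths** — kept profiles are aligned at the midpoint
   between their peaks and averaged per line and per image; monomodal
   profiles (central-element proteins) are summarized by a single-Gaussian
   fit (SD and FWHM = 2 sqrt(2 ln 2) sigma).

A synthetic renderer produces ground-truth fixtures — the validation helix
`y = ±(a/2) cos(bx)` imaged with a Gaussian PSF, straight parallel ridges,
and binary shapes — so the whole chain is testable without microscopy data.

## Worked example

Reproduce the helix self-validation (a = 800 nm, b = 1/1612 nm⁻¹, pixel
size 32.24 nm, three twist periods):

```r
library(lineprofiler)
v <- validate_helix()
#> strand_distance_nm=800.056 stderr_nm=0.325868 pass=true
```

The printed line says the full one-channel pipeline recovered a strand
distance of 800.06 nm from the rendered helix — within the 5 nm pass
window around the known 800 nm ground truth, confirming that the analysis
is not biased by the decreasing separation near twists. The underlying
result object carries the per-profile distances, the histogram and fit,
and stage counts:

```r
r <- v$result
r$counts[c("lines_traced", "distances_kept", "distances_discarded")]
#> $lines_traced
#> [1] 1
#> $distances_kept
#> [1] 521
#> $distances_discarded
#> [1] 141
```

The same run from the shell, via the thin CLI wrapper:

```sh
Rscript inst/cli/lineprofiler.R validate
Rscript inst/cli/lineprofiler.R simulate --out helix.tif
Rscript inst/cli/lineprofiler.R run --input helix.tif --pixel-size 32.24 \
    --mode one_channel --out results/
```

`run` writes `distances.csv`, `profiles.csv` and `summary.json` into the
output directory. Exit codes: 0 success, 1 usage/input error, 2 analysis
failure.

## Package layout

- `R/` — implementation (I/O and config, segmentation, profiling,
  distance fitting, synthetic rendering, pipeline, CLI)
- `vignettes/methods.Rmd` — model, assumptions, parameter choices,
  numerical decisions and limitations
- `tests/testthat/` — unit, property and end-to-end ground-truth tests
- `inst/cli/lineprofiler.R` — shell entry point
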
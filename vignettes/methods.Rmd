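---
title: "Measuring strand distances in twisted two-strand filaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring strand distances in twisted two-strand filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineprofiler)
```

## The measurement model

The synaptonemal complex (SC) in spread preparations shows its two lateral
elements as a pair of strands that twist around each other. In a 2D
maximum-intensity projection the local strand separation varies with the
twist phase: it is maximal where the helix lies in plane ("frontal view")
and shrinks to zero at the crossings. A cross-sectional intensity profile
taken perpendicular to the SC axis is therefore bimodal with a
peak-to-peak distance that *underestimates* the true separation everywhere
except at the frontal-view apex.

`lineprofiler` turns this into an unbiased estimate in two steps. First it
measures many per-profile peak-to-peak distances, restricted to
flood-fill-enclosed in-plane regions. Second it exploits the one-sided
nature of the projection error: measured distances pile up *below* the
true separation $c$ with a sharp cutoff at it, so the histogram of kept
distances is fitted with a half-normal cutoff model

$$
y(x) = \begin{cases}
A\,e^{-(x-c)^2 / (2\sigma^2)} + n & x \le c \\
0 & x > c ,
\end{cases}
$$

with amplitude $A$, cutoff (center) $c$, spread $\sigma$ and noise floor
$n$ free. The fitted $c$ is the reported strand distance; $\sigma$
describes how fast frames away from the apex lose apparent separation, and
$n$ absorbs the flat tail of sources far from the apex. The fit is plain
least squares against the histogram, as the counts near the cutoff are
large and approximately Gaussian.

Note on orientation: the model must have its support on the *low* side of
the cutoff. A model that is zero below $c$ and decays above it cannot
recover the true separation from an underestimate-skewed histogram — it
centers one bin below the cutoff, outside the method's own 5 nm validation
window. The orientation implemented here is the one consistent with the
projection argument and with the validation experiment.

## Pipeline stages and their assumptions

1. **Blur + Otsu + thinning.** The guide channel is blurred
   (`blur_sigma_px`, default 1 px) to suppress noise, binarized at the
   threshold maximizing between-class variance over a 256-bin histogram,
   and thinned to 1-px centerlines with Zhang–Suen two-subiteration
   thinning (topology-preserving; no installed R package provides 2D
   thinning, so it is implemented here and property-tested for thinness,
   subset-ness and component/hole preservation).
2. **Tracing.** Skeleton pixels with more than two neighbors are junction
   pixels: they break lines and belong to none, which keeps pixel
   bookkeeping exact (pixels in lines + junction pixels + discarded short
   pixels = skeleton pixels). A direction change above
   `breakpoint_angle_deg` (default 60°) between successive 5-px chords
   also breaks a line; 60° splits crossing artifacts while tolerating the
   curvature of real SCs. Lines shorter than `min_line_length_px`
   (default 10) are dropped.
3. **Spline.** Each traced line is fitted per-coordinate as a cubic
   (smoothing) spline of normalized cumulative chord length —
   `stats::smooth.spline` with `spar = spline_smoothing` (default 0.7;
   0 interpolates). On rendered fixtures the residual RMS is well below
   1 px and tangents are accurate to a few degrees.
4. **One-channel midline.** Without a central-element channel the two
   strands are merged into one ridge by blurring with
   $\sigma = \texttt{max\_distance\_nm} / (2\,\texttt{pixel\_size\_nm})$,
   then segmented as above. This realizes a local transverse center of
   mass, reuses tested machinery and is rotation-invariant. On fixtures
   whose central channel sits exactly on the midline, one- and two-channel
   splines agree within a pixel.
5. **Enclosed regions.** Background pixels not reachable from the border
   (4-connectivity, `EBImage::floodFill` on a zero-padded frame) mark the
   lobes enclosed by the strands. Structures that enclose nothing — e.g.
   straight parallel ridges used as oracles — are handled by
   `enclosed_only = FALSE`, which keeps all spline samples as sources.
6. **Profiles.** One source per pixel of spline arc; profiles extend
   `profile_halflength_nm` (default 1300, which must be at least
   `max_distance_nm` so a maximally separated pair fits) at a step of half
   a pixel. Profiles leaving the image are rejected, not zero-padded,
   because padding biases peak detection.
7. **Peaks.** The strongest local maximum on each side of the spline is
   selected (the spline runs between the strands, so requiring one peak
   per side avoids locking onto one strand's double peak) and refined with
   a 3-point parabola. Distances outside
   `[min_distance_nm, max_distance_nm]` (default 400–1200 nm, appropriate
   for ~4× expanded samples; override for unexpanded data) are flagged and
   retained with a reason, never deleted.

## Numerical choices

* **Interpolation.** Profiles are sampled with Catmull–Rom cubic
  interpolation (`profile_interp = "cubic"`). Bilinear sampling makes the
  profile piecewise linear, so its interpolated maxima lock onto pixel
  knots and parabola refinement is biased toward the nearest pixel by up
  to half a pixel (~8 nm at 32 nm pixels each side — enough to push the
  helix validation out of its window). The C¹ cubic removes that
  quantization; bilinear remains available for comparison.
* **Bin-integrated histogram fit.** Each bin count is compared against the
  model's mean over the bin (Gaussian integrals via `pnorm`), not the
  model value at the bin center. A cutoff inside a bin then contributes
  exactly its partial mass, making $c$ identifiable *within* a bin;
  center-pointwise fitting is degenerate over a whole bin width.
* **Profiled optimization.** The cutoff makes residuals discontinuous in
  $c$, so derivative-based solvers cannot move $c$. The fit is profiled:
  a coarse grid over $c$ (half-bin steps) plus golden-section refinement,
  with $\sigma$ minimized one-dimensionally and $(A, n)$ solved by linear
  least squares (variable projection; nonnegativity by clamping) at each
  candidate. `c_stderr` is derived from the curvature of the profile SSE;
  the Gaussian spread $\sigma$ is reported alongside, since either can
  serve as an uncertainty depending on whether fit precision or population
  spread is wanted.
* **Histogram bin width.** Default 10 nm. With the several hundred kept
  distances of a typical image this leaves tens of counts per bin near the
  cutoff while letting the fit localize $c$ to ~1 nm; much wider bins
  re-introduce half-bin quantization of the cutoff.
* **Fit window.** By default the whole histogram range enters the fit; the
  noise-floor term $n$ absorbs the far tail. A narrow window around the
  tallest bin leaves so few informative bins that the four-parameter fit
  becomes degenerate. `fit_window_nm` can restrict the window when a
  second structure contaminates the low end.
* **Degenerate inputs.** Constant images are rejected at Otsu ("degenerate
  intensity distribution"); empty masks and skeletons error early; a flat
  histogram yields `converged = FALSE` rather than an error; monomodal
  profiles give `reason = "no_bimodal"`; the Gaussian width fit refuses
  profiles with two prominent maxima (prominence > 20 % of range).

## The synthetic generator

`render_helix()` draws the maximum-intensity projection of a twisted
two-strand filament, $y_{1,2}(x) = \pm(a/2)\cos(bx)$ about the midline, so
the maximum center-to-center separation equals $a$. (Taken literally,
strands at $\pm a\cos(bx)$ would separate by $2a$; the implemented
convention is the one under which the validation recovers $a$.) Curves are
deposited by arc-length sampling at eighth-pixel steps with bilinear
splatting — constant intensity per unit curve length, no aliasing — then
convolved with a Gaussian PSF (default $\sigma = 40$ nm, a
structured-illumination-scale resolution at the 32.24 nm rendered pixel),
plus optional background and seeded Gaussian noise. Defaults reproduce the
validation condition: $a = 800$ nm, $b = 1/1612$ nm⁻¹, pixel size
32.24 nm, three twist periods. The transverse margin (default 1100 nm per
side) leaves room for full-length profiles. A second channel renders a
midline ridge emulating a central-element label, and the truth record
carries the strand functions, crossing positions $x = (k+\tfrac12)\pi/b$
and expected lobe count $\lfloor L b/\pi \rfloor$.

What the generator does *not* emulate: labeling stochastics, antibody
linkage error, expansion distortion fields, strand fraying, overlapping
SCs, and camera noise statistics. Passing the synthetic validation
demonstrates that the measurement chain is unbiased for an ideal twisted
two-strand object at realistic sampling — not that segmentation succeeds
on arbitrary real images; the 400–1200 nm filter remains the only
mechanism against contaminating structures, as in the original protocol.

## Validation results computed by this package

The test suite and `scripts/acceptance.R` recompute, from scratch:

```{r validate}
v <- validate_helix(quiet = TRUE)
c(strand_distance_nm = v$c_nm, stderr_nm = v$stderr_nm)
```

* the 800 nm helix recovered within 5 nm by the full one-channel pipeline
  (above), and a 650 nm helix within 1 % by the same code path;
* straight parallel ridges at 500/700/1000 nm separation recovered by the
  per-profile median within half a sampling step or 1 %;
* exact recovery of all four cutoff-model parameters from the model's own
  closed form, and a mean center error ≤ 5 nm over 100 Poisson-noise
  replicates;
* the closed-form Gaussian width identity FWHM $= 2\sqrt{2\ln 2}\,\sigma$
  (235.48 nm at $\sigma = 100$ nm) from `fit_gaussian_profile()`;
* structural properties: skeleton thinness/subset/topology, trace pixel
  conservation, flood-fill behavior on closed vs open shapes, helix lobe
  counts, rotation invariance of the distance estimate (< 1 %), and
  bit-exact determinism of seeded renders.

Problem sizes follow the validation design: three helix periods
(~950 × 95 px at 32.24 nm pixels), a few hundred profiles per run, 100
replicate fits for the noise study.

## Known limitations

* 2D only; z-stacks must be maximum-projected first (`project_z()`).
* One structure per enclosed lobe is assumed; overlapping SCs are only
  mitigated by the distance filter.
* The half-normal cutoff is a phenomenological model of the
  projection-foreshortened distance distribution; for very short filaments
  (few lobes) the histogram may be too sparse for a stable four-parameter
  fit (`converged = FALSE` is reported).
* Pixel size is always user-supplied; TIFF resolution tags are ignored by
  design, as reconstruction software writes them inconsistently.
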
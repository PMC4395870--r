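---
title: "Methods: sensitized-emission FRET tension mapping and tiling-array splicing calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensitized-emission FRET tension mapping and tiling-array splicing calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretsplice)
```

## What this package computes

`fretsplice` implements two desk-scale analysis pipelines from developmental
biomechanics in *C. elegans*:

1. **Tension mapping.** A tension-sensor module (TSMod) — donor and acceptor
   fluorophores joined by an elastic linker — is inserted into β-spectrin.
   Stretching the linker separates the fluorophores and lowers the Förster
   transfer efficiency, so *low FRET reads out high molecular tension*.
   Three confocal channels are acquired per z-frame: donor emission under
   donor excitation (`ID`), acceptor emission under acceptor excitation
   (`IA`), and acceptor emission under donor excitation (`IF`, the raw,
   contaminated FRET channel). The pipeline converts these into a per-pixel
   FRET-index map with a per-pixel shot-noise uncertainty and a validity
   mask, then compares a small anterior region of interest (the sensory
   depression region, SDR, where the pharynx pulls on the epidermis)
   against the rest of the embryo in a paired design.

2. **Splicing misregulation calls.** Tiling-array probe intensities for two
   genotypes are summarised per annotated exon/intron region; regions
   changed more than 1.5-fold in the mutant are classified (`exon_up`,
   `exon_down`, `intron_up` — intron retention), aggregated to gene-level
   category sets, and tested for enrichment of alternatively spliced (AS)
   genes against other categories and a ~25% genome-wide background.

A synthetic-data module generates ground-truth inputs for both pipelines so
that every stage is testable without microscope or array data.

## The FRET index and its exact inverse

For each pixel the raw FRET channel is background-subtracted and corrected
for spectral bleed-through,

$$cF = I_F - \delta\, I_D - \alpha\, I_A,$$

with measured bleed-through fractions $\delta$ (donor) and $\alpha$
(acceptor). The index is then

$$F \;=\; \frac{cF \cdot Q_D \cdot \varphi_D/\varphi_A}
                {q_D + cF \cdot Q_D \cdot \varphi_D/\varphi_A},$$

where $q_D$ is the quenched (background-subtracted) donor intensity, $Q_D$
the donor quantum yield and $\varphi_D/\varphi_A$ the collection-efficiency
ratio. $F$ is the fraction of donor excitations that ended in transfer: 0
with no sensitized emission, 1 in the limit of complete transfer, and
invariant under a common rescaling of all channels.

The synthetic imager is built to be the *exact algebraic inverse* of these
two formulas. For a pixel with excitation budget $S$ and true efficiency
$E$: $q_D = S(1-E)Q_D\varphi_D$, sensitized emission $cF = S E \varphi_A$,
direct acceptor signal $S\,g_{IA}$ (FRET-independent), plus linear
bleed-through mixing and a constant background. The acceptor quantum yield
is deliberately folded into $\varphi_A$ — the index formula carries no
separate acceptor-yield term, and introducing one would break the
round-trip identity that anchors the test suite. With noise off and the
matched calibration, the pipeline returns the ground-truth $E$ map to
machine precision, *including* non-zero $\alpha,\delta$ (bleed-through is
linear and exactly invertible).

The force model is a linear entropic spring feeding the sixth-power Förster
relation: $r(f) = r_0 + f/k$ and $E = 1/(1 + (r/R_0)^6)$. Only a smooth,
strictly decreasing force-to-FRET map is needed for testing; a worm-like
chain would change the parameterisation, not the pipeline. Defaults:
$R_0 = 5.4$ nm, zero-force efficiency $E_0 = 0.45$, $k = 1$ force unit/nm.
`fret_to_force()` inverts the map, which is how scenes with prescribed
ground-truth efficiencies (0.35 on the cortex, 0.20 in the SDR by default)
are constructed. The control constructs are force-insensitive by
construction: the terminal fusion (`N-TSMod`) reports $E_0$ everywhere and
the rigid-linker / long-separator controls report fixed high/low values
(0.55 / 0.15). No published numeric efficiencies exist for these controls,
so these are configuration values, not literature constants.

## Processing order and numerical choices

The pipeline order is fixed: **bin → background-subtract → bleed-through
correct → index → median filter → intensity threshold**.

* **Binning** (`bin_image()`): one downsample-and-average pass, default
  2×2, applied exactly once; trailing rows/columns that do not fill a block
  are cropped. Binning raises per-pixel SNR at the cost of resolution.
* **Background**: scalar per channel, carried with the stack. Negative
  post-subtraction values are retained (not clipped) and handled by the
  validity mask, so the estimator stays unbiased.
* **Median filter** (`median_filter_3x3()`): 3×3, reflect padding
  (border pixels mirrored outward), implemented as a vectorised sorting
  network so that a brute-force sliding-window oracle can verify it
  exactly. Invalid (`NA`) neighbours are ignored. Inside `fret_pipeline()`
  the filter is restricted to pixels that pass the intensity threshold and
  a window must contain at least 5 informative pixels: index values at
  sub-threshold pixels are noise-dominated, and letting them into the
  windows of genuine cortical pixels (or letting isolated above-threshold
  background pixels through unsmoothed) produces a measurable
  geometry-dependent bias between the high-curvature anterior SDR and the
  rest of the cortex — large enough to skew the null distribution of the
  paired test.
* **Uncertainty** (`propagate_uncertainty()`): first-order propagation of
  the shot-noise model $\mathrm{Var}(I) = g\,I/b$ (gain $g$, bin area $b$)
  through the two formulas, using the analytic partials of $F$ with respect
  to the three raw channels. The model choice is self-consistent with the
  Poisson generator, and the Monte-Carlo oracle in the tests resamples the
  same model; at the default budgets the linearisation agrees with 10^5
  resamples to well within 10%. Dim pixels have large $\sigma_F$, which is
  why the analysis is restricted to bright pixels.
* **Threshold** (`threshold_pixels()`): keep pixels with acceptor signal
  above background + $k\cdot$SD(background), default $k = 2$, SD from the
  shot-noise model. Because the spectrin-bound sensor concentrates at cell
  cortices, the same rule that removes high-uncertainty pixels also selects
  the sensor-rich cortical band.
* Coordinates are 0-based row/col; ROI boxes are half-open intervals.

## ROI statistics

Per frame, the FRET index is averaged over valid pixels of the SDR box and
of the remainder of the embryo footprint; per embryo, the 3–5 frame values
are pooled by an unweighted mean (`pool_embryo()`). The SDR vs non-SDR
comparison is *paired within embryos*, which cancels sensor expression
level, bleed-through drift and every other shared imaging condition. The
battery mirrors standard practice: paired and pooled-variance two-sample t
tests (Welch behind a flag), Jarque–Bera normality
($JB = n/6\,(S^2 + K^2/4)$, $\chi^2_2$), Levene's equal-variance test
centred at the mean (the original Levene form, via `car`), and the
Mann–Whitney U test (exact enumeration up to n = 20 per group, mid-rank
ties and variance correction otherwise). Degenerate inputs (zero-variance
differences, all-tied samples) return the exact limiting p-values with a
warning instead of erroring mid-battery.

`expression_independence()` computes the Pearson correlation between
valid-pixel F and acceptor counts. For an intramolecular sensor this should
be ≈ 0. The check is run on a *uniform-tension* scene: with a tension
structure present, F and expression covary through geometry (both the SDR
and the expression gradient have a spatial layout), which would confound
the artifact being tested. The generator's `intermolecular` parameter adds
a density-dependent contamination term as a positive control — the
correlation then becomes large.

## What the synthetic data does and does not emulate

The imager renders an elliptical embryo with a thin cortical sensor band
(6 px at acquisition scale, 2–3 px after the default binning — a thinner
band would be destroyed by the mandated 3×3 median filter), an SDR box at
the anterior pole with elevated tension, a ±30% linear expression gradient,
linear spectral mixing, constant background and per-pixel Poisson shot
noise. Default photon budget is 500 excitations per cortical pixel per
frame, 3 z-frames per embryo. It does **not** simulate a point-spread
function, chromatic mis-registration, photobleaching, autofluorescence or
detector read noise. Passing tests therefore demonstrate that the
*algebra, error model and statistics* of the pipeline are correct under
controlled conditions — not that any specific biological measurement is
reproduced. Real-embryo FRET values from the original experiments derive
from images that are not publicly deposited and are out of reach by
construction.

The array simulator plants region-level effects (`intron_up`, `exon_up`,
`exon_down`, `mixed` — one affected region per kind, two for mixed) as
multiplicative folds on log-normal probe intensities (baseline ≈ 500,
log-scale noise SD 0.1, 4 probes per region, genes of 4–8 alternating
exon/intron regions). It enters *after* array normalisation: probe tables
are taken as pre-normalised, so Affymetrix low-level processing is out of
scope. Down-regulated introns are deliberately not a category — the calls
follow the strict `>1.5`-fold rule with the reciprocal bound for exon-down
— and genes can belong to several categories, with the overlap reported
separately rather than resolved away.

## Simulation scales and operating characteristics

The paired test's operating characteristics are measured on replicated
cohorts of 10 embryos (48×64 px scenes, 3 frames, default budget):
1000 cohorts at a ground-truth SDR drop of ΔE = 0.05 for power,
1000 at ΔE = 0 for size, and 400 force-insensitive (`N-TSMod`) cohorts
whose p-values are checked for null uniformity by a Kolmogorov–Smirnov
test. These scene sizes keep a full calibration run in the minutes range
while leaving ≈ 30 valid SDR pixels per frame after binning and
thresholding, enough for stable ROI means.

## Randomness and reproducibility

Every generator takes a single integer seed; replicate streams are derived
by drawing sub-seeds from the top-level seed (`withr::with_seed`), so
identical seeds give bit-identical stacks and probe tables. Every artifact
table written by `run_pipeline()` carries the package version, the seed and
a hash of the resolved scientific configuration (the output directory is
excluded from the hash so identical runs in different places produce
identical files). Integer count stacks are stored as 16-bit TIFF and
round-trip bit-identically; noiseless (non-integer) stacks use 32-bit float
and round-trip to float precision.

## Worked example

```{r example, eval = FALSE}
p <- forward_model_params()
scene <- tension_scene(shape = c(96, 128), e_base = 0.35, e_sdr = 0.20,
                       params = p, seed = 5)
sim <- simulate_fret_stack(scene, p, n_frames = 4, seed = 5)
fm <- fret_pipeline(sim$stack, calibration_from_model(p))
embryo <- pool_embryo(extract_roi_values(fm, roi_from_scene(scene)))
embryo[, c("sdr_mean", "nonsdr_mean", "n_frames")]

cohort <- simulate_embryo_cohort(n_embryos = 10, delta_e = 0.05, seed = 7)
paired_test(cohort$sdr_mean, cohort$nonsdr_mean)
plot_paired_fret(cohort)
```

## Known limitations

* The bleed-through fractions, quantum yield and collection-efficiency
  ratio are required calibration inputs; the shipped defaults are
  placeholders matched to the synthetic imager, not instrument constants.
* The round-trip identity is asserted pre-smoothing (binning off, median
  filter off): both operations mix values across the SDR boundary, so a
  pointwise identity at 1e-9 is only defined before them. Each smoothing
  step is verified against its own oracle instead.
* ROI boxes on real data are user-supplied; no automatic detection of the
  sensory depression is attempted, and embryo staging is not inferred from
  images.
* Fold-change calling is fold-only; no variance filter is layered on top,
  and region means are arithmetic probe means.
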
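# fretsplice

Analysis tools for two quantitative read-outs of epidermal mechanics and
its regulation in the *C. elegans* embryo:

1. **Molecular tension mapping** with an intensity-based (sensitized
   emission) FRET tension sensor — a donor/acceptor pair joined by an
   elastic linker inserted into β-spectrin, where stretching lowers the
   transfer efficiency, so *low FRET means high tension*. The package turns
   three-channel confocal stacks into per-pixel FRET-index maps with
   shot-noise uncertainties, and compares the anterior sensory-depression
   region (SDR, where the elongating pharynx pulls on the epidermis)
   against the rest of the embryo in a paired design.
2. **Splicing-misregulation calls** from tiling-array probe intensities:
   exon/intron regions changed more than 1.5-fold between wild type and a
   splicing-factor mutant are classified (`exon_up`, `exon_down`,
   `intron_up`), aggregated to gene level, and tested for enrichment of
   alternatively spliced genes against a ~25% genome background.

Both pipelines come with a synthetic-data module (a force-to-FRET forward
imager with Poisson shot noise and bleed-through mixing; a probe-table
generator with planted splicing effects) so every stage is testable against
known ground truth. The intended users are researchers analysing
tension-sensor imaging or region-level array data who want a tested,
scriptable implementation rather than interactive image-processing macros.

## The core computation

Per pixel, the raw FRET channel is corrected for spectral bleed-through,

```
cF(i,j) = IF(i,j) − δ·ID(i,j) − α·IA(i,j)
```

and converted to the FRET index

```
F = (cF · QD · φD/φA) / (qD + cF · QD · φD/φA)
```

with `qD` the background-subtracted donor channel, `QD` the donor quantum
yield and `φD/φA` the collection-efficiency ratio. The full pipeline is
bin once → subtract background → correct bleed-through → index →
3×3 median filter → intensity threshold, plus first-order propagation of
the Poisson noise model to a per-pixel `σF`. Region calls on the array side
use region-mean probe intensities, the strict `> 1.5`-fold rule (reciprocal
bound for exon-down), and chi-square / exact binomial enrichment tests.

## Worked example

```r
library(fretsplice)

# a synthetic 1.5-fold embryo: cortical FRET 0.35, SDR at 0.20 (high tension)
p     <- forward_model_params()
scene <- tension_scene(shape = c(96, 128), e_base = 0.35, e_sdr = 0.20,
                       params = p, seed = 5)
sim   <- simulate_fret_stack(scene, p, n_frames = 4, seed = 5)
fm    <- fret_pipeline(sim$stack, calibration_from_model(p))
pool_embryo(extract_roi_values(fm, roi_from_scene(scene)))[
  , c("sdr_mean", "nonsdr_mean", "n_frames")]
#>   sdr_mean nonsdr_mean n_frames
#> 1   0.2001      0.3504        4
```

The pooled ROI means recover the planted efficiencies (0.20 / 0.35) to
about ±0.01 at the default photon budget. A cohort of ten embryos with a
ground-truth SDR drop of 0.05 gives the paired comparison:

```r
cohort <- simulate_embryo_cohort(n_embryos = 10, delta_e = 0.05, seed = 7)
paired_test(cohort$sdr_mean, cohort$nonsdr_mean)
#>          method estimate statistic df   p.value
#> 1 paired t-test -0.04512    -63.13  9 3.167e-13
```

i.e. the estimated SDR deficit is −0.045 (truth −0.05) and the paired test
rejects decisively. `autoplot(fm)` shows the index map,
`plot_paired_fret(cohort)` the embryo-wise paired comparison. On the array
side, `simulate_probe_table()` → `region_fold_changes()` →
`classify_regions()` → `aggregate_genes()` → `as_enrichment()` runs the
splicing pipeline; `as_proportion(135, 449)` reproduces the style of
proportion reported for alternatively spliced genes (30%).

`run_pipeline(run_config(...), "simulate-fret")` and friends compose the
same stages into on-disk workflows (TIFF stacks + TSV tables, each stamped
with the seed and a configuration hash).

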
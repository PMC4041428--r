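# slitmap

Single-molecule mapping of protein binding sites on field-stretched DNA
in nanofluidic slits.

## The problem

Where does a DNA-binding protein sit on a genome? `slitmap` implements
the image-analysis half of a nanofluidic single-molecule assay that
answers this directly, one molecule at a time: bacteriophage λ-DNA
(48,502 bp) carrying bound *E. coli* RNA polymerase (RNAP) holoenzyme is
anchored at a micro–nano junction by a streptavidin fluosphere ligated
to its 3′ cos end, stretched into a ~60 nm-deep nanoslit by an electric
field, and imaged in two color channels — YOYO-1–stained DNA backbone
(green) and antibody–quantum-dot (QD)-labeled RNAP (red). Because the
fluosphere fixes both the position and the orientation of every
molecule, each QD's distance from the anchor converts directly into a
base-pair coordinate.

The package covers the full analysis chain plus a synthetic-microscopy
generator with known ground truth:

1. **coords** — the λ coordinate model. With the 3′ end anchored, a
   locus `x` lies at `(48502 − x) · rise` from the fluosphere
   (0.34 nm/bp unstained; 22 µm/48,502 bp stained). The nanoslit
   loop-suppression criterion `U = π k_B T · L_p / 2R > k_B T` (slit
   depth = loop diameter 2R) decides whether hairpin loops are
   suppressed during stretching.
2. **simgen / render** — samples molecules (promoter sites bound with
   probability 0.45, pseudo-promoters 0.30, stretch 0.87 ± 0.03 of the
   stained contour, 70 % end-labeling efficiency, surface-stuck
   contaminant QDs) and renders field-on/field-off two-channel frame
   pairs with Poisson photon noise into multi-page 16-bit TIFFs.
3. **localize** — difference-of-Gaussians spot detection, sub-pixel
   localization by an iterative PSF-weighted centroid (~2.6 nm at
   1,600 photons), backbone segmentation and extension measurement,
   split-view channel registration, and spot→molecule association.
4. **qc** — molecule qualification (fluosphere present, extension
   ≥ 9 µm, ≥ 1 bound QD) and false-positive exclusion by field-reversal
   recoil consistency: a genuine DNA-bound QD rides with the relaxing
   chain when the field is switched off; a surface-stuck contaminant
   does not move.
5. **sitemap** — accepted events are placed on the bp axis
   (`locus = 48502 · (1 − d/extension)`), histogrammed (500 bp bins),
   and fit with a sum of Gaussians (Poisson-weighted nonlinear least
   squares, deterministic residual/split refinement). Site calls carry
   the fitted mean, SD, per-site binding frequency (distinct molecules
   within ±1,500 bp, nearest-peak assignment), and the error against
   the known promoter loci P_R (38,003 bp) and P_L (35,602 bp).
6. **pipeline / cli** — `simulate`, `analyze`, `evaluate` subcommands
   tied together by one YAML config and one master seed.

## Worked example

```r
library(slitmap)

cfg <- default_pipeline_config(seed = 42)
run_simulate(cfg, "sim")                  # 200 molecules, 9 FOV frame pairs
res <- run_analyze("sim", "results", cfg) # localize -> qc -> site calls
ev  <- run_evaluate("results", "sim")     # score against ground truth
```

The run logs its stage counts (`200 molecules segmented, 133
qualified`, `251 accepted binding events`, `5 sites called`) and
`results/comparison.csv` holds the headline table:

| site | class | true locus (bp) | fitted mean | SD (bp) | error (bp) | frequency |
|------|-------|-----------------|-------------|---------|------------|-----------|
| P_R | promoter | 38,003 | 37,846 | 596 | 157 | 0.40 |
| P_L | promoter | 35,602 | 35,565 | 754 | 37 | 0.42 |
| pseudo | pseudo-promoter | 27,649 | 27,458 | 586 | 191 | 0.23 |
| pseudo | pseudo-promoter | 25,620 | 25,328 | 767 | 292 | 0.35 |
| pseudo | pseudo-promoter | 23,619 | 23,443 | 500 | 176 | 0.29 |

Reading it: all five binding sites are recovered; both strong promoters
land within 300 bp of their true loci with fitted SDs under 800 bp;
promoter-class frequencies average ~41 % (configured 45 %) and
pseudo-promoter frequencies ~29 % (configured 30 %); 99.6 % of true
bound QDs are recovered and every surface-stuck contaminant is rejected
by the recoil filter. Equivalent CLI:

```sh
Rscript inst/cli/slitmap simulate --out sim --seed 42
Rscript inst/cli/slitmap analyze  --in sim --out results
Rscript inst/cli/slitmap evaluate --results results --truth sim
```

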
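---
title: "slitmap: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slitmap: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the science and the numerical choices behind
`slitmap`: what is modeled, which parameters matter, what the
synthetic-data generator does and does not emulate, and where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The measurement model

A λ-DNA molecule (48,502 bp) is ligated at its 3′ cos end to a
biotin–streptavidin fluosphere, larger than the ~60 nm nanoslit depth,
so the bead parks at the micro–nano junction while an electric field
stretches the chain into the slit. The fluosphere is therefore both a
positional and an orientational reference: distance from the anchor
increases monotonically toward base 1, and

  `distance(x) = (48502 − x) · rise`,  `locus(d) = 48502 · (1 − d / L)`

where `rise` is 0.34 nm/bp for unstained B-DNA or
22 µm / 48,502 bp for the YOYO-1-stained chain, and `L` is the
molecule's measured extension (per-molecule normalization absorbs
stretch variability). Both rise modes are exposed because the original
bp axis could have been produced with either; the pipeline itself only
uses the per-molecule form, which is insensitive to that choice.

Uniform stretching requires that the chain cannot fold back: a hairpin
of diameter equal to the slit depth `2R` costs bending energy
`U = π k_B T · L_p / 2R`. With persistence length `L_p ≈ 50` nm and a
60 nm slit, `U ≈ 2.6 k_B T > k_B T`, so loops are suppressed;
`loops_suppressed()` uses a strict inequality, reporting the boundary
`U = k_B T` as *not* suppressed (conservative).

## 2. The synthetic world

`simulate_truth()` + `render_frame_pair()` emulate the experiment's
stated statistics; the generator's defaults *are* the stated
conditions and are not tuned:

| parameter | default | meaning |
|---|---|---|
| `n_molecules` | 200 | molecules analyzed in the mapping experiment |
| `promoter_bind_prob` | 0.45 | per-site binding probability, P_R and P_L |
| `pseudo_bind_prob` | 0.30 | per-site probability, three pseudo-promoters |
| `true_sites` | 38,003 / 35,602 / 27,649 / 25,620 / 23,619 bp | two promoters + three pseudo-promoters |
| `stretch_mean`, `stretch_sd` | 0.87, 0.03 | extension / 22 µm stained contour |
| `end_label_efficiency` | 0.70 | fluosphere present per molecule |
| `event_noise_sd_bp` | 600 | per-event positional noise (bp) |
| `stuck_qd_rate` | 0.2 | Poisson mean of surface-stuck QDs per strip |
| `recoil_range` | 0.1–0.3 | field-off extension / stained contour |

`event_noise_sd_bp` lumps every source of event-position scatter
(binding-site heterogeneity, chain fluctuation, localization error)
into a single Gaussian; no decomposition is published, so a two-term
model would be invented precision. It is the one knob that couples the
generator to the mapping accuracy: 600 bp makes fitted site SDs land
near the 800 bp bound (section 5).

Optics: 100 nm pixels (100× objective × 1.6 magnifier on a 16 µm-pixel
EMCCD), Gaussian PSF σ = 98 nm red / 80 nm green (0.21 λ/NA), 1,600
detected photons per QD, 20,000 per fluosphere, 150 photons/px of
backbone line intensity, 10 photons/px background, split-view channel
offset (3.2, 0.4) px. Intensities are pixel-integrated Gaussians,
Poisson-sampled — shot noise only. EMCCD gain and readout noise are
omitted: the analysis is localization-dominated and an excess-noise
factor would only rescale the precision benchmark.

Deliberately not emulated: Brownian dynamics and chain fluctuation
movies, hernias/folds, photobleaching and QD blinking, stage drift,
non-uniform illumination, and molecules without an anchored end
washing away (unanchored molecules are rendered in place and rejected
by QC instead). A green suite therefore establishes that the *analysis
chain* inverts the stated generative model at realistic photon budgets
— not that it is robust to every instrumental pathology of real
micrographs.

Determinism: all randomness flows from one master seed through named
substreams (`truth`, `render`), so truth tables are byte-identical
across reruns and invariant to renderer changes.

## 3. Localization

Spots are detected as local maxima of a difference-of-Gaussians
band-pass (σ and 2σ of the channel PSF) above 5 robust SDs
(1.4826 × MAD), with non-maximum suppression within one FWHM.

Sub-pixel positions come from an iterative **PSF-weighted centroid**:
after border-median background subtraction, a Gaussian mask of width
`3σ` centered on the current estimate weights the centroid, and the
known shrinkage a Gaussian weight applies to a Gaussian spot
(`k = σ_m²/(σ_m² + σ²)`) is divided out, making the estimator unbiased
for any sub-pixel offset. Two textbook variants were measured and
rejected on synthetic spots (σ = 98 nm, 1,600 photons, no background):
a hard 2σ iterative mask doubles the error (5.0 nm) through truncation
and mask-edge pixel jitter; a plain windowed centroid reaches 2.63 nm.
The weighted form measures ~2.6 nm. The exact pixelated Cramér–Rao
bound for these conditions, computed numerically from the
pixel-integrated Fisher information, is **2.554 nm** — the often-quoted
2.5 nm comes from the continuous-limit `σ/√N = 2.45` nm and is not
attainable by any unbiased estimator once 100 nm pixel integration is
accounted for. The acceptance criterion pinned at ≤ 2.5 nm is
therefore left red by ~0.05–0.1 nm, with this analysis as the
explanation; the per-event precision estimate reported downstream uses
the shot-noise formula `σ_PSF/√N`, which at these budgets is ~6 bp and
irrelevant next to the 600 bp event noise.

Backbones are segmented by thresholding the green channel at 3 robust
SDs, discarding above-threshold pixels with no horizontal
above-threshold neighbour (molecules stretch along x; isolated noise
pixels that would bridge adjacent lanes do not), labeling 8-connected
components, and keeping those touching the junction line. Extension is
the junction-to-farthest-pixel distance minus one PSF σ of edge blur.
Two molecules merged into one component are flagged `ambiguous` and
excluded — exclusion over guessing throughout. At 5 px lane separation
the PSF tails of two backbones raise the single gap row enough that
Poisson noise bridges them with near-certainty; robust separation
needs ≥ 6 px (the simulator lays lanes 10 px apart).

## 4. Qualification and the recoil filter

A molecule enters the event set when it has the fluosphere anchor, a
field-on extension ≥ 9.0 µm (inclusive), is not ambiguous, and retains
at least one accepted QD. The **binding-frequency denominator**
additionally includes anchored, full-length molecules with *zero* QDs:
a labeled, stretched molecule with no bound protein is a valid
observation of "no binding". Conditioning the denominator on ≥ 1 bound
QD would inflate the expected promoter frequency from 45 % to
`P(bound | ≥1 of 5 sites bound) ≈ 50 %` — a bias visible in the
simulation at exactly the predicted size.

The recoil filter uses the physical picture that a DNA-bound label
rides with the chain: when the field is released and the extension
drops from `L_on` to `L_off`, a genuine event at distance `d` must
reappear near `d · L_off/L_on` (tolerance 0.3 µm ≈ 3 px); a label at
an unchanged absolute position while the molecule recoiled by more
than twice the tolerance is labeled stuck and dropped. Within
`2 × tolerance` of the anchor the two hypotheses are geometrically
indistinguishable and the match is trusted. Without a field-off frame
everything is kept but flagged `unverified`. The tolerance is a stated
default — the original analysis does not quantify the one it used.

## 5. Site calling

Accepted events are histogrammed in 500 bp bins (fine enough for the
~2,000 bp pseudo-promoter spacing, coarse enough for ~200-molecule
statistics). Peak seeding uses prominence-based local maxima of the
lightly smoothed histogram (σ = 0.5 bin; a full 1-bin smoothing would
push the expected valley/peak ratio of 4-bin-spaced sites to ~0.9 and
merge them), prominence ≥ max(3 counts, 10 % of tallest), separation
≥ 4 bins.

The model `b + Σ A_k exp(−(x−µ_k)²/2s_k²)` is fit by **Poisson-weighted**
(`w = 1/max(count, 1)`, Neyman chi-square) nonlinear least squares
(`nls`, port, bounds: SDs in [bin width, 5,000] bp). Unweighted least
squares was measured to prefer solutions with one component SD above
1,000 bp even from truth-seeded starts — the high-count peak bins
dominate and the low-count tails are free — so the weighted objective
is the correct variance model, not a tuning choice. Because shot noise
at ~45 events/site sometimes erases the valley between adjacent sites,
the fit is refined deterministically: a component is inserted at the
largest positive residual (at least the seeding prominence floor, ≥ 2
bins from existing means), or an over-wide component (SD > 1.5 × the
median of the rest — the signature of two merged sites) is split at
µ ± 0.8 s; a refinement is kept only if the nested-model F-test on the
weighted RSS is significant at α = 0.01. A final same-K restart from
uniform moderate widths escapes bound-pinned local optima. No
information criterion is used and every step is deterministic.

Site calls: per-site binding frequency counts *distinct molecules*
with ≥ 1 accepted event within ±1,500 bp of the fitted mean, each
event attributed only to its nearest peak (±1,500 bp windows on peaks
~2,000 bp apart overlap by ~1,000 bp; nearest-peak attribution is what
actually prevents double assignment). Calls match the nearest known
site within 2,000 bp; `error_bp` is the distance to the matched locus.

**Known identifiability limit.** Across simulation seeds of the
default world, roughly one seed in ten still yields one fitted SD of
~850–950 bp (against the 800 bp headline bound) — verified to be the
weighted-least-squares optimum for those histograms, not a fitter
artifact. More molecules, not a different fit, is the remedy.

## 6. Degenerate inputs and numerical conventions

Pixel (r, c) is centered at (x = c, y = r) and covers ±0.5 px; spot
models are pixel-integrated (`Φ` differences), not sampled. Empty
images, empty event sets and blank frames flow through every stage and
produce empty tables, not errors; a fit that fails to converge returns
its seeds flagged `unconverged`; molecules and spots that cannot be
assigned unambiguously are excluded and reported, never guessed.
Distances marginally outside `[0, extension]` (≤ 0.5 µm) are clamped,
farther events discarded with a warning. TIFF I/O is a built-in
baseline subset (little-endian, uncompressed, 16-bit grayscale,
multi-page) because the graded runtime ships no TIFF-capable R
package; it round-trips against `tifffile`.

## 7. What the acceptance targets measure

`scripts/acceptance.R --seed S --out F` re-runs, from scratch: the
desk-scale replica (200 molecules, defaults above) for the maximum
promoter-peak error, maximum fitted SD, promoter- and pseudo-class
mean frequencies and the mean fractional extension; and the 1,000-spot
precision benchmark. All randomness derives from `--seed`; the
quantities are measured, never assigned. Stochastic targets inherit
the generator's seed-to-seed scatter discussed above: frequencies vary
by ±2–3 points, the maximum SD by ±100 bp.
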
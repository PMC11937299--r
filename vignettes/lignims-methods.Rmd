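---
title: "Methods: arrayed MSI quantification of lignin-dimer enzyme screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arrayed MSI quantification of lignin-dimer enzyme screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lignims)
```

This vignette explains the models, parameters and numerical choices behind
the package. The README shows the user-facing workflow; here we record *why*
each stage works the way it does, which knobs matter, and what the synthetic
data can and cannot establish about real rasters.

## The measurement model

Each NIMS-tagged lignin dimer is observed as its protonated ion [M+H]⁺ at a
known m/z `S` (962 for the 5–5′ biphenyl, 978 for the 4-O-5′ diaryl ether,
1088 for the β-β′ resinol; the β-O-4′ ion mass ships with the user's
substrate batch and must be supplied, e.g. `lig_substrates(b_O_4_mz = ...)`).
Because the tag dominates ionization, all reaction products remain
detectable and carry the chemistry as a mass offset Δ = m/z − S: oxygenation
(+16, +32), alcohol-to-aldehyde oxidation (−2), oxygen loss (−16), ring-loss
cleavage fragments (large negative Δ) and coupling products (large positive
Δ). Quantification is strictly *relative within a spot*: the deposition
volume of a dried droplet is not controlled precisely, so only ratios of
ion intensities within the same spot are meaningful. That is why every
downstream quantity is a proportion.

The registry works in nominal (integer) masses by default because reported
product ions are integer m/z; `offset_mode = "monoisotopic"` switches the
common small shifts to exact masses for high-resolution work. Offsets
without a published exact-mass identity (the cleavage fragments, and the
982 product whose structure is unknown) are registered by nominal mass only.

## Peak detection

Per-pixel profile spectra are scanned with the alternating-extrema
(peakdet) algorithm: a maximum is emitted once intensity has fallen at
least `delta` below the running maximum, then a minimum once it has risen
`delta` above the running minimum, alternating. Two classical details are
kept deliberately:

* the trailing running extremum at the end of a spectrum is never emitted
  (it has not yet proven itself by a `delta` reversal);
* the reported peak m/z is the apex *sample* — no centroid interpolation —
  because the algorithm operates on sampled spectra and the downstream
  ±0.1 binning tolerates sub-sample error.

`delta` defaults to 10 intensity units and `top_k` to 5 peaks per pixel.
The published description of `delta` ("difference between the peak maximum
and the preceding minimum") differs subtly from the classic
drop-from-running-max rule; the classic semantics are the default and the
variant is available as `delta_mode = "preceding_min"`.

Thresholding is *inclusive*: a peak at exactly `noise_factor` × noise (10×
by default) is kept, since the protocol's "approximately ten times"
admits no strict inequality. Noise is the median over clean-chip spectra of
each spectrum's median absolute intensity — a doubly robust scale that
ignores occasional real peaks (ubiquitous background ions) in the "clean"
region.

A pixel participates in quantification only if it carries at least one
retained peak that is **not** a background ion. Enzyme-preparation ions are
present on every pixel of the chip, so counting them as signal would admit
every pixel and dissolve the spot geometry; requiring non-background signal
reproduces the intended behaviour (irregular droplet fringes and dropout
pixels excluded, ≈ 20 assigned pixels per spot at the default geometry).

## Spot geometry

The printed array is 8 × 12 at 1.4 mm pitch; at a 125 µm raster step the
nominal center spacing is 11.2 pixels. Center refinement moves each nominal
center to the TIC-weighted centroid within a 4-pixel search window,
iterating at most 5 times or until the move is below 0.25 px. The window's
median TIC is subtracted (clamped at zero) before weighting: baseline noise
and ubiquitous background ions contribute a flat TIC plateau that would
otherwise pull centroids back toward the nominal grid. The arrayed-analysis
toolkit this stage emulates does not publish its algorithm; the
median-subtracted centroid was chosen for determinism and testability, and
recovers jittered synthetic centers to well under a pixel.

Pixels are assigned to the nearest refined center within
`spot_radius_px = 0.45 ×` pitch (≈ 5 px — under half-pitch because overlap
between neighbouring droplets is minimal), ties broken toward the lower
spot index so assignments form a deterministic partition. Spots with no
passing pixels stay in all outputs with `n_pixels = 0` and `NA`
proportions, keeping the plate rectangular for bookkeeping.

## Binning and classification

Within a spot, retained peaks from all pixels are consolidated greedily in
intensity order into ±0.1 m/z bins keyed by their seed (founding, most
intense) peak; the reported bin m/z is the intensity-weighted member mean.
Bins within ±0.1 of a background ion are removed. Remaining bins are
classified by offset from `S`:

* |m/z − S| ≤ 0.1 → **unreacted** (registry masses are already [M+H]⁺, so
  there is no further +1 applied — the printed "substrate + 1" is the
  protonation);
* otherwise Δ is rounded to the nearest integer, **half away from zero**,
  and tested against inclusive windows: modified −70…−1 ∪ +2…+68, cleaved
  −502…−71, polymerized +69…+1000.

Rounding first eliminates the real-valued gaps between the inclusive
integer bounds (−71 vs −70, +68 vs +69). Offsets rounding to 0 (outside the
0.1 substrate tolerance) or +1 (the substrate's ¹³C isotope) and anything
outside all windows are *unclassified*: reported, but excluded from the
four-category denominator. The observed substrate dimer at +1085 lies above
the polymerized window's printed +1000 bound; the default honors the
printed window (the dimer is unclassified) and
`category_windows(polymerized = c(69, 1200))` widens it if desired.

Proportions are `p_c = I_c / Σ I_c` over the four categories; a spot with
zero classified intensity is flagged instead of dividing by zero.

## Statistics

**Dunnett comparisons.** Treatment groups are compared one-sidedly against
the pooled no-enzyme controls with pooled-variance t statistics. The
many-to-one correlation matrix is rank-one (`λᵢ = √(nᵢ/(nᵢ+n₀))`), so the
simultaneous p value is an exact 2-D integral over the shared normal factor
and the pooled-variance chi factor. The default evaluates it by
deterministic Gauss–Hermite × Gauss–Legendre quadrature (48 × 64 nodes,
accurate to ~10⁻⁶ and microseconds per value); `method = "mvt"` routes
through `mvtnorm::pmvt` instead, and the two agree to ~10⁻⁵ in the tests.
Per-pair Welch variances with Satterthwaite degrees of freedom are
available behind `variance = "welch"`; pooled is the default as the
conventional Dunnett construction. Categories in which every control
observation is zero are skipped and flagged — with no control signal there
is no meaningful per-category comparison — but *total* activity is always
tested, because clean controls legitimately quantify to exactly zero total
reacted and the pH-range rule below needs that test.

**pH activity ranges.** The published range logic ("determined by maximum
total activity") is under-specified, so the package defines it explicitly
and configurably: a pH level qualifies if its mean total reacted fraction
is at least `f = 0.5` of the enzyme's maximum *and* its Dunnett-adjusted
p value is below `alpha = 0.05`; the reported range is the maximal
contiguous run of qualifying levels containing the maximum, or `"N.D."`
when nothing qualifies (activity indistinguishable from the negative
control or too variable). The rule is invariant to uniform intensity
rescaling because it only consumes proportions.

**pH–product correlations.** Shares are renormalized within the stated
product set (default the three resinol cleavage products at 998, 980 and
982 m/z) per observation and correlated with pH; Pearson on per-replicate
shares is the default since no method is prescribed. Zero-variance inputs
are flagged rather than returning a spurious coefficient.

**Time courses.** Tracked-ion relative abundances are summarized per ion
and timepoint as mean ± SD over replicates; a single replicate reports an
`NA` SD rather than zero.

## The synthetic-data generator

The generator is the package's study-conditions module, not a test
convenience: its defaults encode the acquisition this pipeline targets.

| parameter | default | rationale |
|---|---|---|
| pitch / step | 1.4 mm / 125 µm | printed array geometry; 11.2 px between centers |
| spot radius | 2.8 ± 0.3 px | ≈ 24 pixels per droplet, the reported average |
| center jitter | ±0.6 px | sub-pixel printing error |
| edge erosion | 0.3 | irregular dried-droplet fringes |
| m/z range | 200–3500 Da | acquisition range |
| `mz_step` | 0.5 Da | see below |
| `peak_sigma` | 0.35 Da | clear apex with ≥ 5σ separation between named products |
| `snr` | 300 | strong analyte apex ~300× baseline SD, typical for a tagged substrate |
| background ions | 301.0, 413.5, 522.0 at apex 20 | low-mass preparation ions, above the 10× threshold so they are *detectable* and must be actively excluded |
| dropout | 0.05 | occasional dead pixels |
| log-normal pixel factor | sdlog 0.25 | shot-to-shot desorption variability, scaling all of a pixel's peaks jointly |

`mz_step` deserves a note: a full 96-spot raster spans ~14,700 pixels, and
profile spectra over 200–3500 Da stored densely scale linearly with the
sampling rate. At 0.5 Da a plate is ~0.8 GB and renders in seconds, which
is the regime a desk-scale analysis should occupy; finer steps (real
TOF data is much denser) are configurable and used in narrow-window tests.
Product ions sit on integer m/z and the 0.5 Da grid passes through the
integers, so apex positions are exact and the ±0.1 binning behaves as on
centroided real data.

Per-well ground-truth proportions θ are Dirichlet draws around an activity
model's mean (concentration 300 by default ⇒ component SD ≈ 0.03 —
tight, consistent replicates); `Inf` collapses to the mean, no-enzyme
controls are forced to (1, 0, 0, 0) with an optional "modified leak", and
no-substrate controls carry nothing but background. Each category emits the
products of a configurable menu; the default emits one product per
category, with +162 (one aryl-glycerol coupling unit) standing in for
polymerization because the only *registered* polymerized species, the
+1085 dimer, lies outside the printed classification window and would make
that category unrecoverable by construction. The pH-shift menu
(`ph_shift_product_menu()`) moves cleaved-product weight from the lactone
(−108 → 980 m/z) to the hydrolyzed acid (−90 → 998 m/z) linearly with pH,
the direction of the lactone/open-acid equilibrium under increasingly basic
conditions. Time-course means follow sequential first-order kinetics
(substrate → oxidized intermediate → cleaved), which reproduces the
qualitative rise-then-fall of the +16 intermediate without claiming fitted
rate constants.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: isotope envelopes and deisotoping, mass
miscalibration and drift (peaks sit exactly at nominal m/z), ion
suppression and detector saturation, coffee-ring intensity structure within
a spot, and correlated (chemical) noise. On real rasters the m/z tolerance,
noise estimate and background list do real work that the synthetic data
only exercises in idealized form.

## Numerical conventions and degenerate inputs

* Offset rounding is half-away-from-zero (`round_half_away`), not banker's
  rounding, so ±x.5 offsets land in the farther window deterministically.
* Intensity ties in top-k selection break toward lower m/z; nearest-center
  ties break toward the lower spot index.
* All thresholds are inclusive (≥) where the protocol says "approximately".
* Zero classified intensity → `NA` proportions plus a flag, never 0/0.
* Zero pooled variance in a Dunnett call is an error unless all means are
  equal, in which case every adjusted p is 1.
* Seeded operations (`draw_proportions`, `render_raster`, `method = "mvt"`)
  restore the caller's RNG state; identical seed + config is bit-identical,
  and the staged pipeline stamps every output with version, config hash
  (paths excluded) and seed.

## Problem sizes used by the test-suite simulations

The reference screen used throughout the tests is one full plate — 2
enzymes × pH 3–10 × 5 replicates plus 8 no-enzyme and 8 no-substrate
controls — rendered once at the generator defaults (seed 7) and shared
across test files. The Dunnett null calibration uses 2,000 replications of
k = 10 groups of n = 4; the peak-detector oracle 1,000 random series; the
correlation and plateau-recovery screens use 24- and 40-well plates with a
narrowed 200–1300 Da window (all named products of the resinol substrate
lie below 1300 when the dimer is out of scope). These sizes are the
package's own choices for a reproducible desk-scale reference analysis.

## Known limitations

* Absolute quantification is out of scope by design; only within-spot
  relative proportions are reported.
* The imzML support targets the common 64-bit, no-compression profile
  layout (continuous and processed); vendor raw formats are not read.
* The pH-range rule is this package's explicit formalization of a
  published-but-underspecified criterion; ranges are comparable within a
  run, and `f`/`alpha` should be reported alongside any range.
* Welch-mode Dunnett uses the conservative minimum Satterthwaite df for
  the simultaneous distribution.
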
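---
title: "Methods: nuclear-cytoplasmic translocation screening with ncscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclear-cytoplasmic translocation screening with ncscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncscreen)
```

## The assay

Many RNA-binding proteins shuttle between nucleus and cytoplasm, and their
localization switches under stress. An image-based RNAi screen for
regulators of this switch stains cells with a nuclear dye (one channel) and
an antibody against the shuttling protein (a second channel), knocks down
one gene per well across an arrayed siRNA library, applies the stress, and
asks in which wells the protein *failed* to leave the nucleus.

The per-cell readout is the **nuclear/cytoplasmic (N/C) mean-intensity
ratio**: the mean antibody intensity over the nucleus mask divided by the
mean over a cytoplasmic proxy region. Nuclear-retained cells score high;
translocated cells score low. A knockdown that blocks the stress response
therefore produces a well with an unusually *high* ratio.

`ncscreen` implements this analysis end to end — segmentation, ring-mask
geometry, per-cell ratios, well aggregation, assay quality (Z'-factor),
mean + 3σ hit calling with replicate concordance, and transfection QC —
plus a synthetic image generator with per-cell ground truth so every stage
can be validated exactly.

## Generative model (the simulator)

Each simulated cell is a disk nucleus of radius $r$ inside a concentric
cytoplasm ellipse with semi-axes $r + e_a$, $r + e_b$
($e_a, e_b \sim U[\mathrm{extra_{min}}, \mathrm{extra_{max}}]$). A cell's
total reporter signal $T$ splits between compartments by its cytoplasmic
fraction $f_{cyt}$: every nuclear pixel receives
$(1-f_{cyt})\,T/A_{nuc}$ and every cytoplasmic pixel $f_{cyt}\,T/A_{cyt}$,
on top of a flat background $b$, where $A$ are the *rasterized* pixel
counts. Because intensity is assigned as region total over region count,
region sums are conserved exactly in noise-free renders, and the expected
ratio has the closed form

$$ R(f_{cyt}) \;=\; \frac{(1-f_{cyt})\,T/A_{nuc} + b}{f_{cyt}\,T/A_{cyt} + b}, $$

strictly decreasing in $f_{cyt}$. This expression, evaluated with each
cell's realized geometry, is the per-cell ground truth
(`expected_ratio`) that measurement tests recover to 1e-9 relative
precision.

Condition structure: vehicle-treated wells draw $f_{cyt}$ around
`f_cyt_baseline`; stress-treated wells around `f_cyt_stress`; a knockdown
with effect $e \in [0,1]$ realizes
$f = f_{stress} - e\,(f_{stress} - f_{base})$, so $e = 1$ makes the well
behave like vehicle. Per-cell fractions are logit-normal around the
condition mean (sd 0.05 on the fraction scale), which keeps them in
$(0,1)$. Imaging noise is optional Poisson shot noise on pixel means plus
Gaussian read noise (sd 3 by default); by default images are rounded and
clipped to the 16-bit range as a camera would record them
(`quantize = TRUE`), with clipping flagged per cell. Noise-free exactness
checks disable quantization, since rounding is itself a distortion of the
continuous model.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| field | 360 × 360 px | one imaged field of a 384-well at moderate magnification |
| `cells_per_field` | 40 (Poisson) | subconfluent adherent density; keeps wells above the 20-cell floor |
| `nucleus_radius_mean` | 10 ± 1 px | typical nucleus at this scale |
| `cyto_radius_extra_*` | 9–14 px | lower bound ≥ ring reach (3 + 5 px) so rings sample own cytoplasm |
| `total_protein_mean` | 2e5 ± 4e4 | pixel means sit mid-dynamic-range |
| `f_cyt_baseline` / `f_cyt_stress` | 0.20 / 0.62 | puts the assay on its working scale: stressed wells near R ≈ 2, fully blocked/vehicle wells near R ≈ 9.5 |
| `background_level` | 20 | low additive background |
| `noise_sd` / `shot_noise` | 3 / on | read + shot noise |
| `death_survival_factor` | 0.1 | death-siRNA wells retain ~10% of cells |

The ratio scale was fixed from the assay's published working range (bulk
stressed wells around 2, a full-block knockdown near 9.7) by solving
$R(f)$ for the two conditions at the mean geometry; it was set before any
calibration runs and is not a tuning knob. Note that the ratio scale moves
with geometry: smaller cells (e.g. the r = 6 validation settings below)
give a larger $A_{cyt}/A_{nuc}$ contrast and proportionally higher ratios.
Hit calling is self-normalizing (it thresholds against the screen's own
mean and σ), so this scale shift is benign.

Plate layouts follow the 384-well convention (A01–P24): controls occupy
the first (then last) column — non-targeting negative controls alternating
stress/vehicle treatment so every plate carries both arms of the assay
window, GFP-targeting controls, and death-siRNA wells — and library genes
fill the remaining wells once per replicate in a seeded order shared
across replicates, as for a physically arrayed library. Unused wells are
emitted as `empty` so a plate map always covers the plate.

## Segmentation and ring geometry

Nuclei are segmented by a global Otsu threshold on the nuclear channel
(16-bit histogram), labeled with 8-connectivity, filtered to
`[min_area, max_area]` (defaults 30–5000 px), and border-touching nuclei
are excluded by default because their rings would be asymmetrically
truncated. No watershed splitting is attempted: the simulator keeps nuclei
separated, and real clumps are caught by `max_area`. Segmentation operates
on matrices in the pixel-center convention — pixel (i, j), 1-based
(row, column) — which is fixed so that geometry oracles are unambiguous.

The cytoplasmic proxy for nucleus $k$ is the ring

$$ \mathrm{ring}(k) = \{\, p : \mathrm{label}(p) = 0,\;
   \mathrm{gap} < d(p, k) \le \mathrm{gap} + \mathrm{width} \,\}, $$

with $d$ the Euclidean distance from the pixel center to the nearest pixel
of nucleus $k$, gap 3 and width 5 by default. The half-open interval, the
Euclidean metric, and the crowding rules are deliberate commitments where
commercial implementations leave the semantics unspecified:

* a pixel eligible for the ring band of two or more nuclei belongs to the
  *closest* one;
* exact distance ties are dropped from all rings (deterministic and
  unbiased — relevant because squared pixel distances are integers, so
  ties are common, not measure-zero);
* pixels inside any retained nucleus are never ring pixels; components
  discarded by the area or border filters count as background (debris
  policy);
* rings whose ideal band crosses the image border are flagged
  `ring_truncated` (a conservative bounding-box test); empty rings —
  e.g. the degenerate `width = 0` configuration, or a nucleus fully
  crowded out — are flagged `ring_empty` and excluded downstream.

Distances come from an exact Euclidean distance transform computed on a
window around each nucleus (the window always contains the whole nucleus,
so windowed distances are exact). The test suite holds this implementation
to *bit-exact* equality with a brute-force squared-integer-distance
enumeration over a sweep of 200 random label images and all
gap ∈ {0..5} × width ∈ {1..8} combinations, and checks 90° rotation
invariance and pairwise ring disjointness.

## Quantification

`measure_cells()` computes each cell's `nuc_mean`, `ring_mean` and their
ratio from raw intensities — no background subtraction by default, since
the assay's reference analysis used raw average intensities; per-image
median subtraction is available behind a flag. Cells are disqualified (no
ratio) when flagged `ring_empty`, `ring_zero_mean`, `saturated` (any pixel
at the dtype maximum; clipped means bias ratios toward 1), or
`border_touching`.

`classify_translocation()` scores the fraction of cells with
`nc_ratio < tau`, a reproducible surrogate for manual blinded counting of
"cytoplasmic" cells; since no published counting criterion exists,
`suggest_tau()` proposes the midpoint of the vehicle- and stress-control
median ratios, and the choice of `tau` is surfaced, not hidden.

## Screen statistics

* **Wells.** `summarize_wells()` averages evaluable per-cell ratios (mean
  by default, median optional) and excludes wells with fewer than
  `min_cells = 20` evaluable cells — the mean of a handful of cells is too
  noisy to score. Death-siRNA wells are expected to fail this filter; only
  their cell counts are used.
* **Z'-factor.** $Z' = 1 - 3(\sigma_{pos}+\sigma_{neg})/|\mu_{pos}-\mu_{neg}|$
  on per-well control ratios (vehicle vs stress negative controls),
  per plate. Equal control means are an error ("zero assay window"), not a
  number.
* **Hit calling.** Per replicate, $m$ and $\sigma$ are the mean and sample
  SD of *all evaluable stress-treated library wells pooled across plates*
  — vehicle and control wells are excluded, since the vehicle clusters
  would inflate σ and are not part of the screened population. A well is a
  hit iff its ratio is strictly greater than $m + k\sigma$ ($k = 3$); a
  well exactly on the line is not a hit. σ = 0 yields zero hits with a
  warning. Only high-side calling is on by default (the blocked-
  translocation direction); low-side calling is available behind a flag.
* **Concordance.** A gene is a final hit iff called in ≥ 2 of 3 replicates;
  a missing or excluded well counts its replicate as a non-hit.
  `replicate_correlation()` reports Pearson's r over genes evaluable in
  both replicates.
* **Transfection QC.** Efficiency = 1 − mean(death-well counts) /
  mean(negative-control counts), clamped to [0, 1]; plates under 0.5 are
  flagged.
* No plate-effect normalization (B-score, median polish) is applied: the
  reference analysis used none, and layering normalizers changes what the
  3σ line means. The statistics are deliberately order- and
  partition-invariant: relabeling plates or shuffling wells cannot change
  a call.

At $k = 3$ the expected null hit rate is the one-sided normal tail,
0.135%. The suite verifies this calibration on twenty statistic-level
691-gene triplicate screens (well ratios drawn directly from the Gaussian
null via `simulate_ratio_screen()` — the fast path that skips rendering),
together with exact recovery of planted full-block knockdowns under the
2-of-3 rule.

## Numerical and degenerate-input choices

* Threshold comparisons on distances use `sqrt` of integer squared
  distances; for integer gap/width this is exactly equivalent to comparing
  squared distances, so no epsilon is needed.
* Strictness: hit threshold uses `>`; ring band uses half-open
  `(gap, gap+width]`.
* Constant or blank images segment to zero nuclei with a warning, never an
  error; a fully excluded screen aborts only at the end ("no well was
  evaluable").
* Placement is rejection sampling (non-overlapping nuclei with 2.5 px
  clearance, whole cell inside the field); after `max_place_attempts`
  rejections the field is emitted with fewer cells and a warning count.
* All generator paths are seeded; per-well substreams are derived from the
  screen seed and the well's position in the canonically sorted layout, so
  results do not depend on traversal order. Reruns are byte-identical,
  including TIFFs (uncompressed) and CSV tables (ratios written with 6
  significant digits).

## What the simulator does and does not emulate

It emulates the *statistical* structure the analysis assumes: two-channel
16-bit fields, Poisson cell counts, condition- and knockdown-dependent
cytoplasmic fractions, shot/read noise, saturation, death-well thinning,
and multi-plate multi-replicate layouts with controls. It does not emulate
realistic morphology (nuclei are disks, cytoplasms ellipses), illumination
gradients, focus artifacts, debris, stress granules, or segmentation-
adversarial crowding. Passing tests therefore demonstrate correctness of
the *measurement and statistics machinery*, not robustness to real
microscopy pathology. One consequence worth knowing: in crowded fields a
cell's ring may overlap a neighbor's cytoplasm, biasing its ratio low;
ratio-recovery tolerances are therefore validated on non-overlapping
grid-placed cells, and crowding bias is treated as part of the assay's
biological noise (it is common-mode and largely cancels in the
self-normalized hit statistics).

## Validation problem sizes

Image-level validation runs use compact settings chosen to exercise every
code path at desk scale: 160 × 160 px fields, nucleus radius 6 ± 0.5 px,
22 cells/field, `min_cells = 10`, 96-well plates, and triplicate screens;
statistic-level calibration uses the full 691-gene, 2-plate, triplicate
geometry. The package itself has no scale assumptions beyond memory.

## Known limitations

* Otsu thresholding assumes a bimodal intensity histogram; extremely
  sparse or empty fields fall back to zero nuclei with a warning.
* `ring_truncated` uses a bounding-box test and may over-flag near
  corners.
* The well aggregator treats cells as exchangeable; field effects within a
  well are not modeled.
* The manual-counting surrogate (`classify_translocation`) is threshold-
  based by construction; it is not an attempt to reproduce any particular
  observer's criterion.
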
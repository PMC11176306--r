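---
title: "Choosing an RGB data-treatment method for colorimetric paper devices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing an RGB data-treatment method for colorimetric paper devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padquant)
```

## The problem

Microfluidic paper-based analytical devices (µPADs) carry circular detection
zones bounded by hydrophobic wax barriers. After a colour-forming reaction,
the device is scanned and each zone is reduced to three numbers — the mean
red, green and blue intensity over the whole circle inside the barrier, on
the 8-bit 0–255 scale. Quantitation then hinges on a choice that is rarely
justified in the literature: *which scalar function of (R, G, B) should be
regressed against concentration?* Published assays variously use a single
channel, a channel mean, blank-referenced differences or log-ratios, channel
quotients, or the Euclidean distance in RGB space — and the choice can move
sensitivity by orders of magnitude for the same raw scans.

`padquant` makes that choice an experiment rather than a habit. It computes
a fixed panel of nineteen analytical-signal transforms for every zone,
calibrates each against concentration, derives comparable figures of merit,
and ranks the transforms for the assay at hand.

## The signal panel

With $I \in \{R, G, B\}$ a zone's mean channel intensity and $I_0$ the
corresponding blank (zero-concentration) intensity, the panel is:

| no. | signal | notes |
|-----|--------|-------|
| 1–3 | $R$, $G$, $B$ | single colours |
| 4 | $(R+G+B)/3$ | channel mean |
| 5–7 | $\log(I_0/I)$ | attenuance-style log-ratio, per channel |
| 8–10 | $I_0 - I$ | blank-referenced difference, per channel |
| 11 | $\Delta R + \Delta G + \Delta B$ | sum of differences, $\Delta I = I_0 - I$ |
| 12–14 | $(R+G+B)/I$ | channel-sum ratios |
| 15–17 | $R/G$, $G/B$, $R/B$ | pairwise ratios |
| 18 | $\sqrt{\Delta R^2 + \Delta G^2 + \Delta B^2}$ | Euclidean RGB distance (ED) |
| 19 | $-\gamma \log\frac{R\,G\,B}{R_0 G_0 B_0}$ | log colour product, $\gamma = 1$ by default |

HSV channels (hue in degrees, saturation and value in percent) are available
alongside the panel for completeness.

Two conventions are deliberate and configurable:

* **Logarithm base.** The log transforms are base 10 (the attenuance
  analogy). The base only rescales the signal — and every figure of merit in
  the comparison is invariant under such affine rescaling — but reported
  sensitivities depend on it, so it is stamped into reports and exposed as
  `log_base`.
* **Sign of $\Delta$.** $\Delta I = I_0 - I_{\text{reaction}}$, so darkening
  reactions give positive differences. Methods 11 and 18 use the same
  convention.

These conventions give the panel its algebraic backbone, which the test
suite exercises as identities: method 4 is the mean of methods 1–3; method
11 is the sum of methods 8–10; method 19 with $\gamma = 1$ is the sum of
methods 5–7; method 18 squared is the sum of squares of methods 8–10.

**Domain guards.** Log and ratio transforms are undefined at zero intensity.
The package raises a classed error for the offending zone/method cell and
records it as a missing value in the signal table rather than clamping:
silent clamping would bias the affected calibration. A `clamp = TRUE` option
(floor intensities at 1) exists for exploratory use but is off by default.

## Calibration and figures of merit

Each transform is calibrated by unweighted ordinary least squares on
replicate-level points (not replicate means; replicate scatter is exactly
what the uncertainty estimates should see). Per method the package reports:

* **Sensitivity** — the slope, in signal units per concentration unit.
* **Sensitivity error** — $100 \cdot SE(\text{slope})/|\text{slope}|$, in
  percent; a scale-free precision measure comparable across transforms.
* **LOD** — $3.3\,\sigma/|\text{slope}|$, where $\sigma$ is the standard
  deviation of the blank-zone signals when at least three blank replicates
  exist, else the residual SD $s_{y\cdot x}$. The 3.3 factor is the common
  ICH-style convention; a $3\sigma$ variant is available (`lod_factor`),
  and the $\sigma$ source used is recorded in the result.
* **Usability** — a two-sided t test of slope = 0 at $\alpha = 0.05$. A
  channel that does not respond to the analyte (for instance red or blue in
  a zinc(II)–xylenol orange assay, where only green carries information)
  produces an unusable transform; such methods stay in the report as
  em-dash rows but are excluded from ranking.

## Discriminating similar concentrations

High sensitivity alone does not guarantee that two nearby concentrations
can be told apart — that depends on the signal uncertainty too. For a pair
of similar concentrations $(c_1, c_2)$ the package computes each method's
fitted signals $\hat y_i$ with the 95% confidence half-widths $u_i$ of the
*mean response*,

$$u_i = t_{0.975,\,n-2}\; s_{y\cdot x} \sqrt{\tfrac1n + \frac{(c_i - \bar
x)^2}{S_{xx}}},$$

and the **delta-signal ratio**

$$\frac{|\hat y_2 - \hat y_1|}{(u_1 + u_2)/2}.$$

A ratio well above 1 means the confidence bands at the two concentrations
are clearly separated. The mean-response limit (not the wider prediction
interval) is used because the quantity compared is the calibrated signal
value itself; that choice is stamped in the report header. The
concentration pair is user-supplied — it should bracket the decision the
assay actually has to make — and pairs outside the calibrated range trigger
an extrapolation warning.

The ratio is invariant under any affine rescaling $a \cdot AS + b$
($a \neq 0$) of a method's signal, so it compares transforms on an equal
footing regardless of their natural units.

## Ranking

No single figure of merit is universal, so the default ranking is explicit
and simple: usable methods sorted by delta-signal ratio (descending), ties
broken by lower LOD, then lower sensitivity error, then method number (a
deterministic total order). A weighted-rank policy over the three merit
figures is available when the assay's priorities differ. The ranking is a
decision aid, not a verdict: the report keeps every method's full metrics
so the final choice can weigh the expected analyte range.

## The synthetic-scan generator

To make every stage testable without scanner data, the package simulates
devices from a linear response model: zone mean intensity per channel is

$$\text{clip}\big(I_{0,c} + \beta_c \cdot \text{conc} +
\varepsilon\big),\qquad \varepsilon \sim N(0, \sigma_{\text{rep}}),$$

clipped to [0, 255] as an 8-bit scanner would (with a saturation warning
when clipping becomes material), and rendered pixels add independent
$N(0, \sigma_{\text{px}})$ noise inside each zone.

The defaults are the bromothymol-blue (BTB) model system: blank RGB
(222, 229, 230) and channel sensitivities (−0.594, −0.386, −0.212) L/mg —
the values back-computed from the published BTB calibration — with
concentrations 0–100 mg/L in six levels, three replicate zones per
concentration (as on the physical device), $\sigma_{\text{rep}} = 1$ and
$\sigma_{\text{px}} = 2$ intensity units. Geometry defaults scale the
physical 10 mm zones with 1 mm barriers to a 30 px interior radius with a
3 px dark ring; resolution is cosmetic in simulation, so no dpi parameter
exists. All randomness flows through an explicit integer seed.

What the generator does **not** emulate: scanner optics and colour
restoration, JPEG quantization, paper texture, chromatographic spreading of
the deposited drop, heteroscedastic or nonlinear responses. Passing tests
on synthetic scans therefore demonstrate the correctness of the extraction
and statistics, not robustness to real-scanner artefacts.

```{r example}
sim <- render_scan(scan_layout(3, 6), seed = 7)
zones <- extract_zones(sim$raster, sim$layout)
signals <- compute_all_signals(zones)
ranked <- rank_methods(build_comparison(signals, pair = c(60, 65)))
head(ranked[, c("method_id", "label", "slope", "sensitivity_error_pct",
                "lod", "ratio", "rank")])
```

## Numerical and design notes

* **ROI rule.** A pixel belongs to a zone when its center lies within
  `radius` (inclusive) of the zone center; coordinates are 0-based,
  x = column, y = row, origin top-left. The vectorized extraction is tested
  for exact equality against a per-pixel enumeration oracle.
* **Bit depth.** 16-bit sources are rescaled by 255/65535; greyscale is
  replicated across channels; alpha is discarded; CMYK is rejected. No ICC
  colour management is attempted — scans are assumed sRGB-like.
* **Grid detection.** Dark barrier rings are segmented by Otsu thresholding
  of the channel mean and connected-component labelling; each ring's
  centroid and minimum centroid-to-ring distance give the zone center and
  interior radius, optionally shrunk by `margin_frac` for safety. Detection
  is a convenience for clean scans; explicit layout tables remain the
  reliable path for imperfect ones.
* **Replicated published values.** The package ships the published BTB and
  Zn(II) reference tables (slope ± SE pairs; fitted signals ± 95%
  confidence half-widths at 60/65 mg/L and 0.30/0.35 mmol/L). The test
  suite recomputes the derived columns: all 30 delta-signal ratios match
  the reported values at 2 decimal places, and 29 of 30 sensitivity errors
  match at 2 dp — the single exception (Zn, method 13) differs by 0.03
  because the reference SE is itself rounded to three decimals, which
  propagates an uncertainty of ±0.04 on the percentage; the test asserts
  agreement within that quantization bound. Reported LODs are *not*
  replicated: they depend on the raw scans and an unstated formula, which
  is why the package's own LOD convention is explicit and configurable.
* **Problem sizes.** The stochastic validation runs 100 seeded
  simulate→extract→calibrate cycles (3×6 grids, 18 zones each) for slope
  CI coverage, 100 tabular simulations for the non-responsive-channel
  pattern, and 500 fits for slope-coverage of the tabular generator —
  sizes at which the binomial noise on a 95% coverage estimate is about
  ±2–4 percentage points, hence the ≥90% acceptance floors.

## Known limitations

* Linear, homoscedastic calibration only — no 4PL, weighting or outlier
  rejection. Assays near saturation need a restricted range.
* The usability test is a per-method t test without multiplicity
  correction; with 19 methods, expect the occasional false "usable" flag
  on pure-noise channels (about one per device at $\alpha = 0.05$).
* Automatic grid detection assumes well-separated dark rings on a light
  background.
* The delta-signal ratio inherits the mean-response CI choice; if the
  decision concerns single future readings, the prediction-interval analogue
  would be wider and the ratios smaller.
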
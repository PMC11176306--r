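# padquant

Quantitation of colorimetric microfluidic paper-based analytical devices
(µPADs) from RGB scans — and, above all, a principled answer to the question
*which RGB data-treatment method should this assay use?*

## The problem

A µPAD detection zone — a circle of filter paper inside a wax barrier —
changes colour with analyte concentration. A flatbed scanner reduces each
zone to mean red, green and blue intensities (0–255). The analytical signal
regressed against concentration can then be defined in many ways, and the
choice matters: for the same scans, different transforms differ by orders of
magnitude in sensitivity and, more importantly, in their ability to
distinguish similar concentrations.

`padquant` computes a panel of nineteen transforms for every zone and
compares them head-to-head. With a zone's channel means $I \in \{R,G,B\}$
and blank (zero-concentration) means $I_0$, the panel covers: single
colours ($R$, $G$, $B$); the channel mean $(R{+}G{+}B)/3$; per-channel
log-ratios $\log(I_0/I)$ and differences $\Delta I = I_0 - I$; the sum
$\Delta R{+}\Delta G{+}\Delta B$; channel-sum ratios $(R{+}G{+}B)/I$;
pairwise ratios $R/G$, $G/B$, $R/B$; the Euclidean RGB distance
$ED = \sqrt{\Delta R^2 + \Delta G^2 + \Delta B^2}$; and the log colour
product $-\gamma\log\frac{RGB}{R_0G_0B_0}$. HSV channels are available
alongside.

Each transform is calibrated by ordinary least squares and summarized by
its sensitivity (slope), relative sensitivity error
$100\cdot SE(\text{slope})/|\text{slope}|$, detection limit
$3.3\,\sigma/|\text{slope}|$, and the **delta-signal ratio**: the absolute
difference of the fitted signals at two similar concentrations divided by
the average of their 95% confidence half-widths. Methods whose slope is
statistically indistinguishable from zero are flagged unusable. The usable
methods are ranked (delta-signal ratio first, detection limit and
sensitivity error as tie-breaks) to recommend a data treatment for the
assay.

## Worked example

A synthetic scan of a 3 × 6 grid of zones (six concentrations of a
bromothymol-blue-like dye, 0–100 mg/L, three replicates each) is rendered,
the zones extracted, the full signal panel computed, and the methods ranked
by their ability to discriminate 60 from 65 mg/L:

```r
library(padquant)

sim     <- render_scan(scan_layout(3, 6), seed = 7)
zones   <- extract_zones(sim$raster, sim$layout)
signals <- compute_all_signals(zones)
ranked  <- rank_methods(build_comparison(signals, pair = c(60, 65)))
head(ranked[, c("method_id", "label", "slope", "sensitivity_error_pct",
                "lod", "ratio", "rank")])
#>   method_id            label    slope sensitivity_error_pct  lod ratio rank
#> 1        11         dR+dG+dB  1.18539                 0.962 6.45  6.73    1
#> 2         4        (R+G+B)/3 -0.39513                 0.962 6.45  6.73    2
#> 3        18               ED  0.72290                 1.029 3.59  6.29    3
#> 4         2                G -0.39525                 1.306 4.35  4.96    4
#> 5         9             G0-G  0.39525                 1.306 4.35  4.96    5
#> 6        19 -log(RGB/R0G0B0)  0.00255                 1.460 5.80  4.43    6
```

Reading the output: the sum-of-differences signal recovers a sensitivity of
1.185 intensity units per mg/L with a 0.96% relative error and an 6.5 mg/L
detection limit, and separates 60 from 65 mg/L by 6.7 times the average
signal uncertainty. Note the algebraic family structure the comparison makes
visible: methods 11 and 4 are affine transforms of one another, so their
relative error, LOD and ratio coincide exactly while their slopes differ by
a factor of −3.

The same statistics apply directly to published fitted signals. The
Euclidean-distance row of the reference BTB table (fitted signals at 60 and
65 mg/L):

```r
delta_signal_ratio(fitted_signal(50.54, 1.09), fitted_signal(54.24, 1.09))
#>   s_low u_low s_high u_high delta_signal    ratio ratio_2dp
#> 1 50.54  1.09  54.24   1.09          3.7 3.394495      3.39

round(sensitivity_error_pct(-0.594, 0.018), 2)   # single-colour R slope ± SE
#> [1] 3.03
```

A ratio of 3.39 means the two concentrations are separated by well over
three times their average 95% uncertainty — comfortably distinguishable —
whereas a ratio near or below 1 (several single-channel methods) means the
confidence bands overlap.

## Command line

The same pipeline is scriptable via the installed `exec/padquant` wrapper
(or `run_cli()`):

```sh
padquant simulate --out-dir run1 --seed 7
padquant extract  --image run1/scan.tiff --layout run1/layout.csv --out run1/zones.csv
padquant analyze  --rgb run1/zones.csv --pair 60,65 --out-dir run1
```

`analyze` writes the full signal table, a comparison CSV and a text report
with the analysis choices (log base, LOD factor, confidence-limit type)
stamped in its header. `analyze --from-fitted` replays externally fitted
`signal ± CI` tables through the delta-signal-ratio statistic. Exit codes:
0 success, 2 configuration/schema error, 3 data/domain error.

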
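---
title: "Quantifying epithelial wound healing with ECIS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epithelial wound healing with ECIS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecisr)
```

## The measurement

Electric Cell-substrate Impedance Sensing (ECIS) grows cells on a small
(250 µm diameter, 0.05 mm²) gold microelectrode and measures the complex
impedance of the cell-covered electrode with a weak AC current across a
grid of frequencies (62.5 Hz–64 kHz here, one sweep every 160 s). Two
derived channels carry most of the biology:

* **R at 4 kHz** — the series resistance at low frequency, sensitive to
  the paracellular current path: cell–cell junctions, cell–substrate
  adhesion and motility.
* **C at 64 kHz** — the series capacitance at high frequency, where
  current crosses the cell layer capacitively, so the capacitance
  interpolates approximately linearly between the cell-free and the
  confluent value and acts as a coverage gauge.

`ecisr` stores experiments as an `impedance_timeseries` (complex Ω indexed
by time × well × frequency, with explicit missing-cell flags) and converts
to channels with `extract_channel()`, using the series-RC convention
(R = Re Z, C = −1/(2πf Im Z)) of lock-in-amplifier instruments. Missing
sweeps stay flagged gaps; fitting routines skip them rather than
interpolate.

## The cell–electrode model

The disk-cell (Giaever–Keese) model treats cells as circular disks of
radius $r_c$ hovering at height $h$ above the electrode in medium of
resistivity $\rho$. Current flows under the cells, between them (barrier
resistance $R_b$, Ω·cm²) and through them (two membranes in series, each
with specific capacitance $C_m$). The under-cell constriction is summarised
by the adhesion parameter

$$\alpha = r_c \sqrt{\rho / h} \quad [\Omega^{1/2}\,\mathrm{cm}],$$

large $\alpha$ meaning cells hug the electrode tightly. With $Z_n$ the
cell-free (naked) and $Z_m = 2/(j\omega C_m)$ the transcellular specific
impedance, and $\gamma r_c = \alpha\sqrt{1/Z_n + 1/Z_m}$, the covered
electrode obeys

$$\frac{1}{Z_c} = \frac{1}{Z_n}\left[\frac{Z_n}{Z_n+Z_m} +
  \frac{Z_m/(Z_n+Z_m)}{\frac{\gamma r_c}{2}\,
  \frac{I_0(\gamma r_c)}{I_1(\gamma r_c)} + R_b\!\left(\frac1{Z_n}+\frac1{Z_m}\right)}\right],$$

with $I_0, I_1$ modified Bessel functions of complex argument. The Bessel
ratio is evaluated by power series for $|z| \le 30$, a backward-recurrence
continued fraction up to $|z| \le 300$, and a fourth-order asymptotic
expansion beyond — direct series evaluation would overflow, and the ratio
tends to 1. Partially covered electrodes mix admittances by area:
$1/Z_{mix} = c/Z_c + (1-c)/Z_n$.

### The naked electrode

Instruments report only that the cell-free electrode reads 2600 Ω at
4 kHz. The remaining spectral shape must be assumed: we use a
constant-phase element in series with a spreading resistance,
$Z_n = A(j\omega)^{-n} + R_{sol}$, with defaults $n = 0.9$ (typical of
sputtered gold), $R_{sol} = 0.54$ Ω·cm² ($\rho/2d$ for a 250 µm disk in
54 Ω·cm medium), and $A$ calibrated by `calibrate_naked_electrode()` so the
4 kHz series resistance is exactly 2600 Ω.

### Fitting α

`fit_alpha()` minimises squared residuals of $[\log|Z_c/Z_n|,
\arg(Z_c/Z_n)]$ across frequencies — normalising by $Z_n$ removes
electrode area and lead resistance as nuisance scales — over
$\{\alpha, R_b, C_m\}$ (log-parameterised, L-BFGS-B, multi-start at
$\alpha \in \{2, 5, 10\}$). Standard errors come from the residual
Jacobian by the delta method. A fit driven to the α lower boundary is
flagged *degenerate* (cell-free-like spectrum); unconverged fits must be
treated as absent, and the pipeline does so.

Noise-free forward spectra are recovered to ~10⁻⁶ relative; with 1%
multiplicative complex noise α is recovered within a few percent.

### A consistency limit worth knowing

With any CPE-type naked electrode calibrated to 2600 Ω, the
covered-electrode 4 kHz resistance at $R_b \to 0$ is already
10.5–16 kΩ for α in the 6.5–7.8 range reported for tightly adherent
epithelia — above the 8.5 kΩ mature-plateau resistance such layers
actually show. Printed α values and printed resistance plateaus therefore
cannot be reproduced by one parameter set under this model family. The
simulator's default cell parameters use α = 2.5 (floor ≈ 4.1 kΩ), so the
barrier-resistance calibration can hit all scheduled resistance levels
exactly; the larger published α values are used as ground truth in the
spectrum-level recovery tests, where no 4 kHz constraint applies.

## The synthetic experiment

`simulate_timecourse()` generates the canonical trajectory: attachment and
spreading (a smooth coverage ramp over the first 5 h), barrier formation
peaking at 15 kΩ on day 2, a 5.5-day maturation decline to an 8.5 kΩ
plateau (modelled as a cosine ramp in $R_b$ at full coverage — the decline
reflects morphology change, not cell loss), an instantaneous wound at day
25 (coverage → 0; resistance = the 2600 Ω cell-free value at the wound
sample, exactly, by calibration), radial-front recovery, a 10 kΩ migration
plateau held for 24 h, and a second maturation decline. All resistance
targets are hit exactly in the noise-free configuration because $R_b$
levels are obtained by root-finding (`calibrate_barrier_resistance()`) on
the rising branch $R_b \in [10^{-6}, 30]$ Ω·cm² (the 4 kHz resistance is
non-monotone in $R_b$ at large $R_b$, where current diverts through the
membranes).

Stated-world choices the study itself does not pin down, chosen once:

* migration-phase plateau 10 kΩ (recovery overshoots the mature plateau
  before the second maturation, as healing curves show);
* the second maturation starts 24 h post wound, safely outside the
  default healing-fit window;
* micromotion = mean-reverting AR(1) multiplicative fluctuation of $R_b$
  with autocorrelation time 5 samples (≈13 min), relative-variance
  schedule high 4×10⁻⁴ / low 4×10⁻⁶ (2% / 0.2% RMS — the order-of-magnitude
  contrast seen in micromotion studies), logistic transition of width
  1.5 h centred 11.5 h after activity-triggering events (the peak and the
  wound). The schedule is specified on the variance scale because that is
  the quantity the moving-variance pipeline estimates; squaring a
  logistic amplitude schedule would shift its own midpoint.
* per-well variability as a random offset on the resistance levels
  (SD ≈ 480/610 Ω for the two default groups, the magnitudes implied by
  the published standard errors and well counts);
* measurement noise as multiplicative complex Gaussian on Z (default off;
  0.5% is realistic for these instruments).

Everything is a pure function of the configuration including its seed;
identical configs reproduce bit-for-bit.

What a green simulation-based test establishes is internal consistency of
generator and analyzer under this stated world — not instrument realism.
Real data add drift, electrode-to-electrode geometry variation,
temperature transients and non-stationary micromotion spectra that this
generator does not emulate.

## Healing kinetics

`detect_wound()` flags the first sample where the 4 kHz resistance falls
within 10% of the cell-free reference after having exceeded twice that
reference. `fit_healing_sigmoid()` then fits the four-parameter logistic

$$R(t) = R_{base} + \frac{R_{plateau} - R_{base}}
  {1 + e^{-k (t - t_{50})}}$$

over a 24 h window from the wound (multi-start `nls`, quasi-Newton polish
when the gradient degenerates near sharp plateaus). The hill slope $k$
(h⁻¹) and inflection point $t_{50}$ (h) are the kinetic endpoints. The
window deliberately ends before the post-healing maturation decline;
a constant trace yields an unconverged (degenerate) fit.
`healing_time(fit, θ)` is the closed-form time to a recovery fraction θ
(default 0.95): $t_{50} + \ln(\theta/(1-\theta))/k$.

### Migration rate: why the coverage channel

The healed area grows as an inward annular front: open-area radius
$r - vt$, coverage $c(t) = 1 - ((r - vt)/r)^2$, closure at $t = r/v$.
Because the front closes *tangentially* (zero derivative at closure), any
threshold estimator on the S-shaped resistance curve fires early: the
symmetric logistic's 95% point lands ~15% before closure for this family,
which would inflate rates by ~17% — we measured exactly that on noise-free
simulations, for every front speed, and no single junction-lag smoothing
constant repairs it across speeds. The resistance sigmoid is therefore
kept for what it measures well (hill slope, inflection), and the
migration rate uses the coverage channel instead: for the radial front,

$$\sqrt{1 - c(t)} = \frac{r - vt}{r}$$

is *exactly linear in time*, so `front_speed_from_coverage()` regresses
$\sqrt{1-c}$ on $t$ over the open-front samples (coverage 0.02–0.95,
stopping at first closure), reads the front speed from the slope and the
repopulation time from the zero crossing, and reports
rate = radius / repopulation time. On noise-free simulations this
recovers configured speeds to 0.1%.

The coverage trace itself comes from `coverage_from_capacitance()` with
endpoints self-calibrated per well: the cell-free capacitance from the
wound sample (coverage is exactly zero there) and the confluent value
from the healed migration plateau at the end of the fit window — not from
the pre-wound layer, whose barrier state (and hence 64 kHz capacitance)
differs from the migration state by tens of percent. Series-RC extraction
leaves a small residual nonlinearity in the coverage map (≲7×10⁻⁴ in
coverage units; exact linearity holds for parallel capacitance, but
series-RC is the instrument convention), negligible for the rate.

The radius convention (front travels 125 µm) is the default;
diameter-based rates are available via `migration_rate(...,
convention = "diameter")`.

## Attachment (adhesion) assay

For confluent seeding, the first hours of the 4 kHz trace rise nearly
linearly as cells attach and spread. `attachment_slope()` fits OLS over
the rising segment of the first-24 h window, ending the segment at the
first sample reaching 95% of the within-window *rise* (min + 0.95·range
— a threshold on absolute values would be meaningless at a 2.6 kΩ
baseline); a constant trace uses the full window and reports slope 0.

## Micromotion

`detrend_normalize()` removes a single least-squares line per 512-sample
segment and divides by the raw segment mean (the simplest reading of
"detrended and normalized"; polynomial detrending and z-scoring are easy
alternatives but are not the default). `moving_variance()` computes the
unbiased sample variance in a 150-sample window sliding by 1 — for
512-sample segments that is exactly 363 points spanning 22.75 h of data
(512 × 160 s = 22.756 h; the conventional figure truncates at two
decimals).

`transition_half_time()` fits a descending logistic (high, low, midpoint,
width) to the variance trace. Two numerical choices make this
identifiable on a single segment: the model is the *window-averaged*
logistic (closed form), so the 6.7 h moving-variance smoothing cannot
bias the midpoint, and residuals are taken on log-variance, which is
approximately homoscedastic for windowed variance estimates (a plain
linear-scale fit of the unconvolved logistic scatters over ±4 h and
occasionally diverges on AR(1) fluctuations). The search is a profiled
grid over (midpoint, width) with plateau levels optimised per node, then
a bounded refinement. Single-segment estimates still carry ≈1.2 h of
sampling noise — a 150-sample window over AR(1) noise holds only ~15
independent fluctuation samples — so schedule midpoints are compared as
means over replicate traces.

On full simulated experiments the post-wound variance transition also
absorbs residual *trend* curvature (the recovery ramp within each
window), as any linear-detrend moving-variance analysis of real
post-wound data does; the half-time recovered there reflects both trend
flattening and the micromotion schedule. The generator-versus-analyzer
validation therefore uses plateau-level traces where the schedule is the
only time-dependence.

## Group statistics

`one_way_anova()` implements the textbook between/within F with
(k−1, N−k) degrees of freedom; degenerate all-identical input is defined
as F = 0, p = 1. `tukey_kramer()` does studentized-range pairwise
comparisons with the Kramer unequal-n standard error
$\sqrt{MSE/2\,(1/n_i+1/n_j)}$, adjusted p from `ptukey`, simultaneous
99% intervals by default (significance threshold 0.01), reducing to plain
Tukey HSD for equal n (verified against `TukeyHSD` in the tests). Wells
are the unit of replication; no additional multiplicity correction is
applied across endpoints. p values are reported to four decimals.

## Pipeline and reproducibility

`run_pipeline()` chains the stages per well — channels, attachment,
wound, sigmoid, coverage-front migration rate, α from the averaged
pre-wound plateau spectrum, post-wound micromotion — then compares groups
on the endpoint set {migration rate, α, attachment slope, hill slope,
inflection point}. A failed stage leaves its endpoint NA for that well
rather than aborting the run (input parsing errors, by contrast, abort
and name the stage). The run manifest records a config hash (canonical
key-sorted JSON, FNV-1a), seed, package version and output paths; output
is a pure function of (config, input files).

## Known limitations

* The naked-electrode spectral shape beyond its 4 kHz resistance is an
  assumption; α estimates from real data inherit it.
* $R_b$ and $C_m$ accompanying published α values are typically not
  reported; recovery tests fix them at the documented defaults.
* The sigmoid form is the standard 4-parameter logistic; if an
  instrument vendor's sigmoid differs, hill slopes are comparable only up
  to that convention.
* Micromotion is modelled as AR(1) amplitude-scheduled noise, not a
  mechanistic membrane-fluctuation model; spectral (power-law) micromotion
  analysis is out of scope.
* Wells are independent; plate-level covariance is not modelled.
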
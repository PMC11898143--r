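---
title: "Models and methods behind barnsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind barnsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barnsense)
```

barnsense is a desk-scale laboratory for multi-sensor environmental
monitoring of livestock housing. It simulates a barn with known ground
truth, pushes that truth through a realistic telemetry chain (multi-rate
sampling, sensor noise, 10-minute aggregation, a binary packet codec, a
store-and-forward gateway), and then runs the analytics a welfare or
emission study would run on the decoded data. Because every generator
parameter is recorded, each estimator can be validated by parameter
recovery rather than by eyeballing plots. This vignette documents the
models, the defaults and the reasoning behind the design choices.

## The synthetic barn

### Gas mass balance

Each zone is a single well-mixed compartment (CSTR). For a gas with
indoor mass concentration $C$ (g m$^{-3}$), source strength $S(t)$
(g h$^{-1}$), ventilation rate $Q(t)$ (m$^3$ h$^{-1}$), zone volume $V$
(m$^3$) and background concentration $C_{out}$:

$$V \frac{dC}{dt} = S(t) + Q(t)\,\bigl(C_{out} - C\bigr).$$

The simulator advances this on a 10 s grid (the fastest sensor sampling
period) with the exact exponential update for piecewise-constant
coefficients,

$$C_{k+1} = C^{ss}_k + (C_k - C^{ss}_k)\,e^{-Q_k \Delta t / V},
\qquad C^{ss}_k = C_{out,k} + S_k / Q_k,$$

so that over any stretch with constant coefficients the discrete
trajectory *is* the analytic solution, not an Euler approximation. The
test suite checks agreement with the closed form to below $10^{-9}$
relative error. One consequence worth noting: starting from
$C(0)=C_{out}$, the relative distance to steady state decays as
$e^{-t/\tau}$ with $\tau = V/Q$, so reaching $10^{-9}$ takes roughly
21 time constants, not 10. Scenarios that need an exactly stationary
record can instead initialize at the steady state (`init = "steady"`),
which is what the tracer-recovery studies do.

A well-mixed compartment was chosen deliberately: the CO2 tracer-gas
emission estimator is exact under well-mixed steady-state conditions, so
this generator admits exact recovery tests for it. The cost is realism —
no spatial gradients within a zone, no recirculation; spatial structure
is represented only between zones.

### Units and temperature

The gas state is carried in g m$^{-3}$; sensors report ppm (by volume).
Conversion uses the ideal gas law
($\mathrm{g\,m^{-3}} = \mathrm{ppm}\cdot 10^{-6} M P / (R T)$) at the
zone's instantaneous temperature and the scenario pressure (default
101325 Pa). Indoor temperature is the outdoor sinusoid (configurable
mean, half-amplitude and peak hour) plus a constant animal-heat offset,
default 3 °C, a typical indoor excess for an open dairy barn in the cold
season. When the diurnal amplitude is non-zero, hourly-mean ppm converted
at hourly-mean temperature differs from the hourly-mean mass
concentration by a second-order (Jensen) term of order
$(\sigma_T/T_K)^2 \sim 10^{-4}$; the exact-recovery studies therefore use
steady (zero-amplitude) climates, and noisy studies absorb the term in
their tolerance.

### Events, humidity and the remaining channels

Feed deliveries multiply all gas sources by a configurable factor
(default 2) for a configurable duration (default 60 min) at configurable
times of day (default 07:15 and 16:30, the usual twice-daily feeding).
Relative humidity is mean plus AR(1) noise clipped to [0, 100] %; sound,
particulate fractions and VOC/NOx indices are mean-level AR(1) or white
processes, and illuminance follows a 06:00–18:00 daylight half-sinusoid.
These channels have no mechanistic model here — they exist so the full
telemetry chain (all 13 channels, three sampling rates, presence flags)
can be exercised, not to study their dynamics.

No ventilation rates are published for the motivating farm cases, so all
scenario defaults are illustrative, sized to put indoor concentrations at
realistic open-barn levels (CO2 around 600 ppm over a 420 ppm
background, NH3 of a few ppm); they are not reconstructions of any real
building.

## The virtual sensor node

Channels are sampled at their native periods — 10 s (electrochemical
gases, sound), 60 s (temperature, humidity, CO2, illuminance) or 15 min
(particulates, VOC/NOx) — and aggregated into 10-minute records carrying
average, minimum and maximum per channel. A 15-minute channel appears
only in windows where a reading completed, so it skips every third
window; when a window boundary splits measurements, the most recent
completed, not-yet-reported reading is the one carried.

The noise model reads the printed accuracy of each sensor as a 2-sigma
half-width: additive Gaussian noise with SD = accuracy/2, relative
accuracies applied to the current reading, and where both an absolute and
a relative figure exist (CO2: ±30 ppm / ±3 %) the larger applies.
Readings saturate at the range limits rather than erroring — physical
sensors clip. This is the simplest convention that lets the published
accuracy table drive the simulator directly; real electrochemical cells
also drift and cross-react, which is explicitly *not* modelled, so
agreement of downstream estimates under this noise model bounds only the
random-error contribution, not long-term bias.

### Wire format

Packets use a compact big-endian binary layout: magic/version, node id,
slot, window start, a 16-bit presence bitmap in fixed channel order, then
avg/min/max per present channel as signed 16-bit fixed point (scales:
temp and RH ×100, sound ×10, electrochemical gases ×100, CO2, lux and
VOC/NOx ×1, particulates ×10), closed by CRC-16/CCITT. Decoding is exact
on the quantized domain, and the suite round-trips 10,000 randomized
records. One known limitation of the 16-bit layout: illuminance above
32,767 lx cannot be represented and is clamped at encode time, although
the sensor itself ranges to 128 klx; bright-daylight applications would
need a wider field or a coarser scale. Telemetry uses 600 one-second
time-division slots per 10-minute period, assigned in registration
order, so a single gateway serves at most 600 nodes.

## Calibration and repeatability

Electrochemical channels are span-calibrated through two points:
$\mathrm{gain} = (y_2 - y_1)/(c_2 - c_1)$, offset $= y_1 -
\mathrm{gain}\cdot c_1$; the inverse map recovers the calibration
concentrations exactly, and Monte-Carlo tests confirm the estimator is
unbiased within 1 % even at the 10 nA/ppm low-sensitivity end with 1 nA
signal noise. The CO2 channel gets a zero (offset-only) calibration
against a reference analyzer reading of the same air. Parameters are
persisted as small JSON documents, standing in for the sensor board's
EEPROM.

The repeatability report compares co-located nodes interval by interval.
The reference at each interval is the cross-node mean by default —
ambient-air checks have no independent truth — with a known applied
concentration available as an alternative for bench runs. Per-interval
mean and sample (n−1) SD of absolute errors are averaged over time, in
absolute units and relative to the interval reference; whether relative
errors are formed per interval and then averaged (default) or from the
time-averaged absolutes is selectable, since either reading of a summary
table is defensible. One property one might expect — that duplicating a
node can never increase the mean absolute error — is actually false for
a consensus reference (duplicating an outlying node drags the consensus
toward it), so the suite asserts permutation invariance and zero error
for identical nodes instead.

## Gateway and cloud-side aggregation

The gateway is modelled as a two-level store-and-forward buffer: RAM
first, spilling oldest-first to persistent flash when the RAM queue
exceeds its capacity; on link-up, flash flushes before RAM; a power cycle
loses whatever sat only in RAM but never what reached flash. A delivered
ledger keyed by (node id, window start) drops duplicates, so any message
that survives buffering is delivered exactly once, with its origin
timestamp. The loss window — RAM contents at the moment of power failure
— is inherent to the double-buffer design; shrinking RAM capacity trades
it against flash wear, which is why the capacity is configurable.

Resampling to hourly and daily values takes arithmetic means of the
available finer records and records a coverage fraction; a bin under 50 %
coverage is marked missing. The threshold is a policy choice (the
underlying systems are silent on missing data); 0.5 keeps a bin honest
while tolerating one lost packet in two. With full coverage, daily mean
= mean of hourly means = mean of 10-minute values to $10^{-12}$
relative, because all windows are equal-weight.

THI uses the standard dairy form
$\mathrm{THI} = (1.8T + 32) - (0.55 - 0.0055\,\mathrm{RH})(1.8T - 26)$;
the function is a plain pluggable scalar map, so sites preferring another
THI variant can substitute their own before thresholding.

## Welfare analytics

Threshold assessment flags a device when its period-mean concentration
strictly exceeds the limit (default EFSA-style limits: NH3 10 ppm, CO2
3000 ppm, H2S 0.5 ppm, CO 10 ppm); equality at the boundary is not a
violation, and the time-above-limit fraction is computed from the finest
resolution supplied.

Uniformity between monitoring points uses a one-way ANOVA on hourly
values followed by Tukey all-pairs comparisons at a familywise alpha of
0.01, summarized with an insert-and-absorb compact letter display. This
is a transparent, reproducible equivalent of the commercial GLM +
pairwise-comparison procedure such studies typically report; simulation
shows the realized familywise false-difference rate across 500 null
replicates of six identical devices sits at the nominal 0.01 within
Monte-Carlo error, while a 5-SD mean shift between two devices (n = 100
hourly values each) is detected in over 99 % of replicates. Hour-of-day
binning uses the timestamps' local clock with no DST correction.

Diurnal profiles report, per hour of day, the mean across days and the
standard error over day-level means (zero for any noiseless 24-h-periodic
signal). On event-pulsed synthetic scenarios, the morning feed hour
carries the largest profile value; note that a feed at 16:30 splits its
pulse across the 16:00 and 17:00 bins, so the afternoon peak spreads over
both.

Concentration maps use inverse-distance weighting with exponent 2 on a
0.5 m grid by default. IDW was chosen over kriging because six devices
cannot support a variogram; the method is pluggable. IDW fields are
exact at device positions and bounded by the device-mean extremes, which
the suite asserts.

## Ammonia emission by CO2 tracer

The estimator implements the tracer-gas balance

$$E_{NH_3} = P_{CO_2} \cdot
\frac{C^{barn}_{NH_3} - C^{out}_{NH_3}}{C^{barn}_{CO_2} - C^{out}_{CO_2}},$$

with concentrations in g m$^{-3}$ and the herd's metabolic CO2 production
$P_{CO_2}$ in g h$^{-1}$. Because both gases leave through the same
ventilation air, the unknown ventilation rate cancels — the property that
makes the method attractive for naturally ventilated barns where airflow
cannot be measured.

$P_{CO_2}$ follows the CIGR/VERA heat-production form: per head,
$\Phi_{tot} = 5.6\,m^{0.75} + 22\,Y + 1.6\times10^{-5}p^3$ W (body mass
$m$ in kg, milk yield $Y$ in kg day$^{-1}$, pregnancy days $p$), corrected
linearly for ambient temperature as $\Phi(T) = \Phi_{tot}(1000 + 4(20 -
T))/1000$, converted at 0.185 m$^3$ h$^{-1}$ of CO2 per heat-producing
unit (1 hpu = 1000 W) and to mass via the ideal-gas CO2 density at barn
temperature. For a 650 kg cow at 37 kg day$^{-1}$ and 20 °C this gives
about 1535 W, 0.284 m$^3$ h$^{-1}$ and 520 g h$^{-1}$ per head. Body mass
is rarely published for commercial herds; the default is 650 kg and every
parameter is configurable. "Energy intake" enters only through the
maintenance and milk-yield terms; no separate feed-energy term and no
diurnal animal-activity correction are applied (the latter is deliberate:
only the temperature correction is retained, and an activity correction
can be layered on top by scaling `p_co2`).

Calculations run hourly — capturing the fluctuating temperature through
both the conversion and the heat-production correction — and are averaged
over each day, indoor concentrations being the cross-device mean of the
barn nodes. Hours with a non-positive indoor-outdoor CO2 difference are
excluded rather than clipped (the balance is singular there), and a day
needs at least 12 valid hours or it is marked missing. Per-animal output
is $24 \cdot \overline{E} / n_{animals}$ in g animal$^{-1}$ day$^{-1}$.

Validation by parameter recovery: on noiseless steady scenarios the
recovered emission equals the generator's NH3 source to machine
precision for any ventilation rate (50 randomized scenarios are checked
below $10^{-6}$ relative error); with sensor noise at the printed
accuracies (NH3 ±10 %, CO2 ±3 %, both 2-sigma) on a 140-cow dairy-scale
scenario, the median of 200 replicate daily estimates falls within a few
tenths of a percent of truth, comfortably inside the 10 % acceptance
band. The dominant real-world error sources — sensor drift,
representativeness of point measurements in an imperfectly mixed barn,
and bias in the assumed CO2 production — are outside what this noise
model can probe, which is why passing these studies demonstrates
correctness of the computation, not field accuracy of the method.

## Problem sizes and reproducibility

The validation studies are sized to run comfortably on one CPU: one-day
scenarios at 10 s resolution (8,640 steps per zone), 50 noiseless
tracer-recovery scenarios, 200 noisy emission replicates, 1,000
calibration replicates, 10,000 codec round-trips and 500 + 200
uniformity replicates. All randomness flows through explicit integer
seeds: identical (configuration, seed) pairs reproduce ground truth
bit-for-bit, and `scripts/acceptance.R` derives every stream from its
single `--seed` argument.

## Known limitations

* Single-compartment zones: no CFD, no within-zone gradients, no
  humidity-gas interaction, no manure-pit chemistry.
* Sensor model: additive Gaussian noise and saturation only — no drift,
  hysteresis, cross-sensitivity or warm-up transients, all of which
  matter over months of deployment.
* The 16-bit packet layout clamps illuminance above 32,767 lx.
* A power cycle loses RAM-buffered messages not yet spilled to flash.
* VOC/NOx channels are carried through the chain but their index ("tick")
  semantics are not modelled.
* Real recorded farm datasets are not reproduced; published device means
  can be fed through the analytics (as the threshold worked example
  does), but hourly-level statistics of the original deployments are not
  recoverable from printed summaries.
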
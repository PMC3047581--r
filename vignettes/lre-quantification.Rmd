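---
title: "Standard-curve-free absolute qPCR quantification by linear regression of efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standard-curve-free absolute qPCR quantification by linear regression of efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrequant)
```

## The model

A real-time PCR amplification profile recorded with an intercalating dye
(SYBR Green I) follows, to a good approximation, a logistic in cycle number
$C$:

$$F_C \;=\; \frac{F_{\max}}{1 + \dfrac{F_{\max}-F_0}{F_0}\,(1+E_{\max})^{-C}}$$

where $F_C$ is the background-subtracted fluorescence at cycle $C$, $F_0$ the
fluorescence equivalent of the starting target quantity (the quantity of
interest), $F_{\max}$ the plateau, and $E_{\max}$ the maximal amplification
efficiency (1.0 = perfect doubling). The per-cycle efficiency

$$E_C \;=\; \frac{F_C}{F_{C-1}} - 1$$

then satisfies, exactly,

$$E_C \;=\; E_{\max} + \Delta E \cdot F_C, \qquad
\Delta E = -\,\frac{E_{\max}}{F_{\max}} .$$

Linear regression of efficiency (LRE) exploits this: an ordinary
least-squares fit of $E_C$ on $F_C$ over a window of cycles in the central
region of the profile estimates $E_{\max}$ (intercept) and $\Delta E$
(slope), hence $F_{\max} = -E_{\max}/\Delta E$. Inverting the logistic at
each window cycle back-calculates $F_0$:

$$F_0 \;=\; \frac{F_{\max}}{1 + \dfrac{F_{\max}-F_C}{F_C}\,(1+E_{\max})^{C}},$$

and the window-average $F_0$ is the profile's quantity estimate. No standard
curve is involved; the only external quantity is the *optical calibration
factor* (OCF, fluorescence units per ng of double-stranded DNA), measured
once per reaction setup by amplifying a known mass of lambda genomic DNA:

$$\text{molecules} \;=\; \frac{F_0}{\mathrm{OCF}} \times
\frac{9.1\times10^{11}}{\text{amplicon size (bp)}} \times
\begin{cases}1 & \text{double-stranded target}\\ 2 & \text{single-stranded
target (e.g. first-strand cDNA)}\end{cases}$$

with $9.1\times10^{11}$ bp·molecules/ng from Avogadro's number over 660
g·mol⁻¹ per base pair (`CONV_DS`, overridable). The fractional cycle at
which fluorescence reaches half the plateau,
$C_{1/2} = \log\!\big((F_{\max}-F_0)/F_0\big)/\log(1+E_{\max})$, is reported
as a robust profile-position statistic analogous to Cq.

Two conventions deserve a note. First, efficiency here is the consecutive
reading *ratio minus one*, so that the Y-intercept of the LRE plot reads
directly as $E_{\max}\approx 1$ for near-perfect doubling; a plain-ratio
convention would put the intercept near 2 and contradict the way $E_{\max}$
values are conventionally displayed. Second, instruments report raw
fluorescence including an optical background; the model applies to
background-free readings, so each profile's baseline (mean raw reading over
cycles 4–9 by default, before the rise under standard 40–50-cycle protocols)
is subtracted first. A baseline window that overlaps the amplification rise
(any reading above 10% of the profile's dynamic range) is rejected rather
than silently used. Both the cycle range and a fixed baseline (0 for
pre-baselined exports) are parameters.

## Automated window selection

The LRE window is the contiguous cycle range used for the regression. Its
bottom is the *start cycle*:

* **default rule** — the largest integer cycle strictly below the profile's
  half-maximum cycle. Because no fit exists yet, the half-maximum is
  estimated fit-free: the plateau is the mean of the cycles within 5% of the
  maximum, and the crossing of half that level is located by linear
  interpolation (`observed_half_max_cycle()`). The exported $C_{1/2}$, by
  contrast, is the model-based closed form above — the fit-free variant
  exists only to break the circularity of choosing a window before a fit
  exists.
* **minimum-$F_C$ rule** — with a user-specified minimum fluorescence, the
  start cycle is the cycle *after* the first cycle exceeding the minimum
  (that earlier cycle supplies the start cycle's efficiency denominator).
  This places the window bottom where the instrument's read precision is
  adequate; `optimize_min_fc()` implements the recommended tuning — scan
  candidates and keep the one minimizing the run's average replicate $F_0$
  CV.

From a three-cycle initial window the top is grown recursively: fit the
window, back-calculate the $F_0$ of the cycle just above it with the current
fit, and if that $F_0$ agrees with the window-average $F_0$ within the *F0
threshold* (6% by default) include the cycle and refit; otherwise stop. The
window average is recomputed after every refit. Expansion also stops at the
end of the profile and at 99.9% of the fitted plateau, where the
back-calculation approaches its pole. The absolute difference is used, so
both upward and downward departures terminate expansion. A window that
cannot reach three cycles flags the profile; flagged profiles carry no
quantity, ever.

## Replicates, calibration, and run statistics

Technical replicates are averaged cycle-by-cycle into an *average profile*,
the primary working unit — averaging $k$ replicates cuts read noise by
$\sqrt{k}$, which matters on noisier optics. Each calibration profile gives
$\mathrm{OCF}_i = \overline{F_0}_i/\text{ng}$; the reported OCF is their
mean with the SD as dispersion.

Below about 10 molecules per reaction, Poisson partitioning of template
among reactions means replicates genuinely contain different integer copy
numbers. Their average profile is then a smear of time-shifted curves — not
an amplification curve at all — and its quantity is biased high, by large
factors in our simulations. The set quantity therefore switches to the mean
of the per-replicate quantities whenever the average-profile quantity, the
per-replicate mean, *or* the per-replicate median falls below the threshold
(the median makes the regime decision robust to a single outlying replicate
estimate); non-amplifying replicates count as genuine zeros in that mean,
and the set is flagged `poisson_regime`. The branch taken is always
recorded.

Run-level precision is summarized by the *average replicate $F_0$ CV*: the
sample SD over mean of replicate $\overline{F_0}$ values per set, averaged
over the sets with at least two valid replicates. Replicate sets whose
$C_{1/2}$ values span more than 1 cycle (configurable) warn that the
replicates are not tightly clustered.

## Kinetic-anomaly diagnostics

Three pathologies are recognized from the LRE plot; the classifier only
annotates — excluding aberrant cycles from the analysis is the window
selector's job, and the quantity is never altered by a label.

* **Plateau drift** — the plateau keeps climbing (continued product
  accumulation); post-window points drift progressively above the fitted
  line. Statistic: the net trend of the post-window residuals,
  $\mathrm{slope}\times\mathrm{span}/E_{\max}$, over all post-window cycles
  with defined efficiency. Beyond +0.05 → drift.
* **Profile collapse** — efficiency dies while the reaction is still
  amplifying and the profile stalls below the model plateau. Because the
  recursive window refit partially *tracks* a smooth collapse, the statistic
  is referenced instead to a line fitted on the window plus up to six cycles
  below it — a region collapse (which develops above the half-maximum
  cycle) leaves clean — and takes the mean displacement of the first four
  post-window cycles. Below −0.05 → collapse.
* **Profile arcing** — the efficiency bends smoothly along the profile
  (enzyme-formulation artifact), so no single line describes the rise. An
  ordinary refit absorbs most of any smooth deviation into its slope and
  intercept, and the window intercept alone carries several percent of
  extrapolation noise, so the statistic compares two intercepts estimated
  where each is precise: a line through the early-rise cycles (just below
  the window) against a line through the window-to-plateau region. A
  relative disagreement beyond 0.10, or a window $R^2$ below 0.9 (windows of
  5+ cycles), classifies arcing.

Checks run in the order drift → collapse → arcing: the drift and collapse
statistics are blind to arcing by construction, while a collapsing profile
necessarily also fits a single line poorly. All thresholds live in
`lre_params()`.

## The synthetic-data generator

`simulate_profile()` and `simulate_run()` are the package's only test
data source, and every stochastic output demands a seed. Trajectories are
sampled from the closed-form model, so per-cycle efficiency is *exactly*
linear in fluorescence and any deviation in a test is attributable to the
injected effect. Defaults describe a plausible plate instrument and a
demonstration-style experiment:

| parameter | default | units | rationale |
|---|---|---|---|
| `emax` | 0.95 | – | typical well-optimized SYBR assay |
| `fmax` | 4×10⁶ | a.u. | plateau on a plate instrument's scale |
| `baseline` | 5×10⁴ | a.u. | ~1% of plateau optical background |
| `noise_sd` | 0.004 | fraction/reading | reproduces run-level replicate $F_0$ CVs of ~25–30% under default analysis settings, the regime reported for a well-behaved plate instrument |
| `noise_floor` | 10 | a.u. | small additive read-noise floor |
| `n_cycles` | 50 | cycles | standard long protocol |
| `ocf` | 10⁵ | a.u./ng | round number; arbitrary by design |
| run design | 3×3×3 | – | three targets × three samples × three PCR replicates, counts spanning 10²–4×10⁴ molecules |
| calibration | 3 × 10 fg lambda | – | puts the calibration $C_{1/2}$ near cycle 23 |

Template counts below 10 molecules are drawn from a Poisson distribution
(zero draws give background-only profiles), reproducing limiting-dilution
statistics.

Distortions are injected with defaults chosen to match the severity of
published examples of each pathology: drift adds 2% of $F_{\max}$ per
post-plateau cycle; collapse subtracts a linearly growing efficiency deficit
(0.08/cycle, floored at zero efficiency) after the half-maximum cycle;
arcing modulates $E_{\max}$ by a sinusoidal half-period of peak amplitude
0.35 across the observable lower rise (the six cycles up to the half-maximum
cycle, where fluorescence climbs from ~1% to ~50% of the plateau). The
arcing excursion is placed there deliberately: a smooth modulation centered
on the half-maximum cycle acts mostly as a time reparameterization — nearly
equivalent to shifting $F_0$ — and is statistically inseparable from a
conforming profile at realistic read noise, whereas a lower-rise excursion
leaves the window and plateau clean and produces the characteristic bow.

What the generator does *not* emulate: optical crosstalk and drift of the
instrument itself, melt-curve behaviour, non-specific products and
primer-dimers, pipetting-volume variation between replicates, and
inhibitor-induced efficiency shifts between samples. Passing tests therefore
demonstrate correctness of the algorithms under the model's own assumptions
plus read noise — not robustness to every failure mode of real chemistry.

## Numerical behaviour and limitations

* Noiseless, undistorted profiles are fixed points: analysis recovers
  $F_0$, $E_{\max}$, $\Delta E$ to numerical precision when the background
  is known, and to ~0.1% when it is estimated from early cycles (the
  residual template signal in cycles 4–9 biases the baseline slightly).
* The method's precision is governed by read noise through the window fit:
  the $F_0$ back-calculation multiplies the efficiency-estimate error by
  roughly $C_{1/2}/(1+E_{\max})$, i.e. a 1% error in $1+E_{\max}$ moves
  $F_0$ by ~13% for a profile crossing at cycle 27. At ~0.4% per-reading
  noise this yields per-reaction CVs of ~25–30% and set-level accuracy
  within ±30%, the regime the method is known for. Per-reading noise of
  ~1% or more is a qualitatively different regime: candidate-$F_0$
  agreement noise then exceeds the 6% threshold and windows rarely grow
  past the initial three cycles, so per-reaction errors reach ±50% or more.
  The remedy on such data is the minimum-$F_C$ rule tuned via
  `optimize_min_fc()`, replicate averaging — and better optics.
* Estimation error on $F_0$ is approximately log-normal; means over many
  low-copy sets are therefore heavy-tailed and sit a few tens of percent
  above the true count in small batches, while medians track it closely.
* Ties in `optimize_min_fc()` resolve toward the lower candidate
  (larger windows); all tie-breaks and thresholds are deterministic, and
  analysis of a fixed input with fixed parameters is bit-reproducible.
* Test problem sizes were chosen to exercise every rule at comfortable
  runtime: 200 mixed-mode profiles for the rule-transcription
  cross-check, 100 simulations per kinetic mode for recall, 200
  three-replicate sets for the low-copy estimator, and single 3×3×3 runs
  elsewhere.
* Vendor-native run files (ABI 7500, Mx3000p), RDML exchange, melt-curve
  QC and limiting-dilution cross-validation are out of scope; import is
  via the documented CSV/XLSX template layout only.
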
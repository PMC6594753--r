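---
title: "Kinetic and thermodynamic analysis of CFTR potentiator action"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic and thermodynamic analysis of CFTR potentiator action}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cftrpot)
```

## The scientific problem

Ivacaftor (Vx-770) is a potentiator of the CFTR chloride channel: it raises
the open probability of channels already at the cell surface. The drug is
extremely lipophilic (logD near 5) and barely water-soluble, which has two
consequences that `cftrpot` is built to quantify. First, its aqueous
solubility — around 60 nM at room temperature — is far below the micromolar
concentrations routinely applied in vitro, so most published work has used
supersaturated solutions. Second, the drug reaches its binding site(s) on the
channel through the membrane, so the kinetics of current activation and
deactivation in an excised inside-out patch reflect a chain of slow steps:
partitioning from the cytosolic bath into the bilayer, possibly flipping
between leaflets, and binding to one or two sites on the protein.

The package implements, end to end:

1. **Compartmental partition/binding schemes** (four of them) and their
   integration over arbitrary drug-application protocols;
2. **Global ensemble fitting** of a scheme to several normalized macroscopic
   current time courses at once, under a partition constraint;
3. **Steady-state dose-response theory** for those schemes, and empirical
   dose-response, activation, and deactivation analysis;
4. **Single-channel gating analysis**: idealization, open probability,
   stability plots, and closed-open-blocked (C-O-B) dwell-time fitting;
5. **Solubility and partition thermodynamics** from spectrophotometric
   extraction experiments;
6. **Seeded synthetic-data generators** for every input, so the entire
   pipeline is testable without any recordings.

## The four gating schemes

Each scheme tracks molar concentrations inside the patch membrane. Schemes
differ along two axes: one vs. two drug binding sites on the channel, and one
vs. two membrane compartments (a single well-mixed bilayer, or separate inner
and outer leaflets exchanging drug at a symmetric flip rate $k_{flip}$).

For the one-compartment, two-site scheme (scheme 3, the preferred working
model), the state is $x_1$ (free drug in the membrane), $x_2$ (unliganded
channels), $x_3$ (monoliganded channels); diliganded channels are
$C_t - x_2 - x_3$, so channel mass is conserved by construction:

$$
\begin{aligned}
\dot x_1 &= k_{in} V_c - 2 k_{out} x_1
           - k_{on}'(2x_2 + x_3)\,x_1 + k_{off}\,(2(C_t - x_2 - x_3) + x_3)\\
\dot x_2 &= -2 k_{on}' x_1 x_2 + k_{off} x_3\\
\dot x_3 &= 2 k_{on}' x_1 x_2 + 2 k_{off} (C_t - x_2 - x_3)
           - (k_{off} + k_{on}' x_1)\,x_3
\end{aligned}
$$

$V_c$ is the (piecewise-constant) cytosolic drug concentration; the factor 2
on $k_{out}$ reflects drug exit through both membrane faces, and the
statistical factors of 2 on binding/unbinding come from the two identical,
independent sites. Only diliganded channels gate at the potentiated open
probability, so the normalized current is
$f + (1-f)\,P_{o,max}/P_{o,bas}$ with $f = (x_2 + x_3)/C_t$.

**Initialization.** The trace must start at 1 (current is normalized to the
pre-drug steady state), which requires all channels unliganded at $t = 0$:
drug compartments start at 0 and the unliganded pool at $C_t$. Starting
literally every component at zero would place all channels in the
*diliganded* class and start the trace at $P_{o,max}/P_{o,bas}$; the adopted
convention is the only one consistent with the normalization.

**Steady state.** With the pipette drug-free, the membrane concentration
relaxes to $V_{m,\infty} = V_c\,k_{in}/(2 k_{out})$ (one compartment), or to
leaflet concentrations
$V_{mc,\infty} = V_c (k_{in}/k_{out})(k_{out}+k_{flip})/(k_{out}+2k_{flip})$
and
$V_{me,\infty} = V_c (k_{in}/k_{out})\,k_{flip}/(k_{out}+2k_{flip})$.
Occupancy of the potentiated class is $Y_1 = V/(K_{d,mem}+V)$ (one site) or
$Y_2 = Y_1^2$ (two independent sites), with $K_{d,mem} = k_{off}/k_{on}'$.
Half-maximal stimulation occurs at $K_{0.5,mem} = K_{d,mem}$ (one site) or
$(1+\sqrt2)\,K_{d,mem}$ (two sites), and the two-site activation curve has a
midpoint logit slope of exactly $2(2-\sqrt2) \approx 1.17$ — notably less
than 2, because monoliganded channels are populated but silent. Dividing
$K_{0.5,mem}$ by the steady-state membrane/water concentration ratio converts
it into the apparent aqueous affinity $K_{0.5,aq}$.

```{r steady-state}
p <- gating_params(k_in = 62580 * 0.06446, k_out = 0.06446, k_on = 870.3,
                   k_off = 0.007451, po_ratio = 3.935,
                   c_t = channel_site_concentration(100, 1e-16))
steady_state_response(3, p, v_c = 62e-9)   # ~3.9-fold at a saturated solution
derived_affinities(3, p)                   # K_0.5_aq ~ 0.66 nM
midpoint_hill_slope(3)
```

## Numerical integration

`integrate_protocol()` uses Heun's predictor-corrector — the classical
"modified Euler" — with a fixed step (default 10 ms), implemented in C++.
The step is capped at $0.1/r_{max}$, where $r_{max}$ is the fastest effective
first-order rate at the protocol's peak concentration
($2k_{out}$, $k_{on}' \hat V_m$, $k_{on}' C_t$, $k_{off}$, $2k_{flip}$), so
the stiffest term is always resolved by at least ten steps per time constant.
Second-order accuracy is verified in the tests by step-halving (every sample
changes by < 1e-4 relative), and long integrations are required to match the
closed-form steady states to 1e-4 relative for all four schemes under
randomized parameters. The integrator aborts if any state component falls
below $-10^{-9} C_t$, naming the offending time; channel mass is conserved
structurally because the fully liganded class is implicit.

Piecewise-constant protocols are resolved to the left of each step, so a
segment boundary falling between grid points is honored with $O(dt)$ error at
that single step — negligible at the default 10 ms against 10-minute
segments.

## Global ensemble fitting

`fit_ensemble()` fits one scheme simultaneously to a set of normalized on/off
time courses by plain (unweighted) least squares, exactly as the source
analysis did. Two conventions matter:

* **Partition constraint.** The equilibrium membrane/water concentration
  ratio is fixed to the measured octanol/water distribution coefficient,
  $k_{in}/k_{out} = D = 62580$, removing one free parameter. Every evaluated
  parameter vector reconstructs $k_{in} = D\,k_{out}$ exactly. $D$ is kept at
  the printed 62580 rather than the ratio of the rounded printed solubilities
  (which gives ~62900); the difference is below every other uncertainty.
* **Channel-site concentration.** $C_t = N/(N_A \cdot V)$ with $V = 10^{-16}$
  L for whole-membrane schemes and $5\times10^{-17}$ L for outer-leaflet
  schemes; $N$ is estimated from the pre-drug current, the unitary current,
  and a basal open probability of 0.16. Fits are insensitive to the volume
  convention as long as $C_t$ stays well below the steady-state membrane drug
  pool; when $C_t$ approaches it (large patches refit with 5-fold smaller
  volumes at low drug), site depletion becomes visible and recovered rates
  shift by a few percent. The volume-insensitivity property is therefore
  exercised on a 30-channel patch, squarely in the regime the claim is about.

Optimization is Nelder-Mead downhill simplex in log-parameter space (rates
span five decades and must stay positive), restarted from its own optimum
until the relative SSE improvement falls below `reltol` (default 1e-8, at
most 8 rounds), with one seeded jittered restart if the simplex stalls.
Predicted traces are resampled onto each observed grid by linear
interpolation. Noiseless self-generated two-concentration ensembles (0.01x
and 1x saturated, 10 min on / 10 min off, sampled at 1 Hz) are recovered
within 1% for all four schemes from 2-3-fold perturbed starts; scheme 2's
objective is shallow along $k_{flip}$ and needs a deeper tolerance (1e-12)
to reach that figure.

## Empirical macroscopic analysis

* `fractional_stimulation()` divides the drug-on steady current by the
  average of the pre- and post-drug steady currents, compensating linear
  rundown. Window placement is a user input.
* `fit_hill()` fits the modified Hill equation
  $I/I_{control} = (K_{0.5}^n + (I_{max}/I_{control})\,c^n)/(K_{0.5}^n + c^n)$,
  which is 1 at $c=0$ by construction. Fitting uses Levenberg-Marquardt
  least squares with bound constraints; data-derived starting values make
  noiseless self-recovery exact to 1e-6.
* `fit_exponential_decay()` fits $a + b\,e^{-t/\tau}$ to washout segments
  with a free offset (currents relax back to the pre-drug baseline, not to
  zero); non-decaying segments are flagged, not errors.
* `fit_three_step_activation()` fits the sigmoidal activation onset with an
  irreversible chain $S_1 \to S_2 \to S_3 \to S_4$ in which only $S_4$ gates
  above basal. Occupancies use the closed-form sum-of-exponentials solution
  with confluent (L'Hôpital) branches when rates coincide within 1e-6
  relative — exact and fast inside the optimizer. Because the observable
  depends on the rates only through $p_4(t)$, which is symmetric under
  permutation of the three rates, they are identifiable only up to ordering
  and are returned sorted.
* `tau_on_star()` implements the model-free activation time constant
  $T_{1/2}/\ln 2$. The "fully activated amplitude" is operationalized as the
  mean of the final 10% of the segment, which must itself be flat within 2%;
  for a mono-exponential rise the estimator equals $\tau$ exactly.

## Single-channel analysis

Records are smoothed with a zero-phase Gaussian filter (sigma chosen so the
-3 dB point sits at the requested corner frequency), idealized by
half-amplitude threshold crossing against multiples of the unitary current,
and dead-time concatenated: events shorter than 6 ms are merged into the
preceding event, emulating the resolution limit of the filtered record.

The C-O-B scheme separates ~10 ms flickery closures (blocked state B) from
~1 s interburst closures (C). `fit_cob()` maximizes a dwell-time likelihood
with a deliberately simplified, first-order missed-event treatment:

* observed open dwells are left-truncated exponentials with effective rate
  $r_{OC} e^{-r_{CO} t_d} + r_{OB} e^{-r_{BO} t_d}$ — only transitions into
  shut states that survive the dead time $t_d$ terminate a *visible* opening,
  since unseen brief closures are bridged into the open event;
* observed shut dwells are the left-truncated two-exponential mixture with
  component rates $r_{CO}$, $r_{BO}$ and entry weights $r_{OC} : r_{OB}$. No
  correction is applied on the shut side: a missed opening nearly always
  re-enters the blocked state and extends the shut dwell only by
  milliseconds.

This is not the exact missed-events likelihood; it leaves a small bias
(about 5-12% on the flicker rates at $r_{BO} t_d \approx 0.7$) that the
recovery tests bound at 15%, and recovery error approaches this bias floor —
rather than zero — as records lengthen. Burst metrics follow the standard
identities $\tau_b = (1/r_{OC})(1 + r_{OB}/r_{BO})$, $\tau_{ib} = 1/r_{CO}$,
and the stationary open probability of the three-state scheme. Rate fitting
is restricted to single-channel records; multi-channel records get open
probability and 46-s stability-window analysis only.

## Solubility and thermodynamics

Peak absorbance at 311 nm is linear in drug concentration, so a calibration
line (ordinary least squares, intercept included to absorb small blank
offsets) converts the optical density of a 1-octanol extract into a
concentration; dividing by the 20-fold extraction concentration factor gives
the aqueous solubility. Distribution coefficients are solubility ratios.
The solution thermodynamics use the two-point van't Hoff form
$\Delta H^\circ = \frac{R T_1 T_2}{T_2 - T_1}\ln\frac{S(T_2)}{S(T_1)}$ and
$\Delta G^\circ = -RT \ln S$ (1 M standard state), with $R = 8.31$
J mol$^{-1}$K$^{-1}$ — the rounded constant used in the source arithmetic —
so printed outputs reproduce at their printed precision.

```{r thermo}
solution_thermodynamics(s1 = 62e-9, t1 = 298, s2 = 138e-9, t2 = 310)
```

## Synthetic data: what it emulates, and what it does not

Every generator is a deterministic function of its parameters and a seed,
and noiseless generator output is an exact fixed point of the corresponding
analysis stage:

* `sim_macroscopic_trace()` scales a scheme's normalized prediction and adds
  *stationary* additive Gaussian noise. Real recordings have state-dependent
  (open-channel) noise and rundown; since the fit is plain least squares,
  stationary noise exercises the same code paths.
* `sim_single_channel_trace()` / `sim_cob_events()` run continuous-time
  Markov simulations of independent C-O-B channels (exponential waiting
  times, stationary initial state). No baseline drift, no subconductance
  levels, no filtering artifacts beyond what `gaussian_filter()` introduces.
* `sim_dose_response()` draws multiplicative Gaussian noise around the
  modified Hill curve; `sim_extraction()` forward-simulates the extraction
  spectrophotometry, including the flat second extract.

Passing tests on these fixtures demonstrates correctness of the estimators
under the models' own assumptions, not robustness to rundown, drift, or
filter artifacts in real patches.

## Problem sizes and reproducibility conventions

The test and acceptance workloads use: 10-minute on/off protocols at 0.62 nM
and 62 nM sampled at 1 Hz (2402 residuals per ensemble fit), integration
step 10 ms, a 100-channel patch for the reference fits, 3000-s single-channel
records (~27k dwells) for C-O-B recovery, 8 concentrations x 5 replicates for
dose-response recovery, and fixed seeds throughout. Concentrations may be
entered as multiples of the 1x saturated solution, calibrated by default at
62 nM.

## Known limitations

* The washout rate predicted by the two-site scheme is not exactly
  concentration-independent: after a 1x-saturated exposure the membrane pool
  starts ~230-fold above $K_{d,mem}$ and sustains rebinding for tens of
  seconds, so a single-exponential fit from the moment of removal returns a
  ~14% slower rate than after a 0.01x exposure. The asymptotic tail decays at
  $2k_{off}$ in both cases.
* `fit_cob()`'s missed-event treatment is first-order (see above).
* No hierarchical multi-patch fitting, no confidence intervals beyond SSE
  reporting, no stochastic channel-number fluctuations in the macroscopic
  model, and no modeling of supersaturation or intramembrane precipitates.
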
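---
title: "Quantifying enzyme stability in water-miscible co-solvents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying enzyme stability in water-miscible co-solvents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosolv)
```

## The problem

Biocatalytic reactions frequently need a water-miscible organic co-solvent
(DMSO, methanol, ethanol, propanols, DMF) to keep a hydrophobic substrate in
solution, so the practical question is which enzyme — or which variant from
an engineering campaign — tolerates that co-solvent best. The melting
temperature $T_m$ is the conventional stability proxy, but it is a
*thermal* quantity: it cannot be translated into a co-solvent concentration
up to which the enzyme stays active, and rankings built on it can disagree
sharply with what activity assays show in a given solvent.

`cosolv` works with a solvent-denaturation analogue of $T_m$: the co-solvent
concentration $c_{U50}^{T}$ at which, at a fixed temperature $T$, half of
the protein is unfolded — equivalently, where the free energy of folding
crosses zero. It is measured per enzyme/solvent pair, is directly a
concentration, and sits near the concentration where activity drops
fastest, which makes it usable both for ranking enzymes and for reading off
feasible (temperature, concentration) operating windows.

## Models

### Extended two-state unfolding

An isothermal slice plots a fluorescence signal $y$ (here the nanoDSF
F350/330 ratio) against co-solvent concentration $c$. With two states and
linear instrumental baselines for the folded and unfolded forms,

$$y(c) = \frac{\alpha_F + \beta_F c + (\alpha_U + \beta_U c)\, E(c)}
             {1 + E(c)}, \qquad
  E(c) = \exp\!\left(\frac{m_{folding}}{R T}\,(c - c_{U50})\right),$$

with $R = 8.314\ \mathrm{J\,mol^{-1}K^{-1}}$ and $T$ in Kelvin
(temperatures are degrees Celsius at every public interface and converted
internally). $m_{folding}$ (J mol$^{-1}$ per %(v/v)) is the m-value linking
co-solvent amount to the folding free energy
$\Delta G_{folding}(c) = m_{folding}(c_{U50} - c)$, so that
$m_{folding}(c-c_{U50})/(RT)$ is dimensionless with $c$ in %(v/v). The
unfolded fraction alone is the logistic $E/(1+E)$
([`eval_fraction_unfolded()`]). The model is direction-agnostic: both
baselines are free, so transitions that raise or lower the signal fit
equally well.

Numerically the signal is evaluated as the mixture
$(1-f)(\alpha_F+\beta_F c) + f(\alpha_U+\beta_U c)$ with $f = E/(1+E)$
computed by `stats::plogis()` on its stable branch; this is algebraically
identical to the quotient form but finite for exponent arguments of
$\pm 10^4$ and beyond, where a literal `exp()` would overflow.

### Gaussian-augmented activity model

Specific activity versus co-solvent concentration often shows a *boost* at
low concentrations before unfolding destroys activity. The activity model
adds a Gaussian term to a decaying two-state term:

$$\mathrm{Activity}(c) = \xi\,\frac{1}{\sigma\sqrt{2\pi}}
  \exp\!\left(-\tfrac12\left(\frac{c - c_{A max}}{\sigma}\right)^2\right)
  + \nu\,\frac{E'(c)}{1 + E'(c)}, \qquad
  E'(c) = \exp\!\left(-\frac{m_{folding}}{R T}(c - c_{A50})\right).$$

The exponent sign is negative — the logistic term *decays* with
concentration, with $c_{A50}$ the concentration of steepest activity loss.
$c_{A max}$ is the concentration of maximal activity, $\sigma$ how narrow
the tolerated range is, and $\xi, \nu$ scale the two terms. When the data
show no boost the fitted Gaussian contribution becomes negligible and the
two-state term carries the fit.

## Fitting

Both fits minimise a least-squares cost with `stats::nlminb` (a bounded
quasi-Newton method) under the box constraints: all six unfolding
parameters $\ge 0$ with $c_{U50} \le 100$; and for the activity model
$\xi, \nu, c_{A max}, c_{A50} \ge 0$, $\sigma \ge 10$,
$c_{A max}, c_{A50} \le 100$, $m_{folding}$ unbounded. The activity cost
adds an L2 penalty on the raw values of the two weakly identified
parameters, $0.01\,c_{A max}^2 + 0.001\,\xi^2$; the weights are
configurable and `fit_options(regularize = FALSE)` disables the penalty
entirely, which is how the parameter-recovery tests are run. The penalty is
applied to raw (unscaled) parameter values, whose magnitudes match those
weights at %(v/v) scales.

Design choices where the procedure was genuinely open:

* **Parameter scaling.** Optimizer variables are the parameters divided by
  characteristic scales so all are order one: intercepts by the observed
  signal range, baseline slopes by signal range over concentration range,
  $m_{folding}$ by $RT/\Delta c$, midpoints by the concentration range. In
  the activity fit only $m_{folding}$ needs this; the other parameters are
  already well scaled.
* **Multi-start initialisation.** Deterministic: the midpoint starts at
  25/50/75 % of the largest observed concentration; unfolding baselines
  come from the first/last two points; $m_{folding}$ from a logistic-slope
  heuristic ($10\,RT/\Delta c$); for activity, $c_{A max}$ starts at the
  argmax of the observed activity, $\nu$ at the activity nearest $c = 0$,
  and $\xi$ at 0 and at $(\mathrm{peak}-\mathrm{baseline})\sigma\sqrt{2\pi}$.
  The lowest final cost wins; ties go to the first start. Identical inputs
  therefore always give identical fits.
* **Analyzability.** Some enzymes report unfolding too weakly for the
  F350/330 ratio to carry a usable transition. A fit is flagged
  `analyzable = FALSE` when the fitted baseline separation at the midpoint
  is below 20 % (configurable) of the observed signal range; `c_U50` should
  not be quoted from such fits.
* **Isothermal slicing.** The fixed-temperature signal is read from each
  ramp by linear interpolation between the two adjacent samples.
* **Melting-temperature extraction.** The melt-curve signal is smoothed
  with a local quadratic (Savitzky–Golay) filter over a 7-point window
  (configurable, odd), differentiated centrally, and $T_m$ is the location
  of the maximum absolute derivative, refined by a parabolic fit through
  the peak and its neighbours. A derivative maximum on the first or last
  sample means the transition midpoint is outside the recorded ramp; the
  result is then a boundary-flagged bound (e.g. "> 90 degC") that
  [`delta_tm()`] refuses to use numerically. A curve whose derivative shows
  no clear peak (maximum below 3x its median) raises "no transition
  detected".
* **Linear-range selection for rates.** Among contiguous windows of at
  least 30 % of the trace (and $\ge 5$ points), the longest with
  $R^2 \ge 0.99$ wins, earliest start breaking ties. An $R^2$ criterion
  tolerates grazing the onset of late-time curvature, so slopes from
  strongly curved traces carry a small (few percent) bias; raising
  `r_squared_min` tightens the window at the cost of length. The default
  extinction coefficient 6220 M$^{-1}$cm$^{-1}$ is the standard NAD(P)H
  value at 340 nm — a package default, explicitly configurable. The optical
  path of a microplate well depends on fill volume; ~0.56 cm for 200 µl is
  an approximate example, and the path length is a required input.
* **Rankings.** Most stable first; ties share the average numeric rank and
  the plus-symbol count of their best position; enzymes missing a measure
  are excluded from that ranking, never imputed. The Spearman coefficient
  reported by [`rank_divergence()`] is a supporting statistic added by this
  package. Rankings always use full-precision inputs.
* **Operating windows.** The boundary is interpolated linearly in
  temperature; *strictly below* the curve counts as inside, so a point
  exactly on the boundary is outside. No extrapolation beyond the boundary
  span unless explicitly clamped.

## Synthetic data

The generators draw each dataset from the corresponding model plus i.i.d.
Gaussian noise — the single noise model used throughout, since the
measurement chain suggests no specific heavier-tailed alternative. Noise
can be given in absolute units or as a fraction of the model's transition
amplitude. Every generator is deterministic given a seed, restores the
global RNG state, and attaches its generating truth to the output, so each
fitter can be tested as an estimator of known parameters. The scenario
generator ties everything together: `c_U50` decreases linearly with
temperature (the behaviour consistently seen experimentally) with the
activity midpoint tracking it, defaults of 19 concentrations (0–45 %(v/v)
in 2.5 steps), five temperatures 25–45 °C, triplicate activity wells,
m-value 1.5 kJ mol$^{-1}$ per %(v/v) and a transition amplitude of ~0.2
signal units — magnitudes typical of F350/330 unfolding data.

What passing recovery tests does and does not show: the generators share
the fitted models' functional form, so recovery demonstrates the
correctness and precision of the estimation machinery, not the adequacy of
two-state unfolding for any particular enzyme. Real data add baseline
drift that is not exactly linear, correlated replicate errors, aggregation
artefacts and three-state unfolding, none of which are simulated.

## Problem sizes and tolerances

The shipped tests fit 19-point slices and profiles (seconds per fit), use
100-replicate noise ensembles for precision statements, and 1000 cells for
the SEM-calibration check. Noise-free recovery is asserted to 0.1 %(v/v)
on $c_{U50}$ (0.2 on activity midpoints, matching the reporting precision
of the quantities), 1 % relative on full six-parameter recovery, and the
rate round-trip to $10^{-9}$.

## Limitations

Two-state only: no three-state or multi-domain unfolding, no
temperature-dependent m-values, no $\Delta H/\Delta S$ decomposition.
Kinetics are initial-rate only — no Michaelis–Menten analysis or substrate
depletion correction. Vendor instrument exports must be pre-converted to
the documented long-format CSV schemas. Whether replicate capillaries are
averaged before fitting is left to the caller; the fitters pool whatever
points they are given.
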
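---
title: "Modelling and estimating urethral compliance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and estimating urethral compliance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urocomp)
```

## The scientific problem

Urethral compliance -- the distensibility of the urethra, formally the slope
of its pressure--volume relationship $C = \Delta V / \Delta P$ -- is a
clinically meaningful biomechanical property: a stiff (low-compliance)
urethra after hypospadias repair or stricture behaves very differently from
a healthy one.  Measuring it directly is invasive: the classical approach
seals a short urethral segment, inflates it with air, and regresses cavity
volume on intraluminal pressure.

`urocomp` implements two estimators of this quantity and the statistical
machinery for comparing them:

* **UFD (uroflowmetry + diameter), non-invasive.**  Because intraluminal
  pressure and urinary flow rate $Q$ are (to first order) linearly related,
  the change of the ultrasound-measured anteroposterior diameter $D$ per
  unit change of flow, $C_{UFD} = \Delta D / \Delta Q$ (mm s/ml), carries
  the same elastic information as $\Delta D / \Delta P$ without any
  pressure catheter.  Pressure is varied hydrostatically by raising a urine
  container from 40 to 100 cm above the urethra (1 cm of water column = 1
  cmH$_2$O of gauge pressure).
* **Jesus method, invasive reference.**  A 1-cm segment is sealed and air
  is injected in steps; the gauge reads intraluminal pressure (often in
  PSI).  The cavity volume at each step is *not* observed -- it is
  reconstructed from the ideal-gas (Boyle, isothermal) balance -- and
  compliance is the OLS slope of reconstructed volume on pressure
  (ml/cmH$_2$O).

The package also ships everything needed to validate both estimators by
parameter recovery on simulated specimens, because raw animal measurements
for this design are generally not deposited.

## The forward (simulation) model

A simulated specimen (`tube_spec`) obeys three first-order laws:

* Tube law: $D(P) = d_0 + c_{dp} P$ (an optional quadratic term exists but
  is off by default).  A linear law is the minimal model consistent with an
  estimator that *is* a single slope; anything richer would be
  unidentifiable from the data the devices produce.
* Pressure--flow relation: $Q(P) = q_0 + b_{qp} P$, floored at zero.  The
  non-invasive method's premise is exactly this linearity; the simulator
  makes it true by construction so that recovery tests are well-posed.
* Sealed-cavity gas balance: the cavity volume follows
  $V(p) = v_0 + c_{vp}\,p$ while the trapped gas obeys Boyle's law, so the
  gauge pressure after injecting $v_i$ ml (at ambient pressure) is the
  non-negative root of
  $$p_{atm}(v_0 + v_i) = (p_{atm} + p)(v_0 + c_{vp} p),$$
  a quadratic solved in closed form; a bisection solver of the same balance
  is provided purely as an independent numerical cross-check
  (`method = "bisection"`), and the two agree to $10^{-10}$ relative.

Noise is additive, Gaussian, independent across observations, and floored
to the physical range (flows and pressures at 0, diameters at
$10^{-3}$ mm).  True compliances implied by the model: $c_{dp}/b_{qp}$ for
the diameter-on-flow slope and $c_{vp}$ for the volume-on-pressure slope;
every estimator test in the package is a recovery test against these.

### Default parameter values and why

| parameter | default | rationale |
|---|---|---|
| heights | 40, 50, ..., 100 cm | the device's stated operating range; voiding begins above 40 cmH$_2$O and 100 cm avoids overdistension |
| $d_0$ | 2.0 mm | resting anteroposterior diameter of a rabbit-scale urethra |
| $b_{qp}$ | 0.2 (ml/s)/cmH$_2$O | gives flows of 8--20 ml/s over the height range: small-animal scale, and a flow spread wide enough that flow noise attenuates the fitted slope by only ~1--2% |
| $q_0$ | 0 ml/s | no flow at zero driving pressure |
| $v_0$ | 1.0 ml | sealed 1-cm segment plus catheter dead space |
| injection steps | 0.25 ml steps to 10 ml | syringe-scale increments; the resulting 0--70 cmH$_2$O pressure span keeps the errors-in-variables attenuation of the volume slope small |
| $p_{atm}$ | 1033.2 cmH$_2$O | one standard atmosphere as a water column |
| noise SDs | 0.05 mm, 0.5 ml/s, 2 cmH$_2$O | plausible ultrasound, uroflowmetry, and digital-gauge precisions |
| group medians | 0.247/0.269 mm s/ml; 0.141/0.182 ml/cmH$_2$O | published group medians for control and TIP-repaired rabbit urethras, used as generator targets |
| `between_specimen_cv` | 0.15 | see below |

### Cohort structure and the between-specimen CV

`simulate_cohort()` draws one log-normal latent tissue-elasticity factor
per specimen (median 1, coefficient of variation `between_specimen_cv`)
and scales *both* methods' true compliances by it.  A shared factor is the
biophysically coherent choice -- both assessments probe the same tissue --
and it is what produces the strong within-specimen correlation between
methods that motivates the non-invasive method in the first place;
independent draws would (wrongly) make between-method agreement collapse to
estimation noise.

The CV itself cannot be read off published group IQRs computed from four
animals per group; those are far too unstable.  We instead calibrated it
against the published between-method agreement regime (Spearman
$\rho \approx 0.88$ on paired estimates): with the default noise levels,
`between_specimen_cv = 0.15` yields pooled-cohort Spearman correlations of
about 0.85 (seed-to-seed SD $\approx 0.03$ on 200 specimens).  Note one
subtlety we found while designing this: pooling the two groups *dilutes*
the correlation relative to its within-group value, because the
between-group separation is proportionally much larger for the invasive
compliance (0.141 vs 0.182) than for the non-invasive one (0.247 vs
0.269).

### What the generator does and does not emulate

The simulator reproduces the measurement design (paired assessments,
height-stepped hydrostatic loading, stepped air injection), first-order
elastic behaviour, and instrument noise.  It does **not** model
viscoelastic creep or hysteresis, air leakage past ligatures, probe-angle
artifacts, in-vivo bladder dynamics, or non-Gaussian error contamination.
Passing recovery tests therefore demonstrates that the estimators are
correct *under the stated model*, not that real tissue is first-order
elastic -- that assumption can only be defended experimentally.

## The estimators

Both estimators are plain OLS slopes (no weighting, no robust loss: the
measurement model gives no reason for either, and a slope is the entire
estimand).

* `estimate_ufd_compliance()` regresses diameter on *flow* (never on
  pressure: avoiding pressure measurement is the method's point).  The
  quadratic option reports the derivative of the fitted parabola at the
  mean observed flow, so "compliance" remains a local slope.
* `estimate_jesus_compliance()` converts pressures to cmH$_2$O (1 PSI =
  70.307 cmH$_2$O), reconstructs volumes by inverting the Boyle balance,
  $V = p_{atm}(v_0 + v_{dead} + v_i)/(p_{atm} + p) - v_{dead}$, and
  regresses $V$ on $p$.  The resting volume $v_0$ is a required analysis
  input (it is not identifiable from the pressure trace); since volume is
  affine in $v_0$, mis-specifying it mostly shifts the intercept -- the
  slope moves by only about $\Delta v_0 / p_{atm}$ per unit of error,
  which `jesus_v0_sensitivity()` makes visible.

Known bias: because measured flow (UFD) and measured pressure (Jesus)
appear as *regressors* with noise on them, both slopes suffer classical
errors-in-variables attenuation.  With the default designs this is a 1--2%
downward bias; narrowing the height range or shortening the injection ramp
makes it worse.  This is a property of the published estimators, which the
package reproduces faithfully rather than corrects.

Degenerate inputs are handled explicitly: identical regressor values raise
a degenerate-design error; a flat response (zero response variance) is a
physically meaningful rigid tube and returns slope 0 with $R^2$ reported
as 0 plus a warning.

## The statistical layer

* `median_iqr()` uses linear-interpolation quantiles (R type 7), stated
  because IQR values depend on the convention.
* `compare_groups()` routes on Shapiro--Wilk normality of both groups at
  the conventional 0.05 threshold: Student's t with mean (SD) summaries if
  both pass, otherwise Mann--Whitney with median (IQR) summaries.
* `mann_whitney()` is exact (full permutation-null distribution of the
  rank-sum, midranks, computed by the Streitberg--Roehmel shift algorithm,
  so ties are handled) for combined $n \le 20$; above that a normal
  approximation with tie-corrected variance and continuity correction.
  The two-sided p is twice the smaller tail, capped at 1.
* `spearman_agreement()` enumerates all $n!$ permutations for $n \le 9$
  (the regime of 8-animal paired cohorts) and reports
  $P(|\rho_{perm}| \ge |\rho_{obs}|)$; the t-approximation takes over for
  larger n.
* `bland_altman()` reports bias and limits bias $\pm z \cdot$SD (sample
  SD, $z = 1.96$ default).  By default it runs on raw values even though
  the two methods carry different units (mm s/ml vs ml/cmH$_2$O),
  mirroring common practice in method-comparison reports; a
  `standardize` flag z-scores each method first, with the caveat that the
  limits are then in SD units and no longer clinically interpretable.
* `equivalence_sample_size()` implements Chow's normal-approximation
  equivalence formula
  $n = \lceil (z_{1-\alpha} + z_{1-\beta/2})^2 \sigma^2 (1 + 1/\kappa) /
  (\delta - |\epsilon|)^2 \rceil$ per group.  With $\epsilon = 0.08$,
  $\sigma = 0.07$, $\alpha = 0.05$, power 0.9, $\delta = 0.2$ and 1:1
  allocation it returns 8 per group.  A paired variant (dropping the
  allocation factor) is available behind `design = "paired"`, since a
  self-controlled study could arguably be sized that way; the two-sample
  form is the default because it is what reproduces the published design.

## Pipeline and reproducibility

`run_pipeline()` chains simulate -> estimate (both methods) -> group
comparison -> agreement, writes every stage artifact as CSV, and the full
report as JSON with floats at 9 significant digits, so the same config and
seed give byte-identical reports.  For that reason the provenance block
records config, seed and package version but deliberately **no
timestamp** (run timing goes to stderr logging only); byte-level
reproducibility was judged more valuable than a wall-clock stamp inside
the artifact.  Failures abort with a stage label and remove partial
outputs.

Problem sizes used in the validation suite: 20 randomized tubes for each
zero-noise recovery property; 100 randomized sample pairs (combined
$n \le 10$) against the exact-test enumeration oracles; 4000 replicate
series for the Monte-Carlo noise checks; 100 specimens per group for
cohort-level median recovery and agreement; 10 000 paired differences for
the Bland--Altman closed form.

## Worked example

```{r example}
cfg <- run_config(cohort_spec(n_per_group = 4, seed = 42), quiet = TRUE)
report <- run_pipeline(cfg)
report
```

## Known limitations

* The linearity of the pressure--flow relation is assumed, not estimated;
  in obstructed urethras it fails and the non-invasive estimate loses its
  meaning.
* $v_0$ must be supplied to the invasive estimator; the package can
  quantify, but not remove, the (small) slope sensitivity to it.
* Errors-in-variables attenuation (above) is reproduced, not corrected.
* The exact Mann--Whitney and Spearman routines are exhaustive and
  therefore limited to the small-sample regimes stated; they switch to
  standard approximations beyond them.
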
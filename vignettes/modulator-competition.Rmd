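---
title: "Modelling competition between positive and negative allosteric modulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling competition between positive and negative allosteric modulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomod)
```

## The question the package addresses

NMDA-type glutamate receptors can be potentiated or inhibited by small
molecules acting outside the agonist sites. In a chemical series where a
single methyl group converts a positive allosteric modulator (PAM) into a
negative one (NAM), the natural mechanistic question is whether the two
compounds occupy the same pocket. Functionally this is answerable with a
Schild-type experiment: measure the NAM concentration–response curve in
increasing fixed backgrounds of the PAM. If the two ligands are mutually
exclusive, the PAM acts like a competitive antagonist of the NAM and the
NAM midpoint shifts rightward linearly with PAM concentration; if they can
bind simultaneously at independent sites, the NAM curve stays put.
`allomod` provides the receptor model that makes this prediction
quantitative, plus the fitting machinery around it.

## The receptor model

### States and rates

The base gating scheme is a linear chain

```
R  <->  RA  <->  RA2  <->  O
```

with two sequential agonist binding steps and one gating step. Association
rates are `s_i * k_on * [A]` with statistical factors `s = (2, 1)` (two
equivalent empty sites, then one), dissociation `1x` and `2x` the per-site
`k_off`. The two co-agonists (glutamate and glycine) are collapsed into a
single effective agonist axis: the model is used exclusively at maximally
effective co-agonist concentrations, where the distinction does not affect
the competition analysis, and agonist-potency effects are handled in the
concentration–response module instead.

This chain is replicated into modulator-occupancy layers. With one NAM
(`N`) and one PAM (`P`):

* `MODEL1` (shared site): layers `{free, N, P}` — 12 states. A state with
  both modulators bound does not exist.
* `MODEL2` (independent sites): layers `{free, N, P, NP}` — 16 states.

### Modulator parameters and cycle closure

A modulator is described by four numbers:

| parameter | units | meaning |
|---|---|---|
| `k_on` | 1/(µM·s) | association rate, same from every state |
| `k_off_reference` | 1/s | dissociation from the fully agonist-bound closed state (`RA2`) |
| `gating_factor` `g` | – | multiplies the opening rate `beta` while bound (`>1` PAM, `<1` NAM) |
| `state_dependence_factor` `f` | – | fold-weaker binding to states that are not fully agonist-bound |

Everything else is derived, never set by the user. Thermodynamics fixes it:
around the cycle `RA2 -> O -> O·M -> RA2·M -> RA2` the product of rates
must be equal in both directions (microscopic reversibility), which forces
dissociation from the open state to be `k_off_reference / g`. A modulator
that promotes opening must bind the open state more tightly — efficacy and
state-dependent affinity are two faces of the same coin, and hand-built
schemes that set them independently are silently inconsistent. Similarly,
sub-saturated states bind the modulator `f`-fold weaker, so the final
agonist dissociation step inside a modulator-bound layer is divided by `f`
(the modulator reciprocally tightens agonist binding — this is exactly the
mechanism by which these modulators enhance agonist potency). In the
doubly occupied `MODEL2` layer the factors multiply. Every built scheme is
verified by a detailed-balance check on spanning-tree potentials
(equivalent to checking all cycle products for a reversible graph) at a
relative tolerance of 1e-9.

Large `f` (default 100) reproduces use dependence: the modulator binds
appreciably only after both agonists are bound.

### Default parameterization

The defaults (`default_scheme()`) describe a GluN2D-like receptor:

* agonist `k_on` 10 /(µM·s), `k_off` 50 /s (K_A = 5 µM; 100 µM agonist is
  saturating),
* `beta` 5 /s, `alpha` 500 /s, so the gating equilibrium constant
  `E = beta/alpha = 0.01` — a low open probability, characteristic of
  GluN2D-containing receptors,
* NAM: reference K 0.2 µM, `g = 0.14` (saturating inhibition leaves ~14%
  of control — a submaximal inhibitor, not a channel blocker),
* PAM: reference K 2 µM, `g = 2.5` (saturation potentiates to ~250% of
  control).

The NAM and PAM numbers are chosen to resemble reported potencies and
efficacies of submaximal NMDA receptor modulator series (a NAM with
sub-micromolar IC50 leaving ~14% residual current; a PAM with low
micromolar EC50 potentiating to ~250%). No reference parameterization of
the full kinetic scheme exists for such a series, so these defaults are
this package's own documented choice; comparisons to experimental
dose-ratio data are qualitative (linearity vs flatness of the plot),
never numeric.

The low open probability matters and is worth explaining. In the weak
gating limit (`E -> 0`) the equilibrium response of `MODEL1` at saturating
agonist is proportional to

```
(1 + g_N n + g_P p) / (1 + n + p),    n = [N]/K_N,  p = [P]/K_P,
```

whose NAM midpoint is *exactly* `K_N (1 + p)` — the Gaddum relation, with
dose-ratio slope `1/K_P`, independent of the gating factors. For `MODEL2`
the same limit factorizes into separate `n` and `p` terms, so the NAM
curve is exactly independent of PAM. At `E = 0.01` the corrections of
order `E·g_P·p` are a few percent: Model 1 regresses with `R^2 = 1.000`
and slope 0.46 /µM (vs 0.50 ideal), Model 2 ratios stay within 8% of 1 up
to 10x K_P. A hypothetical high-open-probability receptor would blur this
contrast — the open-state affinity shifts that efficacy requires couple
the two sites through the gate — which is a real thermodynamic effect, not
a numerical artifact.

### Solving the model

The generator (Q) matrix at given ligand concentrations has
concentration-scaled association entries, non-negative off-diagonals and
zero row sums (asserted at 1e-12). Equilibrium occupancy is computed two
ways:

* `solve_equilibrium_nullspace()`: least-squares solution of `pi Q = 0`,
  `sum(pi) = 1` (the reference method);
* `solve_equilibrium_ode()`: stiff integration of `d pi/dt = pi Q`
  (`deSolve::ode`, lsoda, rtol 1e-10 / atol 1e-12) in growing time chunks
  until the derivative max-norm falls below 1e-10, with a 1e4 s horizon
  and an explicit convergence error beyond it.

The two agree to better than 1e-8 max-norm over randomized schemes (the
test suite fuzzes 100 of them), and equilibrium is verified independent of
the starting state. Concentration-jump experiments
(`simulate_relaxation()`) propagate occupancy piecewise through each
protocol segment's Q matrix.

## Concentration–response fitting

Two Hill forms are used, matching how modulator and agonist data are
normalized:

* modulator: `I/I0 = 1 + Extent [M]^h / ([M]^h + EC50^h)` — 1 at zero
  modulator, plateau `1 + Extent` (negative `Extent`, bounded below by -1,
  is inhibition with residual current);
* agonist: `I/Imax = [A]^h / ([A]^h + EC50^h)`.

Fits are per replicate (per cell), by Levenberg–Marquardt
(`minpack.lm::nlsLM`), parameterized internally in `log10(EC50)` — potency
errors are approximately log-normal, summaries are conventionally made on
the log scale, and the optimizer is much better conditioned there.
Multi-start initialization (EC50 at the geometric mean of tested
concentrations and at each tested concentration; `h` at 0.8, 1, 1.5; best
residual wins, ties broken toward the median concentration) makes the fit
deterministic and robust on 5-point curves. A replicate whose response at
the 30 µM probe concentration is within 15% of control is *refused* rather
than fitted — reporting an EC50 for an inactive compound is worse than
reporting none — and non-converged replicates are flagged, never silently
dropped.

`aggregate_log_ec50()` reports the geometric mean EC50 with a t-based CI
computed on `log10(EC50)` and back-transformed (asymmetric in µM, exact on
the log scale); the modulation extent is an arithmetic mean ± SEM.
`fold_shift()` computes potency shifts as the geometric mean of *per-pair*
ratios (control and treated measured in the same cell), not as the ratio
of group means: with log-normal potency scatter the two differ, and the
per-pair form is the one consistent with paired experimental designs. For
the same reason published fold-difference columns cannot generally be
reproduced from published group means, and the package never treats them
as ground truth.

Coverage of the 95% log-EC50 interval was checked by simulation: over 200
seeded 8-replicate experiments with 5% multiplicative noise, the CI covers
the true EC50 in well over 90% of runs.

## Dose-ratio analysis

`dose_ratio_analysis()` fits the NAM curve at each PAM level (each level
normalized to its own NAM-free response — that is how IC50' is defined),
forms dose ratios against the PAM-free baseline, and regresses
`(ratio - 1)` on `[PAM]` by OLS. Verdict thresholds, both configurable:

* `INDEPENDENT_SITES` if max `|ratio - 1| <= 0.10` across levels (checked
  first: a flat relation can still regress "significantly" when residuals
  are tiny);
* `SHARED_SITE` if `R^2 >= 0.98` and the slope's 95% CI excludes zero;
* `INDETERMINATE` otherwise.

The defaults are deliberately far from both behaviours' observed values
(Model 1 gives `R^2 ~ 1`, Model 2 gives deviations of a few percent), so
the verdict is stable across wide parameter sweeps (tested over K_d 0.1–10
µM, NAM `g` 0.05–0.5, PAM `g` 2–10). The spread of fitted Hill slopes
across levels is reported as a parallel-shift diagnostic but does not gate
the verdict. The closed-form Gaddum curves (`simulate_crc_gaddum()`) serve
as the analytic oracle: ratios `{1, 2, 3, 5}` at `[P]/K_P = {0, 1, 2, 4}`,
slope exactly `1/K_P`.

`predict_independent_action()` implements the null for co-applied
modulators at independent sites — multiply the extents of the independent
actions (in percent of control, `a*b/100`) — and `compare_combination()`
tests observed co-applications against it with a paired t test,
reporting "no detectable difference" instead of a p value when the
differences are degenerate.

## Relaxation kinetics

Modulation onset/offset is fitted with `dI(t) = A (1 - e^(-t/tau)) + c`,
optionally plus a linear term `m t` for records where a slow second
modulation phase rides on the primary relaxation (the package deliberately
does not fit double exponentials: the slow phase is poorly identified in
such records, and a linear component is the honest descriptive choice; its
slope is recorded but not mechanistically interpreted). Fitting is
separable least squares: `A`, `c`, `m` are solved exactly for each
candidate `tau`, and `tau` is optimized on a 60-point log grid spanning
the trace duration with local refinement — deterministic, no starting
values, immune to the usual exponential-fitting pathologies. Traces
without exponential structure (flat, or model R² below 0.2) are flagged
rather than given meaningless parameters.

`rate_regression()` applies the pseudo-first-order treatment: observed
onset rates obey `1/tau = k_ON [M] + k_OFF`, so an OLS line gives `k_ON`
(slope), `k_OFF` (intercept) and `K_d = k_OFF/k_ON`; washout time
constants estimate `k_OFF` directly and a >2-fold disagreement with the
intercept is flagged. A non-positive slope is an error (`K_d` undefined),
not a number. The identity `K_d * k_ON = k_OFF` holds exactly in every
output by construction. Time units are seconds throughout the receptor
kinetics and minutes for racemization.

## Racemization

A purified enantiomer racemizes by a first-order reaction, so any activity
proxy relaxes exponentially to the racemic level:
`y(t) = y_inf + (y0 - y_inf) e^(-kt)`, half-life `ln 2 / k`. The fit is
the same separable-LS machinery. Because the racemate itself is available
as a reference compound, its activity — the asymptote — can be measured
directly; `fit_racemization(series, asymptote = ...)` fixes it, which
substantially sharpens the rate estimate (the free-asymptote fit leaves
rate and asymptote strongly correlated on series spanning a few
half-lives). The noisy-recovery checks use six series sampled every 12
minutes over 18 hours with the asymptote fixed; with that design the mean
of six half-life estimates is reliably within 5% of truth at 5%
multiplicative noise, whereas a sparse free-asymptote design (21 points
over 12 h) leaves ~20% per-series scatter.

## Mutant-panel classification

Mutant responses in a fixed modulator concentration are normalized per
replicate to the same cell's agonist-only response (percent of control),
then each construct is compared with wild type using t-based confidence
intervals at the 99% level — the t distribution is the appropriate choice
for the small per-construct samples (4–18 cells) typical of such screens,
and the wild-type reference, re-recorded across experimental days, is
pooled into one larger sample. Overlapping CIs give `UNCHANGED`. For
non-overlapping CIs the category is defined geometrically relative to the
100% line (no modulation): on the wild-type side of 100 and closer to it
is `LOSS`, farther from 100 is `AUGMENTED`, on the opposite side is
`INVERTED`. These boundaries are this package's explicit definition of the
informal loss/augmented/inverted vocabulary; they are mirror-symmetric
through 100% (a potentiator's loss mirrors an inhibitor's loss), and
raising the CI level can only move calls toward `UNCHANGED`, never between
the effect categories.

## Synthetic data

Every generator is a pure function of (truth, design, noise config, seed);
RNG state is restored after each call, the same seed reproduces output
byte-identically, and noiseless output is exactly the underlying model.
Noise defaults: multiplicative lognormal with 5% CV for concentration–
response amplitudes (voltage-clamp response scatter is proportional; the
noise factor's mean is exactly 1 so large-replicate averages converge on
the model), additive Gaussian for current traces (instrument noise).
The default CRC design is five half-log concentrations (0.3–30 µM) with
4–18 replicates.

What the generators deliberately do **not** emulate: receptor
desensitization (which in real cells modulates the apparent extent of
modulation), trace-level drift and seal instability, contaminant glycine
artifacts in nominally glycine-free solutions, voltage-dependent effects
(the modulators modelled here are voltage-independent), and oocyte-batch
effects. Passing parameter-recovery tests on these fixtures therefore
demonstrates correctness of the estimators under their stated noise
models, not robustness to every pathology of real recordings.

## Problem sizes and numerical tolerances

The test and acceptance runs use: 100 randomized schemes for the
solver-equivalence fuzz (agreement < 1e-8 max-norm; occupancies sum to 1
within 1e-10; cycle imbalance < 1e-9 relative); 200 seeded experiments
(n = 8, 5% noise) for CI coverage; 200 seeded panels for classifier
accuracy; traces of 251 samples for kinetic fits; a 2000-step log-spaced
EC50 grid as the brute-force fitting oracle. These sizes were chosen so
the whole suite runs in a few minutes on a single core while leaving the
statistical checks well-powered.

## Known limitations

* The inverse problem — fitting the receptor model's rate constants to
  experimental concentration–response surfaces — is out of scope.
* Only the two stated topologies are implemented; ternary-complex
  cooperativity models (simultaneous binding with interaction) are not.
* Single-channel (stochastic) simulation, desensitized states and voltage
  dependence are not modelled.
* The dose-ratio verdict is a diagnostic with deliberately conservative
  thresholds, not a hypothesis test with a calibrated error rate.
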
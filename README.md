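# allomod

Quantitative pharmacology of competing positive and negative allosteric
modulators (PAMs and NAMs) of NMDA-type glutamate receptors.

Some NMDA receptor modulator series can be interconverted between
potentiators and inhibitors by minor chemical changes, raising a mechanistic
question: do the PAM and the NAM occupy one shared site (mutually exclusive
binding) or two independent sites? `allomod` implements the modelling and
analysis machinery used to answer that question from functional data:

* **Equilibrium Markov receptor models.** The receptor is a
  continuous-time Markov chain `R <-> RA <-> RA2 <-> O` (two agonist binding
  steps with statistical factors 2/1, then a gating step), replicated into
  modulator-occupancy layers. Topology `MODEL1` allows either modulator but
  never both (shared site); `MODEL2` adds the doubly occupied layer
  (independent sites). A modulator is specified by `k_on`,
  `k_off` from the fully agonist-bound closed state, a gating factor `g`
  multiplying the opening rate `beta` while bound, and a use-dependence
  factor. All remaining dissociation rates are **derived by thermodynamic
  cycle closure** (e.g. `k_off` from the open state is `k_off/g`), so every
  cycle satisfies microscopic reversibility by construction. The generator
  (Q) matrix is solved for its stationary distribution both algebraically
  and by stiff ODE relaxation, and concentration-jump experiments are
  simulated by piecewise propagation.

* **Dose-ratio (Schild-type) diagnostic.** NAM concentration–response
  curves are simulated (or measured) in fixed PAM backgrounds, each level
  normalized to its own NAM-free response, and fitted with the Hill
  equation `I/I0 = 1 + Extent [M]^h / ([M]^h + EC50^h)`. For a shared site
  the shifted midpoint follows the Gaddum relation
  `IC50' = IC50 (1 + [P]/K_P)`, so `(IC50'/IC50 - 1)` is linear in `[P]`
  with slope `1/K_P`; for independent sites the ratios stay pinned at 1.
  `dose_ratio_analysis()` fits, regresses and returns a
  `SHARED_SITE` / `INDEPENDENT_SITES` / `INDETERMINATE` verdict.

* **Hill machinery.** Per-replicate Levenberg–Marquardt fits in
  `log10(EC50)` with multi-start initialization, geometric-mean EC50
  summaries with t-based CIs on the log scale, paired potency fold shifts,
  and the convention that a compound changing the response by less than 15%
  at 30 µM is reported as "not fit".

* **Relaxation kinetics.** Exponential (and exponential-plus-linear)
  fitting of modulation onset/offset by separable least squares, and the
  pseudo-first-order regression `1/tau = k_ON [M] + k_OFF` giving the
  kinetic dissociation constant `K_d = k_OFF / k_ON`.

* **Combination nulls and mutant scans.** Independent-action predictions
  (`predicted % = a*b/100`) with paired t comparisons, and 99%-CI
  classification of mutant panels as UNCHANGED / LOSS / AUGMENTED /
  INVERTED relative to wild type.

* **Synthetic data.** Seeded generators for every input (CRC tables,
  relaxation traces, racemization series, mutant panels) with stated noise
  models, so the entire pipeline is testable with no external data.

## Worked example

Discriminate the two binding topologies from simulated equilibrium
responses:

```r
library(allomod)

sch <- default_scheme("MODEL1")      # shared-site demo parameterization
crc <- simulate_crc_grid(sch, nam_concs = 10^seq(-2.5, 2, by = 0.5),
                         pam_concs = c(0, 2, 4, 8))
dose_ratio_analysis(crc)
```

```
Dose-ratio analysis of modulator competition
 pam_uM ic50_prime_uM dose_ratio hill_slope
      0        0.2220      1.000          1
      2        0.4267      1.922          1
      4        0.6314      2.845          1
      8        1.0410      4.689          1
(ratio - 1) vs [PAM]: slope 0.4611 /uM [0.4611, 0.4611], intercept 8.299e-15, R^2 1.0000
Verdict: SHARED_SITE
```

The NAM IC50 (0.22 µM at zero PAM, close to the NAM's reference K of
0.2 µM) shifts rightward in proportion to the PAM concentration; the slope
0.46 /µM approximates `1/K_P` for the PAM's reference K of 2 µM (small
deviations reflect the open-state affinity shift that efficacy
thermodynamically requires). The same analysis on `default_scheme("MODEL2")`
leaves every dose ratio within 8% of 1 and returns `INDEPENDENT_SITES`.

Kinetic `K_d` from synthetic relaxation traces:

```r
tr <- generate_traces(k_on = 0.3, k_off = 1.2, concentrations = c(1, 3, 10))
taus <- sapply(tr$onset, function(x) coef(fit_relaxation(x, "exp"))[["tau"]])
rate_regression(data.frame(concentration_uM = c(1, 3, 10), tau = taus))
```

```
Rate regression (1/tau = k_ON [M] + k_OFF, R^2 1.0000):
  k_ON 0.3 /(uM s), k_OFF 1.2 /s  =>  K_d 4 uM
```

## Command line

A thin wrapper over the same functions lives at `inst/cli/allomod.R`:

```sh
Rscript inst/cli/allomod.R dump-default-config --outdir cfg
Rscript inst/cli/allomod.R dose-ratio --config my-analysis.yaml --outdir out
```

Every run writes a `report.json` carrying a provenance record (package
version, config hash, seed); identical configs reproduce outputs
byte-identically.

See the methods vignette (`vignettes/modulator-competition.Rmd`) for the
model assumptions, parameter defaults and their rationale, numerical
choices, and known limitations.
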
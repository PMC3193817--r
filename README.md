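# p2x3kinetics

Kinetic modelling and whole-cell trace analysis of P2X3 receptor currents.

P2X3 receptors are ATP-gated cation channels of nociceptive sensory
neurons. Activated by agonists such as α,β-methylene-ATP they produce fast
inward currents that desensitize almost completely within a 2-s
application and take tens of seconds to recover — so the measurable
fingerprint of any change in receptor function is a handful of trace
features: peak amplitude (or current density in pA/pF), 10–90% rise time,
the fast and slow time constants of a biexponential decay fit, and the
paired-pulse recovery at a 30-s interval. This package is for
electrophysiologists and modellers who want to connect those features to
receptor kinetics quantitatively.

At its core is a cyclic 10-state Markov scheme: three sequential
agonist-binding steps on a non-desensitized branch
(R ⇌ AR ⇌ A₂R ⇌ A₃R, rates k₁–k₃/l₁–l₃), gating of the fully occupied
receptor to the single open state (A₃R ⇌ A₃Rₒ, k₄/l₄), a desensitized
branch (D ⇌ AD ⇌ A₂D ⇌ A₃D ⇌ A₃D_f, m/n rates) and five vertical
desensitization/resensitization pairs (d/r), of which d₅ routes the open
state straight into the fast-desensitized state. Occupancies obey
mass-action kinetics dx/dt = Q(c)·x, with the agonist concentration c
entering the six binding steps linearly; the open-state occupancy A₃Rₒ is
the current readout. Two published rate-constant sets ship with the
package: `"control"`, and `"MbCD"` for receptors after membrane
cholesterol depletion with methyl-β-cyclodextrin (k₄ reduced; d₅, n₄ and
n₁–n₃ increased).

The package provides, as testable modules:

* `p2x3_scheme()`, `load_rate_set()`, `build_generator()`,
  `steady_state()` — scheme, validated rate sets, generator matrix;
* `simulate_trace()`, `simulate_paired_pulse()`, `propagate_expm()` —
  stiff ODE simulation under piecewise-constant agonist protocols, plus an
  independent matrix-exponential oracle;
* `analyze_trace()`, `fit_biexponential()`, `compare_groups()`, … — the
  trace features above and the group statistics papers report;
* `fit_rates()` — a seeded, bounded, derivative-free optimizer replacing
  manual rate tuning, with parameter-recovery validation;
* `generate_population()` — synthetic noisy whole-cell recordings with
  realistic per-cell variability, for end-to-end pipeline tests;
* `reproduce_figure5()`, `run_full_pipeline()` — one-call reproduction of
  the paired-pulse simulation comparison, and a configurable
  synth → analyze → compare → fit pipeline with provenance records.

## Worked example

```r
library(p2x3kinetics)

control <- load_rate_set("control")
mbcd    <- load_rate_set("MbCD")

# two 2-s pulses of 0.01 mM agonist, 30 s apart
pp  <- simulate_paired_pulse(control)
ppm <- simulate_paired_pulse(mbcd)
ft  <- analyze_trace(pp$trace)
ftm <- analyze_trace(ppm$trace)

round(c(control = pp$recovery_percent, MbCD = ppm$recovery_percent), 2)
#> control    MbCD
#>   24.36   19.13
round(c(control = pp$first_peak, MbCD = ppm$first_peak), 3)
#> control    MbCD
#>   0.531   0.379
round(c(control = ft$tau_slow, MbCD = ftm$tau_slow), 2)
#> control    MbCD
#>    3.05    1.92
```

Reading: with control kinetics the second response recovers to about 24%
of the first after 30 s — the model's headline number. The
cholesterol-depleted set gives a smaller peak open probability (0.38 vs
0.53, from slower gating k₄), a faster slow decay (fitted τ_slow 1.9 vs
3.1 s, from faster entry into the fast-desensitized state) and poorer
recovery (19% vs 24%), while rise time and τ_fast change by under 15% —
the full functional fingerprint of raft disruption, from six rate-constant
changes.

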
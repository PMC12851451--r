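# icalternans

Beat-to-beat alternans analysis of whole-cell voltage-clamp calcium-current
recordings.

Cardiac alternans — an every-other-beat alternation in a myocyte's electrical
response — precedes atrial fibrillation. In voltage-clamped cardiomyocytes it
appears as sweep-to-sweep alternation of the L-type calcium current (I_Ca)
and of the Na⁺/Ca²⁺-exchanger tail current. `icalternans` is for
electrophysiologists who record pulse-train protocols (hold −80 mV → 50 ms
pre-pulse to −45 mV → 200 ms step to 0 mV → return to −80 mV, repeated ~30
times) and want, per sweep, the six classical features

* `PeakCa` — I_Ca peak amplitude (pA, relative to the steady-state baseline),
* `Q_Ca`, `Q_Tail` — trapezoidal charge areas (pA·ms) starting 2 ms after the
  step onset / the repolarization, against an m-point steady-state baseline
  (m = 20 and 10),
* `τ` — single-exponential I_Ca inactivation constant,
* `τ₁ < τ₂` — fast/slow tail decay constants from a double-exponential fit,
  the model chosen by AIC (least-squares form, k = 4 vs k = 5),

and, on top of them, a scalar **alternation index** per feature series
`m(t)`:

    D(t)  = m(t) − m(t−1)
    CIdx  = mean(D²) / max(D²)   ∈ [0, 1]

CIdx is 1 for perfect square-wave alternation, near 1/(N−1) for an isolated
jump, scale- and shift-invariant, and order-sensitive. The package also ships
a circuit-level simulator of the whole experiment (one-compartment passive
cell, 4th-order Bessel acquisition filter, parametric ionic currents with
analytic ground truth, MAD-calibrated Gaussian noise) and the non-parametric
group statistics (two-sided Wilcoxon rank-sum, mean ± SEM, star notation)
used to compare uniform and alternating cell populations.

## Worked example

Simulate one noisy sweep with known ground truth and extract its features:

```r
library(icalternans)

sim   <- simulate_sweep(noise = noise_model(seed = 11))
feats <- extract_sweep_features(sim$sweep)
round(unlist(feats), 2)
#>  peak_cap_pA   peak_ca_pA peak_tail_pA    q_ca_pAms  q_tail_pAms
#>      2358.87      1777.13       428.14     47252.28      5042.84
#>       tau_ms      tau1_ms      tau2_ms
#>        25.27         4.06        39.03
round(unlist(sim$truth), 2)
#>  peak_ca peak_tail      q_ca    q_tail      tau     tau1     tau2
#>  1796.18    428.99  47769.37   8972.57    25.00     4.00    40.00
```

The calcium-side features land within ~1 % of the analytic truth; `q_tail`
is the noisiest feature by construction (a 10-point baseline across a
~650 ms window). Now a whole alternating cell and its alternation indices:

```r
cell <- generate_cell(alternation = alternation_model(depth = 0.3),
                      noise = noise_model(seed = 11), cell_id = "demo")
fm <- extract_recording_features(cell$recording,
                                 features = c("peak_cap", "q_ca", "q_tail"))
index_over_features(fm[c("q_ca_pAms", "q_tail_pAms")])
#>       feature      cidx n_used degenerate
#> 1   q_ca_pAms 0.9265449     30      FALSE
#> 2 q_tail_pAms 0.2104559     30      FALSE
```

A CIdx of 0.93 on Q_Ca flags strong, regular beat-to-beat alternation; a
uniform cell under the same noise scores ~0.2 (its differences are noise,
so one excursion dominates the maximum). Q_Tail's index is diluted here
because its sweep-to-sweep noise rivals the imposed 30 % modulation. `run_simulate()` /
`run_analyze()` wire the same steps over dataset directories (ASCII sweep
files in, per-cell feature CSVs, a dataset CIdx table and a
uniform-vs-alternant comparison out), and `inst/cli/icalternans` exposes
them as `simulate` / `analyze` / `validate` subcommands.

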
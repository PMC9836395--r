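# runtcoop

Thermodynamic (states-and-weights) modelling of transcriptional repression
by the Runt repressor acting on Bicoid-activated *hunchback* P2 synthetic
enhancers in the early *Drosophila* embryo, with a hierarchical Bayesian
inference cascade that asks: do parameters inferred from simple enhancer
architectures predict complex ones, or must higher-order cooperativities be
invoked?

The package is for quantitative biologists dissecting enhancer grammar with
equilibrium models: it provides the microstate model for 0–3 repressor
binding sites, a synthetic-embryo data generator with the statistical
structure of MS2 live-imaging measurements, trace preprocessing, an
adaptive-Metropolis sampler, AIC model comparison across cooperativity
scenarios, and conversion of cooperativities to interaction free energies.

## The model

Transcription follows the occupancy hypothesis,
`rate = R * p_bound`, with `p_bound` computed from equilibrium statistical
weights. With dimensionless occupancies `b = [Bicoid]/Kb`,
`r = [Runt]/Kr`, `p = [RNAP]/Kp`, six Bicoid sites in the strong-
cooperativity (all-or-none) limit, and direct Runt–RNAP repression, the
one-site rate is

```
            p + b^6 p w_bp + r p w_rp + b^6 r p w_bp w_rp
rate = R ─────────────────────────────────────────────────────────
         1 + b^6 + r + b^6 r + p + b^6 p w_bp + r p w_rp + b^6 r p w_bp w_rp
```

Two-site constructs add a Runt–Runt pair term `w_rr` and a
Runt–Runt–RNAP higher-order term `w_rrp`; the three-site construct
multiplies in all pairwise terms plus `w_rrr` and `w_rrrp`. A microstate's
weight multiplies every interaction term whose full set of parties is
bound; `w = 1` is no interaction, and energies follow the Boltzmann
relation `w = exp(-E/kBT)`.

Inference is a fix-then-infer cascade over the eight constructs
(`000` … `111`): activation parameters per construct from repressor-null
profiles (stage A), a shared Runt dissociation constant and per-site
`w_rp` from the one-site constructs (stage B), pair cooperativities with a
four-scenario AIC comparison from the two-site constructs (stage C), and
`w_rrrp` from the three-site construct (stage D).

## Worked example

```r
library(runtcoop)

# a synthetic study: TF gradients + initial-rate profiles for all eight
# constructs in both genotypes, 17 AP bins, 3 embryos each
study <- simulate_study(seed = 1)

# one activation fit on repressor-null data
fit <- thermo_fit(study$profiles[["000_runt_null"]], study$bicoid,
                  free = list(Kb = c(1, 1e3), omega_bp = c(1e-3, 1e3),
                              p = c(1e-6, 1), R = c(1, 1e5)),
                  n_steps = 10000, seed = 1)
print(fit)
#> Thermodynamic enhancer model fit
#>   data: [000] runt_null
#>   4 free parameter(s), 10000 MCMC steps, acceptance 12.8%
#>   parameter      mean        sd      q2.5    q97.5
#> 1        Kb 3.498e+01   2.95998 3.083e+01  41.5607
#> 2  omega_bp 4.423e+02 264.92834 7.677e+01 951.2377
#> 3         p 5.891e-03   0.00443 9.804e-04   0.0182
#> 4         R 4.959e+02 183.16381 3.054e+02 992.1320
```

The generating truth is `Kb = 30`: the Bicoid dissociation constant is
recovered to within ~15% at this chain length, while `omega_bp` is weakly
identified (its wide posterior drags `p` and `R` along a ridge — the model
only constrains `p*(1 + b^6*omega_bp)` and `R`), which is why downstream
stages inherit the maximum-posterior sample rather than coordinate means.

```r
# the full cascade, then the interaction free-energy table
cascade <- run_cascade(study, cascade_config(n_steps = 10000), seed = 1)
print(cascade$energy_table, digits = 3)
#>     parameter construct energy_mean_kbt energy_sd_kbt manually_set
#> 1    omega_rp       001           1.644         1.148        FALSE
#> 2    omega_rp       010           1.034         0.268        FALSE
#> 3    omega_rp       100           0.194         0.344        FALSE
#> 4    omega_rr       011           0.000         0.000         TRUE
#> 5   omega_rrp       011           0.259         3.774        FALSE
#> 6    omega_rr       110          -0.937         0.763        FALSE
#> 7   omega_rrp       110           3.094         2.199        FALSE
#> 8    omega_rr       101           0.000         0.000         TRUE
#> 9   omega_rrp       101           1.089         3.268        FALSE
#> 10  omega_rrr       111           0.000         0.000         TRUE
#> 11 omega_rrrp       111           0.220         3.852        FALSE
```

Energies are in kBT (`E = -ln w`; negative = favorable co-occupancy).
Rows flagged `manually_set` are cooperativities fixed to 1 (0 kBT) by the
cascade design, not inferred. The generating truths were
2.34 / 1.36 / 0.18 kBT for the Runt–RNAP terms (repression weakening with
distance from the promoter), −0.95 kBT for the Runt–Runt pair of \[110\],
and −2.09 / 4.15 / 1.12 / 2.12 kBT for the higher-order terms: every
recovered mean lies within about one posterior SD of its truth, with the
higher-order pair terms carrying the widest posteriors (the
pair-vs-higher-order channels are only weakly separable at these Runt
occupancies — see the methods vignette).

`summary(cascade)$comparisons[["110"]]` shows the four-scenario AIC table;
`write_cascade_report(cascade, "outdir")` persists chains, summaries, AIC
tables, the energy table, and a config echo, byte-reproducibly from the
seed.

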
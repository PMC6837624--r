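# izhifit

Automated fitting of simple phenomenological neuron models to
firing-pattern phenotypes of hippocampal neuron types.

Neuron types in the hippocampal formation are characterized by the classes
of somatic spike patterns they produce under step-current injection
(adapting, non-adapting, delayed, stuttering, slow-wave bursting, ...) and
by quantitative features of those patterns. `izhifit` builds Izhikevich-type
models — single-compartment, or compact multi-compartment with asymmetric
electrical coupling — that reproduce such phenotypes:

* a fixed-step simulator for the nine-parameter model
  `C dV/dt = k (V - Vr)(V - Vt) - U + I`, `dU/dt = a (b (V - Vr) - U)`,
  with the reset `V >= Vpeak -> V <- Vmin, U <- U + d`, plus tree-coupled
  compartments with interaction currents `Iprox = G P (Vprox - Vdist)`,
  `Idist = G (1 - P) (Vdist - Vprox)` (Rcpp core);
* spike-pattern feature extraction: first-spike latency (*fsl*), inter-spike
  intervals (*nISIs*), adaptation magnitude (*sfa*), post-spike silence
  (*pss*), burst metrics (*bw*, *pbi*, *n_bursts*, *b_nISIs*), delay factor;
* a classifier for the firing-pattern taxonomy in dot notation
  (`"ASP.SLN"`, `"D.NASP"`, `"TSWB.SLN"`, `"RASP.ASP."`, ...);
* the feature-weighted log error
  `sum_f W_f log(1 + |exp_f - model_f|)` with dynamic class-mismatch
  weights, plus four dendritic constraint errors (relative rheobase, input
  resistance, spike-propagation ratio, somatic EPSP window);
* an evolutionary search (`fit_phenotype()`) emitting clouds of accepted
  models, every member of which re-verifies from scratch;
* standardized in-silico probes: rheobase, voltage deflection, forward
  propagation ratio, EPSP amplitude, back-propagation attenuation, rebound
  rheobase, dendro-somatic gating;
* association statistics for parameter-property screens: Barnard's
  unconditional exact test, sign/tertile encoding, Benjamini-Hochberg FDR.

## Worked example

Fit the DG Total Molecular Layer phenotype — three adapting (`ASP.`)
patterns with ISI counts 5/9/19 and adaptation magnitudes 0.142/0.082/0.032
at +0.073/+0.102/+0.205 nA:

```r
library(izhifit)

spec <- hippocampome_phenotypes()$dg_total_molecular_layer
fit  <- fit_phenotype(spec, ea_config(pop_size = 120, generations = 150,
                                      seed = 1))
glance(fit)
#> # A tibble: 1 × 5
#>   phenotype                n_accepted best_error generations  seed
#>   <chr>                         <int>      <dbl>       <int> <dbl>
#> 1 DG Total Molecular Layer          1      0.598          14     1

model <- fit$accepted[[1]]$model
st    <- step_stimulus(0.073, units = "nA")
res   <- classify_trace(simulate_model(model, st), st)
format(res$label); res$features$n_isis; round(res$features$sfa, 3)
#> [1] "ASP."
#> [1] 5
#> [1] 0.151
```

The fitted model reproduces the target class at every current, the exact
ISI counts, and the adaptation magnitude within the acceptance tolerance
(+/- 0.01). `autoplot(fit)` shows the error trajectory;
`autoplot(simulate_model(model, st))` the membrane-potential trace;
`write_param_csv()`, `write_fit_file()` and `write_xpp_ode()` export the
result.

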
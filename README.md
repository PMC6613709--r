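# gadoflux

Model-based estimation of liver function from gadoxetate-enhanced MRI.

## The problem

Gadoxetate (Gd-EOB-DTPA) is a liver-specific MRI contrast agent: it is
taken up by hepatocytes through OATP1-family transporters and excreted
into bile via MRP2. Because these transporters also clear bilirubin,
drugs and other organic solutes, the kinetics of gadoxetate — visible as
the change in longitudinal relaxation rate, ΔR1, in liver and spleen over
a ~30-minute examination — carry direct mechanistic information about
liver function. `gadoflux` is for researchers in quantitative liver MRI
and pharmacometrics who want to turn such ΔR1 time series into
per-patient transporter rate constants, test whether a short (≤10 min)
protocol suffices, and relate the rates to histological fibrosis stage.

## The model

A whole-body compartment model with hepatocyte (C_hep), blood plasma
(C_p) and extracellular-extravascular (C_ees) pools:

    dC_hep/dt = k_ph·C_p·Alb − k_hp·C_hep − k_hb·C_hep
    dC_p/dt   = [ (k_hp·C_hep − k_ph·C_p·Alb)·V_l·v_h − CLr·C_p·Alb
                  + k_diff·(C_ees − C_p·Alb)·V_ees + u(t) ] / V_p
    dC_ees/dt = k_diff·(C_p·Alb − C_ees)

with the signal layer

    ΔR1_liver  = ξ·(C_hep·v_h·r1_hep + C_p·v_pl·r1_p + C_ees·v_eesl·r1_ees)
    ΔR1_spleen = ξ·(C_p·v_ps·r1_p + C_ees·v_eess·r1_ees)

Five parameters are estimated per subject: k_diff (plasma↔EES exchange),
k_ph (OATP1 uptake), k_hp (MRP3 back-flux), k_hb (MRP2 biliary
excretion), and the arbitrary signal scale ξ. Two estimation routes are
provided:

* **STS** — each patient fitted independently by minimizing the χ² cost
  Σ (ŷ−y)²/σ², σ being the ROI SEM floored at the cohort uncertainty
  limit 0.18; goodness of fit tested against χ²(df = #observations).
* **NLME** — lognormal random effects on the rates and a normal effect on
  ξ (p = θ·e^η or θ+η); per-patient MAP estimates alternate with
  population (θ, ω) updates in an EM-style scheme. Shrinkage towards the
  population is what keeps short-protocol estimates stable.

The ODE system is linear with a rectangular-pulse input, so the forward
solver evaluates the exact spectral closed form (compiled, ~60 µs per
trajectory); `deSolve::lsoda` is retained as an independent cross-check.

## Worked example

```r
library(gadoflux)

# a virtual cohort with the clinical fibrosis-stage mix
gen <- generate_cohort(cohort_spec(n_patients = 20,
                                   stage_counts = c(F0 = 6, F1 = 4, F2 = 4,
                                                    F3 = 4, F4 = 2),
                                   seed = 1))
fit <- fit_population(gen$cohort)
sapply(fit$population$distributions, `[[`, "theta")
#>       k_diff         k_ph         k_hp         k_hb           xi
#> 1.653602e-03 3.565356e-03 2.813503e-05 3.823923e-05 1.563906e+00

est <- fit$estimates[[1]]
est$params$k_ph          # hepatocyte uptake, this patient (s^-1)
#> [1] 0.005378384
est$gof
#> chi-square goodness of fit: chi2 = 3.09 on df = 8 (critical 15.51 at alpha = 0.05) -> pass
```

The fitted typical uptake (θ(k_ph) ≈ 3.6e-3 s⁻¹) sits below the healthy
prior 4.7e-3 s⁻¹ because the cohort contains fibrotic patients with
reduced OATP1 function; the per-patient goodness-of-fit verdict accepts
the model when χ² stays under the 95% quantile at df equal to the number
of fitted observations. `truncation_experiment()` repeats the fits with
only ≤10-min data and tests the prediction of the held-out 20/30-min
points; `advanced_fibrosis_confusion()` classifies advanced fibrosis
(≥F3) from k_ph at the 0.00198 s⁻¹ cut-off.

The numbered scripts under `analysis/` run the full study: simulate the
91-patient cohort, fit STS and NLME, run the short-protocol experiment,
predict blood/biopsy concentrations, and produce the fibrosis-stage
statistics. Each writes its tables under `results/`.

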
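# dphpk — a human PBPK model for the plasticiser DPHP

`dphpk` is an R package for interpreting human biomonitoring data on
di-(2-propylheptyl) phthalate (DPHP), a high-molecular-weight plasticiser,
after single oral doses.  It is aimed at toxicokinetic modellers and
exposure scientists who need to connect blood concentrations of DPHP and
its monoester metabolite MPHP with urinary excretion of the second-order
metabolites OH-MPHP and cx-MPHP.

The biomonitoring phenomenology is counter-intuitive: the metabolite MPHP
peaks in blood *before* the parent, urinary metabolites peak before the
parent peaks in blood, and the urinary excretion rate shows secondary
peaks ("harmonics") at roughly 8-hour intervals.  The package's core is a
two-chemical physiologically based pharmacokinetic (PBPK) model, solved as
a system of delay differential equations, that reproduces all three
features through:

* a **lymphatic uptake** fraction (`FracDOSELymph`) that reaches venous
  blood at the thoracic duct after a lag, bypassing first-pass metabolism;
* **very high plasma protein binding** — only the unbound fraction
  `fu` exchanges with tissues, so `CL_H = Q_H fu CLint / (Q_H + fu CLint/R)`
  (the well-stirred summary) is small even though the scaled intrinsic
  clearance `CLint = (ln 2 / T_1/2) (mL incubation / mg protein) · MPY · V_li`
  from microsomal substrate depletion is enormous;
* **enterohepatic recirculation** — first-order biliary export of liver
  DPHP and MPHP returning to the gut lumen after a transport lag, in
  competition with faecal loss.

Around the core model the package provides the full analysis pipeline:
in-vitro-to-in-vivo parameter derivation, uncertainty analysis over a
maximin Latin hypercube, two-phase global sensitivity analysis (Morris
elementary effects screening with a `mu*` retention rule, then eFAST),
hierarchical Bayesian calibration against blood and urine series with
zero-truncated normal error models, and a synthetic six-volunteer
biomonitoring data generator so every stage is testable without access to
the (non-public) volunteer data.

## Worked example

Simulate a 83 kg subject given a single 0.717 mg/kg oral dose, at the
calibrated (posterior-median) parameter values:

```r
library(dphpk)

raw     <- default_parameters(c(list(BW = 83), as.list(calibrated_medians())))
subject <- build_subject(raw, exposure_scenario(dose = 0.717))
subject
#> PBPK subject parameter set
#>   BW 83.0 kg, dose 0.717 mg/kg (59.5 mg over 0.25 h)
#>   QC 385.0 L/h | CL_H DPHP 14.79, CL_gut DPHP 0.06, CL_H MPHP 22.34 L/h (well-stirred)
#>   lags (h): gut 0.50, lymph 2.00, bile 6.00

sim <- simulate_pbpk(subject)
sim
#> PBPK simulation: 481 time points over 48.0 h
#>   peak blood DPHP 0.2264 mg/L at 7.3 h; peak blood MPHP 0.02851 mg/L at 1.6 h
#>   max |mass balance residual| 1.01e-05 mg

extract_metrics(sim)$urine_maxima$OH
#> [1] 8.6
```

Reading the output: blood MPHP peaks at 1.6 h, well before blood DPHP at
7.3 h — the signature of near-complete hepatic first pass plus
lymph-delivered, protein-bound parent.  The urinary OH-MPHP rate has a
post-peak local maximum at 8.6 h, the enterohepatic harmonic.  The mass
balance residual (mg of DPHP-equivalents across all compartments minus
dose delivered) stays at solver-tolerance level, about 2e-7 of the dose.

Downstream stages follow the same pattern, e.g.:

```r
design <- lhd_maximin(parameter_priors(), 200, seed = 1)  # uncertainty design
batch  <- run_batch(design)                               # 200 monitored runs
mor    <- morris_screen(pbpk_metric_fun(), parameter_priors(), r = 5)
kept   <- retain_parameters(mor, 0.2)                     # mu* retention rule
ds     <- generate_dataset(study_design(), seed = 1)      # synthetic volunteers
post   <- mcmc_calibrate(calibration_spec(
            global = c("K1_MOH", "K1_cx", "FracMetabOH"),
            subject = "FracDOSEHep"), ds,
            scale_moves = list(list(global = "FracMetabOH",
                                    subject = "FracDOSEHep")))
posterior_summaries(post)
```

See the methods vignette (`vignettes/dphp-pbpk-methods.Rmd`) for the model
equations, parameter conventions, prior choices, and known limitations.

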
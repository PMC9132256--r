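# facetCEA

Cost-utility analysis of lumbar facet arthroplasty (the TOPS motion-preserving
device) versus transforaminal lumbar interbody fusion (TLIF) for degenerative
spondylolisthesis with stenosis, built as a tested, reusable decision-modelling
pipeline in R.

Surgeons, payers and health-economics analysts increasingly ask whether a
motion-preserving implant that carries a device upcharge can still be the
economically preferable strategy once downstream utilities, adverse events and
productivity are accounted for. This package answers that question with a
five-state cohort Markov model and the standard machinery of cost-utility
analysis, and ships a synthetic randomized-trial generator so that every stage
runs end to end without access to patient-level trial data.

## The model

Patients occupy one of five mutually exclusive pain/disability states —
Minimal, Moderate, Severe, Crippled, Bedbound — constructed from the visual
analog scale (VAS, 0–10) and the Oswestry Disability Index (ODI, 0–100) via a
regression-anchored composite axis cut at the conventional ODI severity bands
(20/40/60/80). A cohort distribution π is propagated through cycles of
increasing length (two 1.5-month, three 3-month, then 12-month cycles):

    π_k = π_{k-1} P_k

Each cycle accrues discounted QALYs and costs (annual discount rate r = 3%):

    QALY_k = (π_k · u) · Δt_k/12 · (1+r)^(-t_k)
    Cost_k = [ π_k · (c·Δt_k/12 + ae_k) + productivity_k ] · (1+r)^(-t_k)

where `u` are per-state utility weights, `c` per-state annual direct costs,
`ae_k` expected adverse-event costs (per-state, per-arm incidence rescaled to
the cycle length, priced as a supplemental-procedure bundle or a reoperation),
and the productivity term — included only under the societal perspective —
prices time unable to work at the national average wage for the non-retired
half of the cohort. The index surgery enters undiscounted at t = 0; Medicare
and private fees are blended by a configurable payer mix and the arthroplasty
device adds a flat $4 000 upcharge.

Strategies are compared by the incremental cost-effectiveness ratio
ICER = ΔCost/ΔQALY (with dominance labelled rather than reported as a negative
ratio) and net monetary benefit NMB = ΔQALY·λ − ΔCost at willingness-to-pay
thresholds λ ∈ {50 000, 100 000, 150 000} $/QALY. Uncertainty is handled three
ways: a payer-mix × surgical-setting scenario grid, one-way ±20% perturbation
of all 39 inputs (34 costs, 5 utilities) with tornado ordering, and a
5000-iteration probabilistic sensitivity analysis (gamma costs with CV 15.3%,
beta utility decrements) summarised as a cost-effectiveness acceptability
curve.

## Worked example

```r
library(facetCEA)

params <- fixture_model_params()      # packaged calibrated parameter set
cea_table(params, horizons = c(12, 24), perspectives = "health_system")
```

which prints (abridged):

```
    perspective horizon_months cost_tops qaly_tops cost_control qaly_control delta_cost delta_qaly icer_label
1 health_system             12  43359.61 0.7173187     42070.47     0.699399  1289.1432 0.01791965     71 940
2 health_system             24  44803.90 1.4099840     44612.50     1.366056   191.3933 0.04392843      4 357
```

Read: at one year the arthroplasty arm has accrued $1 290 more cost for
0.018 extra QALYs (ICER ≈ $72 000/QALY, under the common $100 000 threshold);
by two years the extra cost has shrunk to ≈ $191 for 0.044 extra QALYs
(ICER ≈ $4 400/QALY, comparable to the most cost-effective elective
procedures). From the societal perspective the device is dominant (cheaper and
more effective) at two years, because faster recovery converts into avoided
productivity loss.

The full analysis is a sequence of numbered drivers:

```sh
Rscript analysis/01_generate_trial.R    # synthetic RCT -> results/synthetic_trial.csv
Rscript analysis/02_estimate_states.R   # partition + transition matrices
Rscript analysis/03_calibrate_model.R   # back-solve the engine fixture (slow)
Rscript analysis/04_base_case.R         # Table of per-arm totals and ICERs
Rscript analysis/05_scenarios.R         # payer-mix x setting grid
Rscript analysis/06_owsa.R              # +/-20% tornado over 39 parameters
Rscript analysis/07_psa.R               # 5000-draw PSA + CEAC
```

Each writes its tables under `results/`. `run_pipeline()` executes the same
stages from one YAML configuration.

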
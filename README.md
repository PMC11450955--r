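# fatomics

Fat-omics feature engineering and survival modeling for epicardial adipose
tissue (EAT) in noncontrast cardiac CT.

EAT — the fat depot enclosed by the pericardial sac, in direct contact with
the myocardium and coronary arteries — is captured by every calcium-score CT
but usually reduced to a single volume or mean attenuation, both of which
are weak predictors of major adverse cardiovascular events (MACE).
`fatomics` computes a comprehensive, fixed 148-entry "fat-omics" descriptor
per study and links it to time-to-event outcomes:

* **Morphology** — EAT and sac volumes (cm³), principal axis lengths
  (4·√λ of the physical-coordinate covariance eigenvalues), aspect ratio.
* **HU distribution** — moments of the EAT attenuation histogram including
  `Negative_skewness` (elevated HU is a fat-inflammation correlate), plus
  8×20-HU and 4×40-HU bins over the fat window [−190, −30] HU, as absolute
  volumes (`vol_50_30`, …) and normalized probabilities (`Pro_50_30`, …).
* **Spatial subregions** — four equally thick axial slabs PQ1 (bottom) to
  PQ4 (top of the heart) and four equidistant radial shells obtained by
  anisotropy-aware physical-distance erosion, with per-subregion volume and
  HU features.
* **3D thickness** — 64,800 ray-cast EAT thickness measurements (1° grid:
  180 polar × 360 azimuth from the sac centroid), summarized by moments and
  four fixed 8-mm bins.

The survival side is the classic screened-penalized pipeline: greedy mRMR
(relevance = univariable Cox |z|, redundancy = mean |correlation|) reduces
148 → 50 features; a Cox proportional-hazards elastic net
(α = 0.8, Breslow ties, 10-fold cross-validated penalty) with an explicit
cap re-tightens the penalty until at most 15 features remain.  The risk
score is the linear predictor Σ βⱼ·xⱼ.  Evaluation covers Harrell's
C-index, IPCW time-dependent AUC, AIC of the unpenalized refit, median-split
Kaplan–Meier stratification with log-rank test and group hazard ratio,
out-of-bag bootstrap validation, and categorical net reclassification
improvement.

Synthetic ground truth is first-class: ellipsoidal CT phantoms with
controllable shell-thickness fields and HU laws, and a Weibull
proportional-hazards cohort simulator with calibrated censoring, so every
stage of the pipeline can be checked against an analytic or generative
oracle.

## Worked example

```r
library(fatomics)

## a synthetic study: lobed 10 mm EAT shell inside an ellipsoidal sac
spec <- phantom_spec(seed = 8,
                     thickness = list(type = "lobed", t0 = 10, a = 4),
                     hu_eat = list(type = "gaussian", mean = -85, sd = 22))
ph <- generate_phantom(spec)
fv <- extract_features(ph$volume, ph$sac)
round(fv[c("EAT_vol", "SAC_vol", "EAT_HUmean", "Negative_skewness",
           "Pro_50_30", "Thickness_Mean", "Thickness_Max", "Vol_PQ4")], 3)
#>           EAT_vol           SAC_vol        EAT_HUmean Negative_skewness
#>           224.188           437.760           -85.539             0.268
#>         Pro_50_30    Thickness_Mean     Thickness_Max           Vol_PQ4
#>             0.003            10.311            15.962            49.688
```

`EAT_vol`/`SAC_vol` are in cm³; the mean EAT attenuation sits at −85.5 HU
with a mildly right-shifted histogram (`Negative_skewness` 0.27) and almost
no mass in the highest-attenuation bin (`Pro_50_30` 0.003, a low-risk
pattern); the ray-cast thickness averages 10.3 mm, peaking at 16 mm where
the lobed field is thickest; `Vol_PQ4` is the EAT volume in the top quartile
slab of the heart.

```r
## a simulated 400-subject, 56%-event cohort with a 15-feature signal
X  <- simulate_cohort_features(400, seed = 1)
sv <- simulate_survival(X, cohort_spec(400, default_signal_beta(),
                                       event_fraction = 0.56, seed = 2))
model <- fatomics_cox(X, sv$time, sv$event, seed = 3)
model
#> Fat-omics Cox elastic-net model
#>   n = 400 subjects, 227 events
#>   mRMR screening: 50 features; active set: 12 (cap 15)
#>   alpha = 0.8, lambda = 0.09502, training C-index = 0.741

scores <- predict(model, X)
km <- km_stratify(scores, sv$time, sv$event)
#> log-rank p = 1.3e-24, high/low HR = 4.00 [3.01, 5.32]
#> C-index = 0.741, AUC(2y) = 0.815
```

Here the median split of the fitted risk score separates the cohort into
groups whose hazards differ fourfold, and the score orders 74% of
comparable subject pairs correctly.

For batch work there is a thin command-line wrapper,
`inst/cli/fatomics.R`, with `phantom`, `extract`, `fit-eval` and
`bootstrap` subcommands over NIfTI/CSV/JSON/YAML files.

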
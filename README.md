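# bcgdyn

Personalized modelling of intravesical BCG (Bacillus Calmette–Guérin)
immunotherapy for non-invasive bladder cancer.

BCG instilled into the bladder triggers an immune cascade that clears
superficial tumors, but response varies widely between patients, and the
clinical data available to calibrate any mechanistic model is sparse: for
most patients only two tumor-burden measurements exist (start and end of
treatment), plus routinely recorded socio-demographics. `bcgdyn` implements
a six-compartment impulsive ODE model of the treatment together with a
fitting procedure built for exactly this kind of data, for modellers and
biostatisticians working on treatment-outcome prediction.

## The model

Six populations interact inside the bladder: intravesical BCG `B`,
effector immune cells `E`, BCG-infected and uninfected cancer cells
`T_i`, `T_u`, and uninfected/infected healthy urothelial cells `H_u`,
`H_i`:

    dB/dt   = Σ_{m=0}^{N-1} b δ(t − mτ) − p1 E B − p2 B T_u − p8 B H_u − μ_B B
    dE/dt   = −μ_E E + α (T_i + H_i) + p4 E B − p5 E T_i − p6 E H_i
    dT_i/dt = p2 B T_u − p3 T_i E
    dT_u/dt = λ T_u − p2 B T_u − p3 T_u E
    dH_u/dt = p7 H_u (1 − (H_u + H_i + T_u + T_i)/H_m) − p8 B H_u
    dH_i/dt = p8 B H_u − p9 E H_i

Weekly instillations enter as a Dirac-like pulse train (`N` doses of `b`
BCG units every `τ` hours; triangular ε-approximation or equivalent state
jumps). Treatment starts from `B = 0, E = e₀, T_u = T₀,
H_u = H_m − T₀`. Patients are partitioned into 72 socio-demographic
groups (6 age bands × 2 genders × smoking × 3 weight classes), each
carrying its own parameter set.

Fitting is a three-step procedure driven only by
`(T(0), T(t_f), socio-demographics)`:

1. per-group gradient descent on the relative mean absolute error
   (RMAE = mean |predicted − observed| / observed), with gradients from
   the five-point finite-difference stencil, in log-parameter space;
2. training-set augmentation with synthetic patients accepted only when
   the mechanistic model predicts their outcome better than an optimised
   k-nearest-neighbour regressor, kept only if a paired one-sided t-test
   on held-out errors confirms an improvement;
3. selection among candidate regression pipelines mapping
   socio-demographics to model parameters, scored on a validation split,
   with predictions averaged over cross-validation folds.

The package also provides equilibrium/stability analysis (the
treatment-free system has exactly two equilibria, both non-hyperbolic and
unstable under tumor growth), a virtual-cohort generator with hidden
ground truth, and a three-way evaluation against a pooled
(non-personalized) variant and the legacy continuous-instillation
four-compartment model.

## Worked example

```r
library(bcgdyn)

# simulate the standard induction course for one patient
pars  <- model_params(T0 = 1e6)        # 1e6 tumor cells at presentation
sched <- dose_schedule()               # 6 x 2.8e6 BCG units, weekly
traj  <- simulate_treatment(pars, sched)
traj
#> BCG treatment trajectory: 1009 time points over [0, 1008] h
#>   final tumor burden: 1.894e+05 cells

tumor_burden(traj, 1008) / 1e6         # ~81% tumor reduction
#> [1] 0.1894077

# stability of the treatment-free equilibria
eqs <- find_equilibria(pars)
classify_stability(pars, eqs[[2]])
#> Equilibrium (healthy): unstable
#>   eigenvalues (Re): 0.002, 0, 0, -0.001, -0.005, -0.006

# generate a virtual cohort and fit the personalized model
syn <- generate_cohort(ground_truth(), n = 150, seed = 11)
cfg <- fit_config(k = 2, free = c("lambda", "mu_E", "alpha"),
                  n_restarts = 1, gd_max_iter = 25, n_augment = 10,
                  max_aug_rounds = 2, seed = 9)
fit <- fit_bcg(syn$records, cfg)
cmp <- compare_models(
  list(personalized = fit,
       no_socio = fit_no_socio(syn$records, cfg),
       legacy = fit_legacy(syn$records, cfg)),
  syn$records, n_samples = 50, seed = 4)
cmp
#> Model comparison on 31 unique-profile samples:
#>   personalized   RMAE 0.109 +/- 0.075
#>   no_socio       RMAE 0.234 +/- 0.193
#>   legacy         RMAE 0.867 +/- 0.496
#>   ANOVA F = 53.24, p = 5.51e-16; winner: personalized
```

The RMAE lines read as mean relative prediction error of the final tumor
burden over the evaluation samples (0.109 ≈ 10.9%): the socio-demographic
personalization roughly halves the error of the pooled model, and both
six-compartment variants clearly beat the legacy continuous-instillation
model on cohorts whose heterogeneity follows the shipped "strong"
scenario.

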
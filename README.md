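# adhertraj

Longitudinal adherence-pattern analysis for adjuvant endocrine therapy
(AET) in registry settings where medication is handed out at semi-annual
clinic visits rather than dispensed at pharmacies. The package takes
visit-level treatment registrations, builds per-patient **supply diaries**
and interval-wise **proportion-of-days-covered (PDC)** series, identifies
latent adherence-behaviour groups with a **censored-normal group-based
trajectory model**, and relates baseline clinical characteristics to group
membership with **multinomial logistic regression**. A synthetic
registry-cohort generator with known ground truth makes every stage
testable without access to protected health data.

It is aimed at pharmacoepidemiologists analysing clinical-database cohorts
(breast cancer follow-up programmes and similar) and at methodologists who
want a transparent, fully scriptable alternative to SAS `PROC TRAJ` for
censored-normal trajectory mixtures.

## The model

For patient *i* in latent group *j*, the adherence propensity at six-month
interval *t* is

y\*ᵢₜ = xₜ′βⱼ + εᵢₜ,  εᵢₜ ~ N(0, σ²),

with xₜ a polynomial basis (degree 0–2) on interval time scaled to [0, 1].
The observed PDC is yᵢₜ = min(1, max(0, y\*ᵢₜ)), so the likelihood uses the
Gaussian density for interior values and normal tail probabilities at the
bounds. Groups mix with proportions πⱼ; the observed-data log-likelihood

ℓ = Σᵢ log Σⱼ πⱼ exp( Σₜ log f(yᵢₜ | xₜ′βⱼ, σ) )

is maximised by EM over the latent group indicator with multi-start
initialisation. Model selection follows a three-step protocol: (1) choose
the number of groups J ∈ {2,…,7} by BIC (Nagin convention
ℓ − (k/2)·ln n, larger is better) among all-quadratic candidates; (2) prune
each group's polynomial order by Wald tests on the highest-order
coefficient; (3) assess the result with average posterior probability of
assignment (APPA), odds of correct classification (OCC) and spaghetti
plots.

Supply diaries follow the semi-annual dispensing rule: each visit at which
AET use is reported adds a 182-day supply to a running balance consumed one
day per calendar day, and at each 182-day interval boundary at most 182
days of supply carry forward. Aromatase-inhibitor registrations after
tamoxifen initiation still count as adherence. PDC denominators shorten at
censoring (recurrence, death, second primary, emigration, or five years
after diagnosis).

## Worked example

Simulate PDC panels from a known three-group model (57/36/7 percent
mixing; one constant and two declining trajectories; σ = 0.15) and run the
three-step selection:

```r
library(adhertraj)

sim <- simulate_pdc_panels(
  n = 1000, mixing = c(0.57, 0.36, 0.07),
  polynomials = list(high  = c(0.97, 0, 0),
                     slow  = c(0.98, -0.20, -0.35),
                     rapid = c(0.95, -2.40, 1.20)),
  sigma = 0.15, n_intervals = 9, seed = 42)

sel <- select_model(sim$panel, j_range = 2:4, seed = 1, n_restarts = 2)
sel$model
#> Censored-normal trajectory model: 3 groups, n = 1000, T = 9
#>   loglik = -339.381   BIC = -373.920   sigma = 0.1519   converged
#>   group 1: pi = 0.070, order 2, beta = (0.936, -2.380, 1.200)
#>   group 2: pi = 0.335, order 2, beta = (0.978, -0.206, -0.338)
#>   group 3: pi = 0.595, order 0, beta = (0.970)
```

Step 1 picks three groups by BIC; step 2 prunes the high-adherence group
to a constant (order 0) while the two declining groups keep second-order
polynomials; the recovered mixing proportions (0.070 / 0.335 / 0.595) and
coefficients sit close to the generating values. Classification is sharp:

```r
sel$diagnostics$table
#>   group   n share      appa      occ flagged
#> 1     1  70 0.070 1.0000000      Inf   FALSE
#> 2     2 334 0.334 0.9945116 360.0270   FALSE
#> 3     3 596 0.596 0.9955890 153.5013   FALSE
```

APPA is the mean posterior membership probability among patients assigned
to a group (1.0 = perfect separation; values below 0.70 are flagged).

The same machinery runs end to end from registry-style tables:

```r
cfg <- list(sim = sim_config(n_patients = 2000), seed = 1,
            out_dir = "run1")
report <- run_pipeline(cfg)   # simulate -> eligibility -> PDC -> GBTM -> ORs
render_report(report)         # trajectory/spaghetti/forest plots + report.md
```

External data are supplied as `patients.csv`, `visits.csv` and
`censoring.csv` via `config$input_dir`; a thin command-line wrapper lives
at `inst/cli/adhertraj.R`.

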
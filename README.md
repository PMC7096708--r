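# chitkin

Progress-curve enzyme kinetics for chitinase activity assays.

Chitinases degrade chitin, the insoluble β-1,4-linked N-acetylglucosamine
polymer of fungal walls and arthropod cuticle; in mammalian airways the
secreted enzymes AMCase and chitotriosidase clear inhaled chitin, and
their activity differences matter for asthma and lung fibrosis biology.
Measuring that activity honestly is awkward: convenient fluorogenic
oligomers (4MU-chitobioside) report only the chemistry of the catalytic
cleft, while the physiological substrate — crystalline bulk chitin — must
be assayed as an insoluble suspension through scattering, endpoint
reducing-sugar chemistry, or an enzyme-coupled fluorescence readout.
Engineering campaigns screened only on oligomers can optimize fluorophore
binding instead of chitin turnover.

chitkin is a toolkit for analysts running these assays. It implements one
statistical pipeline behind four assay chemistries, plus the simulator
needed to validate every stage by parameter recovery:

* **Progress-curve fitting** — nonlinear least squares of the relaxation
  model `signal(t) = Σ Aᵢ(1 − exp(−k₁ᵢ t)) + m·t + B`, with a
  runs-test diagnostic for residual structure and automatic model
  extension (`fit_relaxation()`, `assess_residual_structure()`,
  `auto_fit()`). The initial rate is the model derivative at t = 0:
  `v₀ = Σ Aᵢk₁ᵢ + m`.
* **Calibration** — OLS standard curves restricted to each assay's linear
  range; rates convert through the slope alone (`fit_standard_curve()`).
* **Michaelis–Menten estimation** — `v = Vmax·S/(Km + S)` on pooled
  per-well rates, kcat = Vmax/[E], and kcat/Km with a delta-method SD
  that keeps the (Vmax, Km) covariance
  (`fit_michaelis_menten()`, `efficiency_with_sd()`):
  `Var(r)/r² = Var(Vmax)/Vmax² + Var(Km)/Km² − 2·Cov(Vmax,Km)/(Vmax·Km)`.
* **Assay pipelines** — `run_assay()` orchestrates standards → curves →
  rates → MM per assay: continuous 4MU fluorescence; OD680 clearance
  (initial-state subtraction, negative amplitudes); ferricyanide endpoint
  (`(max − min)/incubation`); one-pot chitO coupled assay (matched
  chitinase-free control subtraction).
* **Screen normalization** — per-plate rescaling against on-plate dead
  and wild-type controls (`normalize_screen()`).
* **Simulation** — `simulate_assay_plate()` builds whole synthetic plates
  from known kcat/Km via the integrated Michaelis–Menten equation
  `Km·ln(S0/S) + (S0 − S) = Vmax·t`, solved in closed form with a
  log-scale Lambert-W evaluation.

Units are first-class: oligomer Km in µM, bulk-chitin Km in % w/v, with
`percent_wv_to_monomer_mM()` bridging the two through the 203.21 g/mol
monomer mass (0.03 % w/v ≈ 1.5 mM binding sites — about 50× the
oligomeric Km, which is the crystallinity story in one number).

## Worked example

Simulate a wild-type chitO plate (2 nM enzyme, colloidal chitin halving
series 2 → 0.0156 % w/v, 1-min reads for 16 h, 5% noise, matched
chitinase-free controls) and run the full pipeline:

```r
library(chitkin)
plate <- simulate_assay_plate("chito", seed = 1)   # truth: kcat 1.0/s, Km 0.032 % w/v
res   <- run_assay(plate, plate$config)
res$table
#> # A tibble: 1 × 9
#>   construct assay  kcat kcat_sd     Km    Km_sd efficiency efficiency_sd n_rates
#>   <chr>     <chr> <dbl>   <dbl>  <dbl>    <dbl>      <dbl>         <dbl>   <int>
#> 1 WT        chito  1.01 0.00546 0.0317 0.000929       31.8         0.830      14
```

The pipeline calibrated the coupled-fluorescence signal
(`res$standard_curve`: slope 29997 signal per % w/v, R² = 1.0000),
subtracted each well's drifting enzyme-free control, fit relaxation
models, and recovered kcat = 1.01 ± 0.005 /s and Km = 0.0317 ± 0.0009
% w/v against the simulated truth of 1.0 /s and 0.032 % w/v; 14 of 24
wells passed the flag filters (low-substrate wells whose initial rate is
indistinguishable from zero are excluded rather than guessed). The
efficiency 31.8 ± 0.8 (% w/v)⁻¹s⁻¹ carries the covariance-aware SD.

Construct comparison, e.g. a mutant's kcat 4.5 ± 1.2 vs wild type
1.5 ± 0.3:

```r
fold_change(4.5, 1.2, 1.5, 0.3)
#> $ratio      3
#> $ratio_raw  3
#> $p_value    0.0153
```

A thin CLI wraps the same functions (`inst/cli/chitkin`):
`simulate`, `fit-standards`, `fit-curves`, `assay`, `screen`, `compare`.

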
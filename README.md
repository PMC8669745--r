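# soilenzkin

Depth-resolved kinetics and temperature sensitivity of soil extracellular
enzymes, as a tested, reusable pipeline.

Soil exoenzymes — here β-glucosidase (BG, carbon acquisition), leucine
aminopeptidase (LAP, nitrogen) and acid phosphatase (AP, phosphorus) —
catalyse the rate-limiting depolymerisation steps of soil organic matter
turnover. Their kinetic traits (maximal velocity V<sub>max</sub>,
Michaelis constant K<sub>m</sub>, catalytic efficiency CE =
V<sub>max</sub>/K<sub>m</sub>) and thermal traits (Q<sub>10</sub>,
Arrhenius activation energy E<sub>a</sub>, and the Macromolecular Rate
Theory parameters ΔC<sub>p</sub><sup>‡</sup>, T<sub>opt</sub>,
TS<sub>max</sub>) vary down the soil profile and determine how deep-soil
carbon responds to warming. This package implements the full analysis
chain for fluorometric microplate assays of such enzymes across a
depth × temperature factorial design, for soil ecologists who want the
entire path from raw plate fluorescence to trait statistics to be
scripted, seeded, and testable:

1. **Reduction** — quench-corrected net fluorescence,
   `net = (raw − blank_hom)/q − blank_sub`, converted to rates in
   nmol g⁻¹ (dry soil) h⁻¹ using per-batch standard curves;
2. **QC** — negative readings removed; at most one of four analytical
   replicates removed by Tukey-fence IQR filtering; every exclusion
   ledgered;
3. **Michaelis–Menten fitting** — v = V<sub>max</sub>S/(K<sub>m</sub>+S)
   by transform-both-sides Box–Cox least squares with the exponent λ
   chosen by profile likelihood (heteroscedastic analytical variance),
   significance gating of both parameters, optional removal of one
   consistently misfitting substrate concentration, and selection of the
   minimum sufficient incubation time per temperature batch;
4. **Traits** — V<sub>max/ds</sub>, V<sub>max/MBC</sub> (per microbial
   biomass C from chloroform fumigation–extraction), CE<sub>ds</sub>,
   CE<sub>MBC</sub>;
5. **Thermal models** — Q<sub>10</sub> = e<sup>10·slope</sup> from
   ln(parameter) vs °C; E<sub>a</sub> = −slope·R from ln(V<sub>max</sub>)
   vs 1/T; MMRT fits of ln V<sub>max</sub> with T₀ = 315 K giving
   ΔC<sub>p</sub><sup>‡</sup>, T<sub>opt</sub> (closed form) and
   TS<sub>max</sub> (rate-curve inflection, bisection), compared to
   Arrhenius by AIC/AICc/BIC;
6. **Statistics** — two-way and blocked ANOVA, Tukey HSD with compact
   letter displays, assumption diagnostics, percent-decline summaries and
   between-enzyme trait ratios.

A synthetic campaign generator simulates every well of the factorial
design (3 enzymes × 6 depths × 6 temperatures × 8 concentrations × 4
replicates × 3 cores × 3 timepoints) from a seeded ground-truth profile,
so the whole pipeline runs and is validated without any field data.

## Worked example

```r
library(soilenzkin)

## Michaelis-Menten fit with Box-Cox on one assay unit
set.seed(101)
conc <- rep(sek_substrates$BG, 4)                  # 8 concentrations x 4 replicates
rate <- 120 * conc / (90 + conc) * rlnorm(32, -0.005, 0.1)
fit <- fit_mm(conc, rate)
print(fit)
#> MM fit: Vmax = 119.6 (se 3.57, p 2.56e-25), Km = 91.19 (se 5.1, p 1.5e-17)
#>   lambda = -0.02, n = 32, converged = TRUE

## Q10 from exact Arrhenius kinetics with Ea = 31.5 kJ/mol
tc <- c(4, 10, 16, 25, 35)
vmax_T <- exp(-31500 / (8.314 * (tc + 273.15)))
q <- q10_fit(tc, vmax_T)
cat(sprintf("Q10 over 4-35 C: %.2f\n", q$q10))
#> Q10 over 4-35 C: 1.56

## MMRT thermal traits of a noiseless curve
m <- mmrt_fit(sek_temperatures,
              mmrt_lnrate(sek_temperatures + 273.15, 15400, 20, -790))
print(m)
#> MMRT fit: dCp = -790.0 J/mol/K, dH = 15400 J/mol, Topt = 338.05 K,
#>   TSmax = 303.37 K, valid = TRUE
```

The fitted V<sub>max</sub> and K<sub>m</sub> recover the generating values
(120, 90) within their standard errors; λ ≈ 0 says the profile likelihood
chose an approximately logarithmic variance-stabilising transform, as
expected for proportional noise. The Q<sub>10</sub> of 1.56 is the
log-linear summary of an activation energy of 31.5 kJ/mol over the 4–35 °C
field range. The MMRT fit returns its generating parameters exactly (the
model is linear in ΔH<sup>‡</sup>, ΔS<sup>‡</sup>, ΔC<sub>p</sub><sup>‡</sup>
after moving the k<sub>B</sub>T/h pre-factor to the response side), with
the temperature optimum at 338.05 K (65 °C) and the point of maximum
temperature sensitivity at 303.4 K (30 °C), below it.

## The analysis workflow

`analysis/` holds the numbered drivers of the full campaign study; each is
a thin script over package functions and writes its tables under
`results/` (large well-level intermediates go to `scratch/`):

```sh
Rscript analysis/01_simulate.R      # factorial campaign from seeded truth
Rscript analysis/02_reduce_qc.R     # fluorescence -> rates, exclusion ledger
Rscript analysis/03_fit_kinetics.R  # MM fits, incubation choice, traits
Rscript analysis/04_thermal.R       # Q10 / Arrhenius / MMRT + AICc
Rscript analysis/05_stats.R         # ANOVA, Tukey letters, declines, ratios
```

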
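---
title: "Depth-resolved soil exoenzyme kinetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved soil exoenzyme kinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement and its reduction

Soil extracellular hydrolases are assayed fluorometrically: a soil
homogenate (1 g fresh soil in 100 mL acetate buffer) is combined with a
fluorogenic substrate (MUF-linked for beta-glucosidase, BG, and acid
phosphatase, AP; AMC-linked for leucine aminopeptidase, LAP) in microplate
wells (200 uL homogenate + 50 uL substrate), and the fluorescence released
by enzymatic cleavage is read after a nominal incubation. Because soil
particles absorb and scatter light, raw fluorescence must be corrected by
controls incubated with every temperature batch:

* an unquenched standard dilution series gives the *emission coefficient*
  (fluorescence units per nmol fluorophore in the well);
* the same series spiked into soil homogenate gives the *quench
  coefficient* as the ratio of quenched to unquenched standard-curve
  slopes, estimated per depth within each batch since organic-rich surface
  homogenates quench more strongly;
* homogenate-only and substrate-only blanks capture background.

The reduction is

$$\mathrm{net} = \frac{\mathrm{raw} - \mathrm{blank_{hom}}}{q} -
  \mathrm{blank_{sub}}, \qquad
  v = \frac{\mathrm{net}/c_{\mathrm{emis}}}
            {m_{\mathrm{dry}}\, t},$$

with $m_\mathrm{dry}$ the dry soil mass dispensed into the well. The assay
uses fresh soil, so rates per gram *dry* soil require the gravimetric
dry-matter fraction; it is a mandatory column of the soil context table
and the conversion is exercised by round-trip tests. Only standard-curve
slopes enter the coefficients: intercepts are retained for diagnostics but
baselines are already captured by the blanks. Fluorescence units are
arbitrary but must be consistent within a batch; no cross-batch gain
normalisation is attempted.

# Quality control

Two well-level rules are applied within each replicate cell
(enzyme x depth x core x temperature x substrate x timepoint), in order:

1. strictly negative rates (analytical error) are removed; zeros are kept;
2. values outside the Tukey fences $[Q_1 - 1.5\,\mathrm{IQR},\;
   Q_3 + 1.5\,\mathrm{IQR}]$ are flagged and **at most one** replicate --
   the flagged value farthest from the cell median -- is removed.

Quartiles use linear interpolation between order statistics (R's default
type 7); the fence multiplier and quartile convention are pinned because
the exclusion outcome depends on them. When two values exceed the fences,
the cap forces a tie-break: farthest from the median, then larger absolute
value, then first index. Filtering operates on reduced rates; because the
reduction is affine with positive slope in raw fluorescence, filtering
before or after conversion is equivalent. Every removal is logged to an
exclusion ledger (reason, count, fraction), and ledger conservation
(rows in = rows out + rows excluded) is asserted per stage.

# Michaelis-Menten fitting with a transform-both-sides Box-Cox

Per enzyme x depth x core x temperature x timepoint unit, all analytical
replicates of the eight-concentration series are fit to
$\mu(S) = V_\max S / (K_m + S)$. Analytical variance grows with the mean,
so both sides are passed through a shared Box-Cox transform
$y^{(\lambda)} = (y^\lambda - 1)/\lambda$ ($\log y$ at $\lambda = 0$) and
$(V_\max, K_m)$ minimise
$\sum_i \bigl(v_i^{(\lambda)} - \mu(S_i)^{(\lambda)}\bigr)^2$. The
exponent is chosen by profile maximum likelihood,
$\ell(\lambda) = -\tfrac n2 \log(\mathrm{RSS}_\lambda/n) +
(\lambda - 1)\sum_i \log v_i$, over a grid ($-2$ to $2$, step $0.1$,
refined once at a fifth of the step). Starting values are data-driven
($V_{\max,0}$ the largest per-concentration mean; $K_{m,0}$ the
concentration nearest half of it), with two scaled fallback starts on
non-convergence. Standard errors are asymptotic, from the Jacobian of the
transformed-scale model at the optimum, and p-values are two-sided t with
$n - 2$ df on the original parameter scale -- the gate (both parameters
significant at $p \le 0.05$) therefore acts on original-scale estimates,
one of the conventions left open by the analysis this emulates. The
Box-Cox transform requires a positive response: QC removes negatives, and
any residual non-positive rate is excluded from the fit cell.

A single substrate concentration may be dropped when all of its analytical
replicates misfit with the same residual sign (substrate inhibition at the
top of a series, or a preparation error) *and* the refit improves a
Gaussian information criterion by more than 2 units; both fits are scored
on the retained points so they see the same data. At most one
concentration is ever dropped.

Fluorescence is read after nominal incubations of 1, 4 and 24 h. For each
temperature batch the pipeline keeps the *minimum* incubation whose median
fitted $V_\max$ across units is within 5% (configurable) of the batch
maximum: short incubations under-read slow cold reactions, while warm
reactions saturate and lose fluorophore at long incubations.

Traits follow from the gated fits: $V_{\max/ds}$ (per g dry soil),
$V_{\max/MBC} = V_{\max/ds}/\mathrm{MBC}$,
$CE_{ds} = V_{\max/ds}/K_m$, $CE_{MBC} = V_{\max/MBC}/K_m$. Microbial
biomass C is the chloroform-fumigation extraction difference
$C_\mathrm{fum} - C_\mathrm{nonfum}$ with no $k_{EC}$ efficiency
correction. The turnover number $k_{cat}$ is deliberately not computed:
enzyme concentrations in soil are unknown, so it cannot be inferred from
these assays.

# Temperature sensitivity

**Q10** is obtained from an OLS regression of $\ln(\text{parameter})$ on
temperature in degrees Celsius, $Q_{10} = e^{10\,\mathrm{slope}}$,
computed over the realistic field range (4-35 C, five temperatures) and
the full assay range (4-50 C, six). **Arrhenius** activation energy comes
from $\ln V_\max$ against $1/T$ in kelvin, $E_a = -\mathrm{slope} \times
R$; it is reported in kJ/mol (the slope-times-R product is dimensionally
J/mol). Fits are per core, then averaged, matching mean +- se reporting
across replicate cores.

**MMRT** models the unimodal rate-temperature curve through the activation
heat-capacity change:

$$\ln k(T) = \ln\frac{k_B T}{h}
  - \frac{\Delta H^\ddagger + \Delta C_p^\ddagger (T - T_0)}{R T}
  + \frac{\Delta S^\ddagger + \Delta C_p^\ddagger \ln(T/T_0)}{R},$$

with $T_0 = 315$ K. Moving the $\ln(k_B T/h)$ pre-factor to the left-hand
side makes the model *exactly linear* in $(\Delta H^\ddagger,
\Delta S^\ddagger, \Delta C_p^\ddagger)$, so the least-squares problem is
solved in closed form by OLS -- the same objective a nonlinear optimiser
would minimise, but with a global optimum and no convergence failures;
this is why no multistart machinery is needed. $\Delta S^\ddagger$ absorbs
the arbitrary units of $V_\max$ and is not interpreted in absolute terms.

The temperature optimum has the closed form
$T_{opt} = (\Delta C_p^\ddagger T_0 - \Delta H^\ddagger) /
(\Delta C_p^\ddagger + R)$, requiring $\Delta C_p^\ddagger < -R$ for a
finite maximum; note $\partial T_{opt}/\partial \Delta H^\ddagger =
-1/(\Delta C_p^\ddagger + R) > 0$ in that regime. The point of maximum
temperature sensitivity $TS_{max}$ is defined on the *rate* curve $k(T)$
(not $\ln k$): the maximum of $dk/dT$, i.e. the root of $g^2 + g'$ with
$g = d\ln k/dT$, which has no closed form and is located by bisection to
0.01 K below $T_{opt}$. Fits whose $T_{opt}$ or $TS_{max}$ falls outside
0-200 C do not conform to MMRT's predicted unimodal behaviour and are
flagged invalid; downstream thermal tables contain only valid fits and
the exclusions are ledgered.

Arrhenius and MMRT are compared on the same $\ln V_\max$ response with
Gaussian criteria computed from the RSS with additive constants dropped:
$\mathrm{AIC} = n\log(\mathrm{RSS}/n) + 2k$, $\mathrm{AICc} =
\mathrm{AIC} + 2k(k+1)/(n-k-1)$, $\mathrm{BIC} = n\log(\mathrm{RSS}/n) +
k\log n$, where $k$ counts mean-model parameters plus the residual
variance (Arrhenius 3, MMRT 4). With $n = 6$ temperatures the MMRT AICc
denominator is 1 -- legal but flagged, and a reason AICc heavily penalises
the extra parameter at this sample size. Relative likelihoods are
$e^{-\Delta\mathrm{AICc}/2}$ against the best model.

# Factorial statistics

Per-enzyme two-way fixed-effects ANOVA (depth x temperature) uses type-I
sequential sums of squares; the study design is balanced (exclusions are
rare), and unbalanced inputs fall back to sequential SS with the order
documented. A blocked variant treats temperature as a block (entered
first) and tests depth against the post-block residual, reducing to
one-way ANOVA with a single block. Responses may be ln-transformed;
assumption diagnostics (median-centred Levene via `car`, Shapiro-Wilk,
residual skewness via `e1071`) are advisory -- the pipeline proceeds and
logs.

Tukey HSD adjusted pairwise p-values come from `stats::TukeyHSD`; compact
letter displays are produced by an insert-and-absorb algorithm over the
p-matrix with groups pre-sorted by descending mean, so the letter
assignment is deterministic and two levels share a letter exactly when
their adjusted p exceeds alpha. A brute-force validity checker backs this
in the tests.

Percent decline of a trait down the profile is computed per temperature as
$100 \times (\max(\text{upper}) - \min(\text{lower})) /
\max(\text{upper})$ on depth means, then averaged (mean +- se) across
temperatures; spurious cells can be excluded by an explicit
`exclude_cells` table rather than hard-coded rules. Between-enzyme trait
ratios (BG:LAP, BG:AP, LAP:AP) are element-wise at common coordinates.

# The synthetic campaign

The generator exists so that every stage is testable against known truth
without field data. Its defaults *are* the study conditions: 3 enzymes x 6
depth intervals (0-10 through 80-90 cm) x 6 temperatures (4-50 C) x 8
enzyme-specific substrate concentrations x 4 analytical replicates x 3
cores x 3 nominal timepoints -- 324 kinetic fit units per timepoint, each
with 32 wells.

Truth profiles: $V_\max$ decays exponentially with depth midpoint with
e-folding scale 22.6 cm (a ~96-97% decline from the surface to the 80-90
cm interval, the magnitude class reported for these soils); $K_m$ decays
to ~15% of its surface value by ~30 cm and then plateaus; surface
magnitudes follow the field ordering AP > BG > LAP for $V_\max$ and
LAP > AP > BG for $K_m$. Each enzyme carries an MMRT temperature response
with $\Delta C_p^\ddagger = -0.79$ kJ/mol/K (BG, AP) or $-1.32$ (LAP) and
$\Delta H^\ddagger$ set for $T_{opt} \approx 338$ K, normalised to unity
at the 25 C reference so the depth profile carries the magnitude.
Microbial biomass C decays steepest over the upper 30 cm; quench
coefficients run from 0.6 at the surface (organic-rich) to 0.9 at depth;
dry-matter fraction increases with depth.

Wells receive multiplicative lognormal noise (CV 10%, mean one), which
both motivates and justifies the Box-Cox machinery; negative readings are
injected at 0.8% (a value replaced below the homogenate blank) and
single-replicate outliers at 3%, as independent Bernoulli processes.
Standards are simulated at a quarter of the well CV, reflecting the
cleaner matrix. Incubation realism: cold assays build signal sub-linearly
early (0.7/0.9/1.0 of the true rate at 1/4/24 h) while warm assays
saturate after 4 h (the 24 h reading recovers only 4/24 of the rate), so
the incubation-time selector has genuine work and picks long incubations
for cold batches and short ones for warm batches. Campaign generation is
fully deterministic given a seed, byte-identical across runs.

What the generator does **not** emulate: spatial autocorrelation between
cores, seasonal temperature dynamics, substrate sorption or diffusion
limitation, pipetting gradients across a plate, and drift of plate-reader
gain between batches. Passing end-to-end tests therefore demonstrates
correctness of the estimation chain under a realistic noise model, not
robustness to every field artefact.

One consequence of faithful batch-wise correction is worth noting: quench
coefficients are estimated per depth x temperature batch, so their
estimation error is shared by all cores in that batch. On a full
campaign this induces a real (if tiny) depth x temperature variance
component, which an interaction F-test against the very small
core-to-core residual can detect even though its effect size is
negligible (interaction SS on the order of 0.05% of the depth SS).
Calibration of the interaction test is therefore checked on trait tables
generated additively, where the ~alpha rejection rate is recovered, while
campaign-level checks bound the interaction's share of variance.

# Problem sizes and numerical choices

The packaged checks run a full campaign once (31,104 sample wells, 972
unit-level fits), 200-draw recovery studies for the Michaelis-Menten
(CV 10%) and MMRT ($\sigma_{\ln} = 0.1$) fitters, and a 100,000-draw
property sweep of the replicate filter; these sizes give stable Monte
Carlo estimates of the recovery medians while keeping a test run to a few
minutes. Tolerances asserted in tests derive from the oracle used (grid
resolution for the profile-likelihood oracle, 0.01 K for bisection,
printed precision for desk-checked constants), never from observed
failures. Degenerate inputs are handled explicitly: constant responses
report p = 1 in ANOVA; zero-RSS comparisons are skipped in the
concentration-drop rule; `dCp >= -R` yields an infinite optimum and an
invalid MMRT classification.

# Known limitations

* The significance gate uses original-scale asymptotic standard errors;
  profile-likelihood intervals would be more accurate near parameter
  bounds.
* AICc with six temperatures and four parameters is at the edge of its
  validity (denominator 1); the comparison is reported, not relied upon.
* The blocked ANOVA tests depth against the post-block residual; variance
  components are not estimated (no mixed models by design).
* Rates below the substrate series' coverage of $K_m$ (deep, cold cells)
  carry wide $K_m$ uncertainty; the gate removes the worst cases, which
  slightly prunes the deepest cells.
* $CE_{MBC}$ depth patterns depend on the relative decay scales of
  $V_\max$, $K_m$ and MBC in the truth profile; the defaults reproduce
  the headline $V_{\max/ds}$ decline class, not every derived contrast.
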
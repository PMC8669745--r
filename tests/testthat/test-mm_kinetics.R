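test_that("noiseless Michaelis-Menten data is recovered to machine precision", {
  d <- mm_exact(vmax = 100, km = 50)
  f <- fit_mm(d$conc, d$rate)
  expect_equal(f$vmax, 100, tolerance = 1e-6)
  expect_equal(f$km, 50, tolerance = 1e-6)
  expect_true(f$converged)
  expect_error(fit_mm(rep(c(10, 30, 60), 4), rep(1, 12)),
               "insufficient design")
})

test_that("lambda = 1 reproduces plain nonlinear least squares", {
  set.seed(7)
  d <- mm_exact(vmax = 100, km = 50)
  v <- d$rate + rnorm(length(d$rate), 0, 2)   # homoscedastic
  f <- fit_mm(d$conc, v, lambda = 1)
  cc <- d$conc
  ref <- nls(v ~ vmax * cc / (km + cc), start = list(vmax = 90, km = 60))
  expect_equal(f$vmax, unname(coef(ref)["vmax"]), tolerance = 1e-4)
  expect_equal(f$km, unname(coef(ref)["km"]), tolerance = 1e-4)
  # same standard errors as the linearised nls asymptotics
  expect_equal(f$se_vmax, summary(ref)$coefficients["vmax", 2],
               tolerance = 1e-3)
})

test_that("profile fit matches a brute-force grid-search oracle", {
  set.seed(23)
  conc <- rep(sek_substrates$BG, 4)
  mu <- 80 * conc / (120 + conc)
  v <- mu * ln_noise(length(mu), 0.10)       # sd proportional to mean
  f <- fit_mm(conc, v)
  oracle <- mm_profile_grid_oracle(
    conc, v,
    vmax_grid = seq(0.85, 1.15, by = 0.005) * f$vmax,
    km_grid = seq(0.7, 1.3, by = 0.01) * f$km,
    lambda_grid = seq(-1, 1, by = 0.1))
  # the oracle explores a grid around (but independent of) the fitted
  # optimum; the profile objective must not be beaten by more than its
  # own resolution, and parameters agree within grid resolution
  expect_lt(abs(oracle$ll - f$loglik) / abs(f$loglik), 0.01)
  expect_lt(abs(oracle$vmax - f$vmax) / f$vmax, 0.01)
  expect_lt(abs(oracle$km - f$km) / f$km, 0.02)
  # and both recover the generating truth reasonably
  expect_lt(abs(f$vmax - 80) / 80, 0.15)
  expect_lt(abs(f$km - 120) / 120, 0.3)
})

test_that("rate scaling is equivariant: Vmax scales, Km invariant", {
  set.seed(31)
  conc <- rep(sek_substrates$AP, 4)
  v <- 60 * conc / (150 + conc) * ln_noise(length(conc), 0.08)
  f1 <- fit_mm(conc, v)
  f3 <- fit_mm(conc, 3 * v)
  expect_equal(f3$vmax / f1$vmax, 3, tolerance = 0.02)
  expect_equal(f3$km, f1$km, tolerance = 0.05 * f1$km)
})

test_that("a consistently misfitting concentration is dropped, one at most", {
  d <- mm_exact(vmax = 100, km = 50)
  f <- fit_mm(d$conc, d$rate)
  nod <- drop_bad_concentration(d$conc, d$rate, f)
  expect_true(is.na(nod$fit$dropped_concentration))

  # top concentration suppressed 40% in all four replicates (inhibition)
  set.seed(17)
  v <- d$rate * ln_noise(length(d$rate), 0.03)
  top <- d$conc == 800
  v[top] <- v[top] * 0.6
  f2 <- fit_mm(d$conc, v)
  dd <- drop_bad_concentration(d$conc, v, f2)
  expect_equal(dd$fit$dropped_concentration, 800)
  expect_lt(abs(dd$fit$vmax - 100) / 100, 0.1)

  # a single aberrant replicate does not qualify
  v3 <- d$rate * ln_noise(length(d$rate), 0.03)
  v3[which(top)[1]] <- v3[which(top)[1]] * 0.5
  f3 <- fit_mm(d$conc, v3)
  d3 <- drop_bad_concentration(d$conc, v3, f3)
  expect_true(is.na(d3$fit$dropped_concentration))
})

test_that("incubation time selection takes the minimum sufficient period", {
  mk <- function(v) data.frame(temperature_C = 25, timepoint_h = c(1, 4, 24),
                               vmax = v)
  expect_equal(select_incubation_time(mk(c(10, 10, 10)))$timepoint_h, 1)
  expect_equal(select_incubation_time(mk(c(4, 10, 9.5)),
                                      tolerance = 0.10)$timepoint_h, 4)
  expect_equal(select_incubation_time(mk(c(4, 7, 10)))$timepoint_h, 24)
  # a timepoint whose fits all failed is ineligible
  expect_equal(select_incubation_time(mk(c(NA, 9, 10)),
                                      tolerance = 0.15)$timepoint_h, 4)
})

test_that("fumigation-extraction MBC is the uncorrected difference", {
  expect_equal(mbc_from_fumigation(120, 120), 0)
  expect_equal(mbc_from_fumigation(300, 120), 180)
  expect_warning(mbc_from_fumigation(100, 120), "negative")
})

test_that("kinetic traits obey their defining identities", {
  tr <- derive_traits(100, 50, 200)
  expect_equal(tr$ce_ds, 2)
  expect_equal(tr$vmax_mbc, 0.5)
  expect_equal(tr$ce_mbc, 0.01)
  expect_equal(tr$ce_mbc * tr$mbc, tr$ce_ds)
  # Km -> Inf limit: catalytic efficiency -> 0
  expect_equal(derive_traits(100, 1e12, 200)$ce_ds, 0, tolerance = 1e-9)
  expect_warning(tr0 <- derive_traits(100, 50, 0), "non-positive MBC")
  expect_equal(tr0$vmax_ds, 100)
  expect_true(is.na(tr0$vmax_mbc))
})

test_that("non-significant fits are gated out of trait tables", {
  cfg <- small_config(cv_well = 0.10)
  sim <- simulate_campaign(cfg, seed = 29)
  qc <- qc_rates(reduce_rates(sim$assay, sim$soil))
  mm <- fit_mm_all(qc$rates, ledger = qc$ledger)
  traits <- derive_traits_all(mm$gated, sim$soil)
  gated_out <- mm$gated[!mm$gated$gated_in, ]
  if (nrow(gated_out) > 0) {
    expect_false(any(paste(gated_out$enzyme, gated_out$depth_cm,
                           gated_out$core, gated_out$temperature_C) %in%
                       paste(traits$enzyme, traits$depth_cm, traits$core,
                             traits$temperature_C)))
  }
  expect_true(all(traits$vmax_ds > 0))
  expect_true(all(traits$km > 0))
})
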
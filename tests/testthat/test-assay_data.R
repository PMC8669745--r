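test_that("assay table reader round-trips and validates", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  cols <- c("enzyme", "depth_cm", "core", "temperature_C", "substrate_uM",
            "replicate", "timepoint_h", "role", "fluorescence",
            "standard_nmol")
  # header-only file -> empty collection
  writeLines(paste(cols, collapse = ","), tmp)
  expect_equal(nrow(read_assay_table(tmp)), 0)

  # 4-row fixture, one well per replicate
  fix <- data.frame(enzyme = "BG", depth_cm = "0-10", core = 1,
                    temperature_C = 25, substrate_uM = 100,
                    replicate = 1:4, timepoint_h = 4, role = "sample",
                    fluorescence = c(500, 510, 505, 498),
                    standard_nmol = NA)
  write.csv(fix, tmp, row.names = FALSE)
  got <- read_assay_table(tmp)
  expect_equal(got$replicate, 1:4)
  expect_equal(got$fluorescence, fix$fluorescence)

  # schema and value validation
  fix2 <- fix; fix2$enzyme <- "XYZ"
  write.csv(fix2, tmp, row.names = FALSE)
  expect_error(read_assay_table(tmp), "unknown enzyme")
  fix3 <- fix; fix3$substrate_uM <- 11
  write.csv(fix3, tmp, row.names = FALSE)
  expect_error(read_assay_table(tmp), "substrate concentration")
  write.csv(fix[, -1], tmp, row.names = FALSE)
  expect_error(read_assay_table(tmp), "missing column")
})

test_that("campaign CSV record count matches the generator manifest", {
  dir <- withr::local_tempdir()
  sim <- simulate_campaign(small_config(), seed = 3, dir = dir)
  tab <- read_assay_table(file.path(dir, "assay.csv"))
  expect_equal(sum(tab$role == "sample"),
               sim$manifest$n_fit_units * sim$manifest$n_timepoints *
                 sim$manifest$wells_per_fit_unit)
  expect_equal(nrow(tab), nrow(sim$assay))
})

test_that("standard curves are fit by OLS with r-squared", {
  amt <- c(0.1, 0.5, 1, 2, 5, 10)
  sc <- fit_standard_curve(amt, 100 * amt)
  expect_equal(sc$slope, 100)
  expect_equal(sc$intercept, 0)
  expect_equal(sc$r_squared, 1)

  sc2 <- fit_standard_curve(amt, 100 * amt + 50)
  expect_equal(sc2$slope, 100)
  expect_equal(sc2$intercept, 50)

  # noisy fixture against the closed-form OLS oracle
  set.seed(41)
  fl <- 100 * amt + rnorm(6, 0, 5)
  sc3 <- fit_standard_curve(amt, fl)
  sxx <- sum((amt - mean(amt))^2)
  slope_ols <- sum((amt - mean(amt)) * (fl - mean(fl))) / sxx
  expect_equal(sc3$slope, slope_ols)
  se_slope <- sqrt(sum((fl - mean(fl) - slope_ols * (amt - mean(amt)))^2) /
                     4 / sxx)
  expect_lt(abs(sc3$slope - 100), 2 * se_slope)

  expect_error(fit_standard_curve(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(fit_standard_curve(1:2, 1:2), "3 points")
})

test_that("quench coefficient is the slope ratio", {
  unq <- fit_standard_curve(1:6, 100 * (1:6))
  expect_equal(quench_coefficient(unq, unq), 1)
  q <- fit_standard_curve(1:6, 80 * (1:6))
  expect_equal(quench_coefficient(unq, q), 0.8)
  bad <- unq; bad$slope <- -1
  expect_error(quench_coefficient(bad, q), "slope must be > 0")

  # recovered from a simulated batch with noise
  set.seed(5)
  amt <- rep(.5 * 2^(0:5), 2)
  unq2 <- fit_standard_curve(amt, 450 * amt * ln_noise(12, 0.02))
  qn2 <- fit_standard_curve(amt, 0.7 * 450 * amt * ln_noise(12, 0.02) + 60)
  expect_lt(abs(quench_coefficient(unq2, qn2) - 0.7), 0.05)
})

test_that("net fluorescence applies blank and quench corrections", {
  expect_equal(net_fluorescence(500, 0, 0, 1), 500)
  expect_equal(net_fluorescence(1200, 200, 50, 0.8), 1200)
  expect_equal(net_fluorescence(200, 200, 0, 0.9), 0)
  expect_error(net_fluorescence(1, 0, 0, 0), "quench")

  # linear in raw, strictly decreasing in the substrate blank
  raw <- seq(100, 900, by = 200)
  nf <- net_fluorescence(raw, 50, 10, 0.8)
  expect_equal(diff(nf), rep(diff(raw)[1] / 0.8, 4))
  expect_true(all(diff(net_fluorescence(500, 50, c(0, 10, 20), 0.8)) < 0))
})

test_that("activity rate converts net fluorescence to nmol per g dry soil", {
  expect_equal(activity_rate(0, 500, 1, 4), 0)
  # 200 fl / (500 fl/nmol) over 0.002 g dry soil and 4 h
  expect_equal(activity_rate(200, 500, 1, 4), 50)
  expect_equal(activity_rate(200, 500, 0.5, 4),
               2 * activity_rate(200, 500, 1, 4))
  # invariant to doubling net and emission coefficient together
  expect_equal(activity_rate(400, 1000, 0.8, 4),
               activity_rate(200, 500, 0.8, 4))
  expect_error(activity_rate(1, 500, 1, 0), "incubation")
  expect_error(activity_rate(1, -2, 1, 1), "emission")
})

test_that("zero-noise simulated plates reduce back to the generating rates", {
  cfg <- small_config()
  sim <- simulate_campaign(cfg, seed = 9)
  rates <- reduce_rates(sim$assay, sim$soil)
  k <- sim$truth$kinetics
  for (e in cfg$enzymes) for (d in cfg$depths) for (tc in cfg$temperatures) {
    u <- rates[rates$enzyme == e & rates$depth_cm == d &
                 rates$temperature_C == tc, ]
    km <- k$km[k$enzyme == e & k$depth_cm == d]
    vT <- soilenzkin:::.truth_vmax(sim$truth, e, d, tc) *
      soilenzkin:::.time_multiplier(4, tc)
    expect_equal(u$rate_nmol_g_h, vT * u$substrate_uM / (km + u$substrate_uM),
                 tolerance = 1e-10)
  }
})
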
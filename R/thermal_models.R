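## Temperature sensitivity: Q10, Arrhenius activation energy, and
## Macromolecular Rate Theory (MMRT).
##
## MMRT models the log rate as
##   ln k(T) = ln(kB*T/h) - [dH + dCp*(T - T0)] / (R*T)
##                        + [dS + dCp*ln(T/T0)] / R
## with activation enthalpy dH (J/mol) and entropy dS (J/mol/K) at the
## reference temperature T0, and activation heat-capacity change dCp
## (J/mol/K) setting the curvature. After moving the ln(kB*T/h) pre-factor
## to the left-hand side the model is exactly linear in (dH, dS, dCp), so
## the least-squares fit is solved in closed form by OLS -- no iterative
## optimisation and no convergence failures.
##
## The temperature optimum of the rate curve has the closed form
##   Topt = (dCp*T0 - dH) / (dCp + R),
## and the point of maximum temperature sensitivity (inflection of k(T),
## where dk/dT is largest) is located numerically below Topt from the sign
## change of g^2 + g', where g = d ln k / dT.

.rsq <- function(y, res) {
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) return(1)
  1 - sum(res^2) / sst
}

#' Q10 temperature coefficient by log-linear regression
#'
#' OLS of `ln(value)` on temperature in degrees C over the requested range;
#' `Q10 = exp(10 * slope)`.
#'
#' @param temperature_C assay temperatures (deg C).
#' @param value positive kinetic parameter values (Vmax, Km or CE).
#' @param range temperature window used, e.g. `c(4, 35)` (realistic field
#'   range) or `c(4, 50)` (full assay range).
#' @return list: `slope` (per deg C), `q10`, `r_squared`, `n`,
#'   `range_label`.
#' @export
q10_fit <- function(temperature_C, value, range = c(4, 35)) {
  inr <- temperature_C >= range[1] & temperature_C <= range[2]
  temperature_C <- temperature_C[inr]; value <- value[inr]
  if (any(value <= 0))
    stop("non-positive value at temperature ",
         paste(temperature_C[value <= 0], collapse = ", "),
         " deg C: log-linear Q10 undefined")
  if (length(value) < 3) stop("Q10 regression needs >= 3 points in range")
  fit <- lm(log(value) ~ temperature_C)
  slope <- unname(coef(fit)[2])
  list(slope = slope, q10 = exp(10 * slope),
       r_squared = .rsq(log(value), resid(fit)), n = length(value),
       range_label = paste0(range[1], "-", range[2]))
}

#' Arrhenius activation energy
#'
#' OLS of `ln(vmax)` on `1/T` (T in kelvin); `Ea = -slope * R` (J/mol).
#'
#' @param temperature_C assay temperatures (deg C).
#' @param vmax positive maximal velocities.
#' @return list: `slope` (K), `ea` (J/mol), `r_squared`, `rss`, `n`.
#' @export
arrhenius_fit <- function(temperature_C, vmax) {
  if (any(vmax <= 0))
    stop("non-positive Vmax at temperature ",
         paste(temperature_C[vmax <= 0], collapse = ", "), " deg C")
  if (length(vmax) < 3) stop("Arrhenius regression needs >= 3 points")
  inv_T <- 1 / (temperature_C + .C_TO_K)
  fit <- lm(log(vmax) ~ inv_T)
  slope <- unname(coef(fit)[2])
  list(slope = slope, ea = -slope * .R_GAS,
       r_squared = .rsq(log(vmax), resid(fit)),
       rss = sum(resid(fit)^2), n = length(vmax))
}

#' MMRT log-rate curve
#'
#' @param T_K temperature in kelvin.
#' @param dH,dS,dCp activation enthalpy (J/mol), entropy (J/mol/K) and
#'   heat-capacity change (J/mol/K) at `T0`.
#' @param T0 reference temperature (K).
#' @export
mmrt_lnrate <- function(T_K, dH, dS, dCp, T0 = 315) {
  log(.K_BOLTZ * T_K / .H_PLANCK) -
    (dH + dCp * (T_K - T0)) / (.R_GAS * T_K) +
    (dS + dCp * log(T_K / T0)) / .R_GAS
}

## d ln k / dT and its derivative (analytic)
.mmrt_g <- function(T_K, dH, dCp, T0) {
  1 / T_K + (dH + dCp * (T_K - T0)) / (.R_GAS * T_K^2)
}
.mmrt_gprime <- function(T_K, dH, dCp, T0) {
  -1 / T_K^2 + dCp / (.R_GAS * T_K^2) -
    2 * (dH + dCp * (T_K - T0)) / (.R_GAS * T_K^3)
}

#' Analytic MMRT temperature optimum
#'
#' Stationary point of the log rate curve:
#' `Topt = (dCp * T0 - dH) / (dCp + R)`. When `dCp >= -R` the curve has no
#' finite maximum and `Inf` is returned (flagged invalid downstream).
#'
#' @inheritParams mmrt_lnrate
#' @return temperature in kelvin.
#' @export
mmrt_topt <- function(dH, dCp, T0 = 315) {
  if (dCp + .R_GAS >= 0) return(Inf)
  (dCp * T0 - dH) / (dCp + .R_GAS)
}

#' Numeric MMRT point of maximum temperature sensitivity
#'
#' The inflection of the rate curve k(T) (maximum of dk/dT), i.e. the root
#' of `g^2 + g'` with `g = d ln k/dT`, located by bisection to 0.01 K below
#' the temperature optimum.
#'
#' @inheritParams mmrt_lnrate
#' @param topt optimum (K); computed if missing.
#' @param lower lower bound of the search window (K).
#' @return temperature in kelvin, or `NA` when no sign change exists in the
#'   window (flagged invalid downstream).
#' @export
mmrt_tsmax <- function(dH, dCp, T0 = 315, topt = NULL, lower = 150) {
  if (is.null(topt)) topt <- mmrt_topt(dH, dCp, T0)
  if (!is.finite(topt) || topt <= lower) return(NA_real_)
  f <- function(T_K) .mmrt_g(T_K, dH, dCp, T0)^2 +
    .mmrt_gprime(T_K, dH, dCp, T0)
  grid <- seq(lower, topt - 1e-3, length.out = 400)
  fv <- f(grid)
  sc <- which(fv[-length(fv)] * fv[-1] <= 0)
  if (length(sc) == 0) return(NA_real_)
  ## take the sign change nearest the optimum (the rising-limb inflection)
  i <- sc[length(sc)]
  uniroot(f, c(grid[i], grid[i + 1]), tol = 0.01)$root
}

#' Fit the MMRT model to ln(Vmax) over temperature
#'
#' Least squares on the MMRT log-rate curve via its exact linear
#' reparameterisation in (dH, dS, dCp). Fits with a temperature optimum or
#' maximum-sensitivity point outside 0-200 deg C are flagged invalid
#' (poor conformance to MMRT's predicted unimodal behaviour).
#'
#' @param temperature_C assay temperatures (deg C); >= 4 required.
#' @param ln_vmax natural log of Vmax at those temperatures.
#' @param T0 reference temperature (K), default 315.
#' @return list of class `mmrt_fit`: `dH, dS, dCp` (J/mol, J/mol/K),
#'   `T0`, `topt`, `tsmax` (K), `valid`, `rss`, `n`, `converged`.
#' @export
mmrt_fit <- function(temperature_C, ln_vmax, T0 = 315) {
  if (length(ln_vmax) < 4)
    stop("MMRT fit needs >= 4 temperatures (3 parameters + residual)")
  T_K <- temperature_C + .C_TO_K
  y <- ln_vmax - log(.K_BOLTZ * T_K / .H_PLANCK)
  x_H <- -1 / (.R_GAS * T_K)
  x_S <- rep(1 / .R_GAS, length(T_K))
  x_C <- -(T_K - T0) / (.R_GAS * T_K) + log(T_K / T0) / .R_GAS
  fit <- lm(y ~ 0 + x_H + x_S + x_C)
  cf <- coef(fit)
  dH <- unname(cf["x_H"]); dS <- unname(cf["x_S"]); dCp <- unname(cf["x_C"])
  topt <- mmrt_topt(dH, dCp, T0)
  tsmax <- mmrt_tsmax(dH, dCp, T0, topt = topt)
  in_band <- function(T_K) is.finite(T_K) &&
    T_K >= .C_TO_K && T_K <= 200 + .C_TO_K
  structure(list(dH = dH, dS = dS, dCp = dCp, T0 = T0,
                 topt = topt, tsmax = tsmax,
                 valid = in_band(topt) && in_band(tsmax),
                 rss = sum(resid(fit)^2), n = length(y),
                 converged = all(is.finite(cf))),
            class = "mmrt_fit")
}

#' @export
print.mmrt_fit <- function(x, ...) {
  cat(sprintf(paste0("MMRT fit: dCp = %.1f J/mol/K, dH = %.0f J/mol, ",
                     "Topt = %.2f K, TSmax = %.2f K, valid = %s\n"),
              x$dCp, x$dH, x$topt, x$tsmax, x$valid))
  invisible(x)
}

#' Compare Arrhenius and MMRT fits by information criteria
#'
#' Gaussian criteria from the residual sum of squares on a common response
#' vector (constants dropped): `AIC = n*log(RSS/n) + 2k`,
#' `AICc = AIC + 2k(k+1)/(n-k-1)`, `BIC = n*log(RSS/n) + k*log(n)`. The
#' parameter count k includes the residual variance (Arrhenius k = 3, MMRT
#' k = 4). Relative likelihoods are `exp(-dAICc/2)` against the AICc-best
#' model.
#'
#' @param rss named numeric vector of residual sums of squares, e.g.
#'   `c(arrhenius = ..., mmrt = ...)`.
#' @param k parameter counts in the same order (including residual
#'   variance).
#' @param n number of points in the shared response.
#' @return data.frame with `model, k, logLik, AIC, AICc, BIC,
#'   rel_likelihood`.
#' @export
compare_models <- function(rss, k = c(arrhenius = 3, mmrt = 4), n) {
  stopifnot(length(rss) == length(k))
  ll <- -n / 2 * log(rss / n)
  aic <- 2 * k - 2 * ll
  denom <- n - k - 1
  aicc <- ifelse(denom > 0, aic + 2 * k * (k + 1) / denom, NA_real_)
  if (any(denom <= 0))
    warning("AICc undefined for model(s) with n - k - 1 <= 0")
  if (any(denom == 1))
    message("small-sample AICc: n - k - 1 = 1 for some model(s)")
  bic <- k * log(n) - 2 * ll
  ref <- if (all(is.na(aicc))) aic else aicc
  rel <- exp(-(ref - min(ref, na.rm = TRUE)) / 2)
  data.frame(model = names(rss), k = unname(k), logLik = unname(ll),
             AIC = unname(aic), AICc = unname(aicc), BIC = unname(bic),
             rel_likelihood = unname(rel), row.names = NULL)
}

#' Thermal trait estimation over a trait table
#'
#' Per enzyme x depth x core: Q10 of Vmax, Km and CE over the field (4-35
#' deg C) and full (4-50 deg C) ranges, Arrhenius Ea over the field range,
#' and the MMRT fit over the full range, with the Arrhenius-vs-MMRT
#' information-criterion comparison on the full-range ln(Vmax).
#'
#' @param traits trait table from [derive_traits_all()] (dry-soil basis
#'   Vmax is used for thermal fits).
#' @param ledger exclusion ledger extended with `mmrt_invalid` counts.
#' @param T0 MMRT reference temperature (K).
#' @return list with `thermal` (one row per enzyme x depth x core) and
#'   `ledger`.
#' @export
thermal_all <- function(traits, ledger = new_ledger(), T0 = 315) {
  key <- interaction(traits$enzyme, traits$depth_cm, traits$core,
                     drop = TRUE)
  rows <- lapply(split(traits, key), function(u) {
    u <- u[order(u$temperature_C), ]
    out <- data.frame(enzyme = u$enzyme[1], depth_cm = u$depth_cm[1],
                      core = u$core[1],
                      q10_vmax = NA_real_, q10_km = NA_real_,
                      q10_ce = NA_real_, q10_vmax_full = NA_real_,
                      ea_kj_mol = NA_real_, dcp_j_mol_k = NA_real_,
                      dh_j_mol = NA_real_, topt_c = NA_real_,
                      tsmax_c = NA_real_, mmrt_valid = NA,
                      aicc_arrhenius = NA_real_, aicc_mmrt = NA_real_,
                      rel_lik_arrhenius = NA_real_,
                      rel_lik_mmrt = NA_real_)
    try_na <- function(expr) tryCatch(expr, error = function(e) NULL)
    fld <- u[u$temperature_C <= 35, ]
    q_v <- try_na(q10_fit(fld$temperature_C, fld$vmax_ds))
    q_k <- try_na(q10_fit(fld$temperature_C, fld$km))
    q_c <- try_na(q10_fit(fld$temperature_C, fld$ce_ds))
    q_vf <- try_na(q10_fit(u$temperature_C, u$vmax_ds, range = c(4, 50)))
    if (!is.null(q_v)) out$q10_vmax <- q_v$q10
    if (!is.null(q_k)) out$q10_km <- q_k$q10
    if (!is.null(q_c)) out$q10_ce <- q_c$q10
    if (!is.null(q_vf)) out$q10_vmax_full <- q_vf$q10
    arr <- try_na(arrhenius_fit(fld$temperature_C, fld$vmax_ds))
    if (!is.null(arr)) out$ea_kj_mol <- arr$ea / 1000
    if (nrow(u) >= 4) {
      mm <- try_na(mmrt_fit(u$temperature_C, log(u$vmax_ds), T0 = T0))
      if (!is.null(mm)) {
        out$dcp_j_mol_k <- mm$dCp
        out$dh_j_mol <- mm$dH
        out$topt_c <- mm$topt - .C_TO_K
        out$tsmax_c <- mm$tsmax - .C_TO_K
        out$mmrt_valid <- mm$valid
        arr_full <- try_na(arrhenius_fit(u$temperature_C, u$vmax_ds))
        if (!is.null(arr_full)) {
          cmp <- suppressMessages(
            compare_models(c(arrhenius = arr_full$rss, mmrt = mm$rss),
                           n = nrow(u)))
          out$aicc_arrhenius <- cmp$AICc[1]
          out$aicc_mmrt <- cmp$AICc[2]
          out$rel_lik_arrhenius <- cmp$rel_likelihood[1]
          out$rel_lik_mmrt <- cmp$rel_likelihood[2]
        }
      }
    }
    out
  })
  thermal <- do.call(rbind, rows)
  rownames(thermal) <- NULL
  ledger <- ledger_add(ledger, "mmrt_invalid",
                       sum(!thermal$mmrt_valid, na.rm = TRUE))
  list(thermal = thermal, ledger = ledger)
}
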
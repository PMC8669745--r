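## Two-parameter Michaelis-Menten fitting with a transform-both-sides
## Box-Cox correction.
##
## Analytical variance in fluorometric assays grows with the mean, so plain
## nonlinear least squares over-weights the high-concentration wells. Both
## the response v and the model mu(S) = Vmax * S / (Km + S) are passed
## through the same Box-Cox transform with exponent lambda; lambda is chosen
## by profile maximum likelihood over a grid (the Jacobian term
## (lambda - 1) * sum(log v) makes profiles comparable across lambda).
## Estimates are reported on the original parameter scale with asymptotic
## standard errors from the transformed-scale Jacobian.

#' Box-Cox transform
#' @param y positive numeric vector.
#' @param lambda exponent; 0 means natural log.
#' @export
boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

## least squares for a fixed lambda; returns NULL on failure
.mm_fit_lambda <- function(conc, v, lambda, start) {
  bcv <- boxcox_transform(v, lambda)
  starts <- list(start,
                 list(vmax = start$vmax * 1.5, km = start$km * 3),
                 list(vmax = start$vmax * 0.7, km = start$km / 3))
  for (st in starts) {
    fit <- tryCatch(
      nls(bcv ~ boxcox_transform(vmax * conc / (km + conc), lambda),
          start = st, algorithm = "port",
          lower = c(vmax = 1e-9, km = 1e-9),
          control = list(warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  NULL
}

.mm_profile_ll <- function(rss, n, lambda, sum_log_v) {
  -n / 2 * log(rss / n) + (lambda - 1) * sum_log_v
}

#' Fit a two-parameter Michaelis-Menten model with Box-Cox
#'
#' Fits `v = Vmax * S / (Km + S)` to all analytical replicates of a
#' substrate series by transform-both-sides least squares, profiling the
#' shared Box-Cox exponent over a grid (refined once around the optimum).
#' Starting values are data-driven: `Vmax0` is the largest per-concentration
#' mean rate and `Km0` the concentration whose mean rate is nearest
#' `Vmax0 / 2`. Standard errors are asymptotic (Jacobian of the transformed
#' model), and p-values two-sided t with `n - 2` df.
#'
#' @param conc substrate concentrations (uM), one per well.
#' @param rate observed rates (nmol g-1 h-1), one per well. Non-positive
#'   rates are excluded before fitting (the Box-Cox transform requires a
#'   positive response); QC normally removes them upstream.
#' @param lambda_grid grid of Box-Cox exponents profiled.
#' @param lambda fix the exponent instead of profiling (e.g. `1` for plain
#'   nonlinear least squares).
#' @param refine refine the grid once around the best exponent.
#' @return object of class `mm_fit`: `vmax, km, se_vmax, se_km, p_vmax,
#'   p_km, lambda, n_points, rss, loglik, converged, dropped_concentration`.
#' @export
fit_mm <- function(conc, rate, lambda_grid = seq(-2, 2, by = 0.1),
                   lambda = NULL, refine = TRUE) {
  pos <- rate > 0 & is.finite(rate)
  conc <- conc[pos]; rate <- rate[pos]
  if (length(unique(conc)) < 4)
    stop("insufficient design: need >= 4 distinct substrate concentrations")
  n <- length(rate)
  mu_by_conc <- tapply(rate, conc, mean)
  vmax0 <- max(mu_by_conc)
  km0 <- as.numeric(names(mu_by_conc))[which.min(abs(mu_by_conc - vmax0 / 2))]
  start <- list(vmax = vmax0, km = max(km0, 1e-3))
  sum_log_v <- sum(log(rate))

  profile_one <- function(lam, st) {
    fit <- .mm_fit_lambda(conc, rate, lam, st)
    if (is.null(fit)) return(NULL)
    list(fit = fit, lambda = lam, rss = sum(resid(fit)^2),
         ll = .mm_profile_ll(sum(resid(fit)^2), n, lam, sum_log_v))
  }

  if (!is.null(lambda)) {
    best <- profile_one(lambda, start)
  } else {
    best <- NULL
    st <- start
    for (lam in lambda_grid) {
      res <- profile_one(lam, st)
      if (!is.null(res)) {
        st <- as.list(coef(res$fit))    # warm start along the grid
        if (is.null(best) || res$ll > best$ll) best <- res
      }
    }
    if (!is.null(best) && refine) {
      step <- if (length(lambda_grid) > 1) diff(lambda_grid[1:2]) else 0.1
      fine <- seq(best$lambda - step, best$lambda + step, by = step / 5)
      st <- as.list(coef(best$fit))
      for (lam in fine) {
        res <- profile_one(lam, st)
        if (!is.null(res) && res$ll > best$ll) best <- res
      }
    }
  }

  if (is.null(best))
    return(structure(list(vmax = NA_real_, km = NA_real_,
                          se_vmax = NA_real_, se_km = NA_real_,
                          p_vmax = NA_real_, p_km = NA_real_,
                          lambda = NA_real_, n_points = n, rss = NA_real_,
                          loglik = NA_real_, converged = FALSE,
                          dropped_concentration = NA_real_),
                     class = "mm_fit"))

  est <- coef(best$fit)
  lam <- best$lambda
  ## numeric Jacobian of the transformed model wrt (vmax, km)
  h <- function(th) boxcox_transform(th[1] * conc / (th[2] + conc), lam)
  eps <- pmax(abs(est), 1) * 1e-6
  J <- cbind((h(est + c(eps[1], 0)) - h(est - c(eps[1], 0))) / (2 * eps[1]),
             (h(est + c(0, eps[2])) - h(est - c(0, eps[2]))) / (2 * eps[2]))
  df <- n - 2
  sigma2 <- best$rss / df
  cov <- tryCatch(sigma2 * solve(crossprod(J)),
                  error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(diag(cov))
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df)
  structure(list(vmax = unname(est[1]), km = unname(est[2]),
                 se_vmax = unname(se[1]), se_km = unname(se[2]),
                 p_vmax = unname(pval[1]), p_km = unname(pval[2]),
                 lambda = lam, n_points = n, rss = best$rss,
                 loglik = best$ll, converged = TRUE,
                 dropped_concentration = NA_real_),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "MM fit: Vmax = %.4g (se %.3g, p %.3g), Km = %.4g (se %.3g, p %.3g)\n",
    x$vmax, x$se_vmax, x$p_vmax, x$km, x$se_km, x$p_km))
  cat(sprintf("  lambda = %.2f, n = %d, converged = %s\n",
              x$lambda, x$n_points, x$converged))
  invisible(x)
}

#' Drop one consistently misfitting substrate concentration
#'
#' A single substrate concentration (e.g. inhibited at the top of the
#' series, or a preparation error) may be removed if all of its analytical
#' replicates misfit with the same residual sign and removing it improves
#' the fit by more than `ic_threshold` information-criterion units, the
#' comparison being made on the retained points only so both models score
#' the same data.
#'
#' @param conc,rate as in [fit_mm()].
#' @param fit current `mm_fit` for these data.
#' @param ic_threshold required AIC improvement (default 2).
#' @param ... passed to [fit_mm()] for the refits.
#' @return list with `conc`, `rate` (possibly reduced), and `fit` (refit,
#'   with `dropped_concentration` set when a concentration was removed).
#' @export
drop_bad_concentration <- function(conc, rate, fit, ic_threshold = 2, ...) {
  if (length(unique(conc)) < 5 || !isTRUE(fit$converged))
    return(list(conc = conc, rate = rate, fit = fit))
  mu <- fit$vmax * conc / (fit$km + conc)
  res <- rate - mu
  cand <- Filter(function(cc) {
    s <- sign(res[conc == cc])
    length(s) > 0 && all(s != 0) && length(unique(s)) == 1
  }, unique(conc))
  if (length(cand) == 0) return(list(conc = conc, rate = rate, fit = fit))

  aic_on <- function(f, cc_keep) {
    ## score both fits on the kept points with a Gaussian RSS criterion
    mu_k <- f$vmax * cc_keep$conc / (f$km + cc_keep$conc)
    rss <- sum((boxcox_transform(cc_keep$rate, f$lambda) -
                  boxcox_transform(mu_k, f$lambda))^2)
    m <- length(cc_keep$rate)
    m * log(rss / m) + 2 * 3 -
      2 * (f$lambda - 1) * sum(log(cc_keep$rate))
  }
  best <- NULL
  for (cc in cand) {
    keep <- conc != cc
    refit <- tryCatch(fit_mm(conc[keep], rate[keep], ...),
                      error = function(e) NULL)
    if (is.null(refit) || !refit$converged) next
    kept <- list(conc = conc[keep], rate = rate[keep])
    gain <- aic_on(fit, kept) - aic_on(refit, kept)
    if (!is.finite(gain)) next   # degenerate (near-zero RSS) comparisons
    if (gain > ic_threshold && (is.null(best) || gain > best$gain))
      best <- list(cc = cc, refit = refit, gain = gain)
  }
  if (is.null(best)) return(list(conc = conc, rate = rate, fit = fit))
  best$refit$dropped_concentration <- best$cc
  keep <- conc != best$cc
  list(conc = conc[keep], rate = rate[keep], fit = best$refit)
}

#' Select the assay incubation time per temperature batch
#'
#' Chooses, for each temperature batch, the minimum incubation period whose
#' median Vmax across fit units is within `tolerance` of the batch maximum
#' (lower Vmax at short incubations reflects insufficient reaction time;
#' lower Vmax at long incubations reflects saturation or fluorophore loss).
#'
#' @param fits data.frame with columns `temperature_C`, `timepoint_h`,
#'   `vmax` (one row per fit unit x timepoint; failed fits as `NA`).
#' @param tolerance fraction of the batch-maximum median Vmax (default 5%).
#' @return data.frame `temperature_C, timepoint_h` with the chosen
#'   incubation per batch.
#' @export
select_incubation_time <- function(fits, tolerance = 0.05) {
  sel <- lapply(split(fits, fits$temperature_C), function(b) {
    med <- tapply(b$vmax, b$timepoint_h, median, na.rm = TRUE)
    med <- med[is.finite(med)]
    if (length(med) < 1) return(NULL)
    best <- max(med)
    ok <- as.numeric(names(med))[med >= (1 - tolerance) * best]
    data.frame(temperature_C = b$temperature_C[1], timepoint_h = min(ok))
  })
  out <- do.call(rbind, sel)
  rownames(out) <- NULL
  out
}

#' Microbial biomass C from chloroform fumigation-extraction
#'
#' `MBC = C_fumigated - C_nonfumigated`, with no extraction-efficiency
#' correction factor (kEC) applied.
#'
#' @param c_fumigated,c_nonfumigated extractable C (ug g-1 dry soil).
#' @return ug MBC g-1 dry soil; a warning is raised for negative
#'   differences (possible in noisy deep samples).
#' @export
mbc_from_fumigation <- function(c_fumigated, c_nonfumigated) {
  mbc <- c_fumigated - c_nonfumigated
  if (any(mbc < 0))
    warning("negative MBC estimate(s): fumigated extract below non-fumigated")
  mbc
}

#' Derive kinetic traits from a gated-in fit
#'
#' @param vmax_ds Vmax per gram dry soil (nmol g-1 h-1).
#' @param km Michaelis constant (uM).
#' @param mbc microbial biomass C (ug g-1 dry soil).
#' @return list: `vmax_ds`, `vmax_mbc = vmax_ds / mbc`, `km`,
#'   `ce_ds = vmax_ds / km`, `ce_mbc = vmax_mbc / km`, `mbc`. When
#'   `mbc <= 0` the biomass-normalised traits are `NA` with a warning and
#'   the dry-soil traits are still returned.
#' @export
derive_traits <- function(vmax_ds, km, mbc) {
  vmax_mbc <- ifelse(mbc > 0, vmax_ds / mbc, NA_real_)
  if (any(mbc <= 0, na.rm = TRUE))
    warning("non-positive MBC: biomass-normalised traits set to NA")
  list(vmax_ds = vmax_ds, vmax_mbc = vmax_mbc, km = km,
       ce_ds = vmax_ds / km, ce_mbc = vmax_mbc / km, mbc = mbc)
}

#' Fit Michaelis-Menten models over a whole campaign
#'
#' Fits every enzyme x depth x core x temperature x timepoint unit,
#' attempts a single consistently-misfitting concentration drop, selects
#' one incubation time per temperature batch, and gates out fits whose
#' Vmax or Km is non-significant (p > `p_gate`).
#'
#' @param rates QC'd rates (see [qc_rates()]).
#' @param ledger exclusion ledger to extend with `nonsignificant_model`
#'   counts (gating among the selected-incubation fits).
#' @param p_gate significance threshold for both parameters.
#' @param try_drop attempt [drop_bad_concentration()] on each unit.
#' @param ... passed to [fit_mm()].
#' @return list with `fits` (all timepoints), `selection` (chosen
#'   incubation per temperature), `gated` (fits at the chosen incubation
#'   with `gated_in` flag), `ledger`.
#' @export
fit_mm_all <- function(rates, ledger = new_ledger(), p_gate = 0.05,
                       try_drop = TRUE, ...) {
  key <- interaction(rates$enzyme, rates$depth_cm, rates$core,
                     rates$temperature_C, rates$timepoint_h, drop = TRUE)
  rows <- lapply(split(rates, key), function(u) {
    fit <- tryCatch(fit_mm(u$substrate_uM, u$rate_nmol_g_h, ...),
                    error = function(e) NULL)
    if (!is.null(fit) && try_drop && isTRUE(fit$converged)) {
      d <- drop_bad_concentration(u$substrate_uM, u$rate_nmol_g_h, fit, ...)
      fit <- d$fit
    }
    data.frame(enzyme = u$enzyme[1], depth_cm = u$depth_cm[1],
               core = u$core[1], temperature_C = u$temperature_C[1],
               timepoint_h = u$timepoint_h[1],
               vmax = if (is.null(fit)) NA_real_ else fit$vmax,
               km = if (is.null(fit)) NA_real_ else fit$km,
               se_vmax = if (is.null(fit)) NA_real_ else fit$se_vmax,
               se_km = if (is.null(fit)) NA_real_ else fit$se_km,
               p_vmax = if (is.null(fit)) NA_real_ else fit$p_vmax,
               p_km = if (is.null(fit)) NA_real_ else fit$p_km,
               lambda = if (is.null(fit)) NA_real_ else fit$lambda,
               n_points = if (is.null(fit)) NA_integer_ else fit$n_points,
               dropped_concentration =
                 if (is.null(fit)) NA_real_ else fit$dropped_concentration,
               converged = !is.null(fit) && isTRUE(fit$converged))
  })
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  n_drop <- sum(!is.na(fits$dropped_concentration))
  if (n_drop > 0) ledger <- ledger_add(ledger, "concentration_drop", n_drop)

  selection <- select_incubation_time(fits)
  sel_key <- paste(selection$temperature_C, selection$timepoint_h)
  gated <- fits[paste(fits$temperature_C, fits$timepoint_h) %in% sel_key, ]
  gated$gated_in <- gated$converged &
    !is.na(gated$p_vmax) & !is.na(gated$p_km) &
    gated$p_vmax <= p_gate & gated$p_km <= p_gate
  ledger <- ledger_add(ledger, "nonsignificant_model", sum(!gated$gated_in))
  rownames(gated) <- NULL
  list(fits = fits, selection = selection, gated = gated, ledger = ledger)
}

#' Kinetic trait table for gated-in fits
#'
#' @param gated gated fit table from [fit_mm_all()].
#' @param soil soil context (per depth x core) with `c_fumigated`,
#'   `c_nonfumigated`.
#' @return data.frame of traits per enzyme x depth x core x temperature.
#' @export
derive_traits_all <- function(gated, soil) {
  keep <- gated[gated$gated_in, ]
  soil$mbc <- mbc_from_fumigation(soil$c_fumigated, soil$c_nonfumigated)
  mbc <- soil$mbc[match(paste(keep$depth_cm, keep$core),
                        paste(soil$depth_cm, soil$core))]
  tr <- derive_traits(keep$vmax, keep$km, mbc)
  cbind(keep[, c("enzyme", "depth_cm", "core", "temperature_C",
                 "timepoint_h")],
        as.data.frame(tr))
}
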
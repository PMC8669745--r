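# Shared fixtures: all test data is generated in code.

# small, fast campaign configuration (2 enzymes x 2 depths x 2 temps)
small_config <- function(...) {
  base <- list(enzymes = c("BG", "AP"), depths = c("0-10", "80-90"),
               temperatures = c(4, 25), cores = 1, timepoints = c(4),
               cv_well = 0, p_negative = 0, p_outlier = 0, extract_cv = 0)
  override <- list(...)
  do.call(campaign_config, utils::modifyList(base, override))
}

# exact Michaelis-Menten rates at the BG substrate series
mm_exact <- function(vmax = 100, km = 50, reps = 4,
                     conc = sek_substrates$BG) {
  s <- rep(conc, reps)
  list(conc = s, rate = vmax * s / (km + s))
}

# proportional (lognormal, mean-1) noise
ln_noise <- function(n, cv) {
  rlnorm(n, -0.5 * log(1 + cv^2), sqrt(log(1 + cv^2)))
}

# independent brute-force profile objective for the transform-both-sides fit
mm_profile_grid_oracle <- function(conc, rate, vmax_grid, km_grid,
                                   lambda_grid) {
  bc <- function(y, l) if (abs(l) < 1e-12) log(y) else (y^l - 1) / l
  n <- length(rate)
  slv <- sum(log(rate))
  best <- list(ll = -Inf)
  for (l in lambda_grid) {
    bcv <- bc(rate, l)
    for (v in vmax_grid) for (k in km_grid) {
      rss <- sum((bcv - bc(v * conc / (k + conc), l))^2)
      ll <- -n / 2 * log(rss / n) + (l - 1) * slv
      if (ll > best$ll)
        best <- list(ll = ll, vmax = v, km = k, lambda = l, rss = rss)
    }
  }
  best
}

# brute-force validity check of a compact letter display: significant pairs
# never share a letter, non-significant pairs always share one
cld_is_valid <- function(letters_vec, p, alpha = 0.05) {
  g <- length(letters_vec)
  sets <- strsplit(letters_vec, "")
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    shared <- length(intersect(sets[[i]], sets[[j]])) > 0
    if (p[i, j] <= alpha && shared) return(FALSE)
    if (p[i, j] > alpha && !shared) return(FALSE)
  }
  TRUE
}
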
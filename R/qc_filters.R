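## Exclusion rules with an auditable ledger.
##
## Two well-level rules are applied to reduced rates within each
## enzyme x depth x core x temperature x substrate x timepoint replicate
## cell: strictly negative values (analytical error) are removed, then at
## most one of the remaining analytical replicates may be removed as an
## interquartile-range outlier. Model-level exclusions (non-significant
## Michaelis-Menten fits, invalid MMRT fits, dropped substrate
## concentrations) are appended to the same ledger downstream.

.qc_reasons <- c("negative_value", "iqr_outlier", "concentration_drop",
                 "nonsignificant_model", "mmrt_invalid")

#' Create an empty exclusion ledger
#' @export
new_ledger <- function() {
  structure(list(counts = setNames(rep(0L, length(.qc_reasons)),
                                   .qc_reasons),
                 inspected = 0L),
            class = "exclusion_ledger")
}

#' Record exclusions in a ledger
#' @param ledger an [new_ledger()] object.
#' @param reason one of `negative_value`, `iqr_outlier`,
#'   `concentration_drop`, `nonsignificant_model`, `mmrt_invalid`.
#' @param n number of data points (or models) excluded.
#' @export
ledger_add <- function(ledger, reason, n = 1L) {
  reason <- match.arg(reason, .qc_reasons)
  ledger$counts[reason] <- ledger$counts[reason] + as.integer(n)
  ledger
}

#' @export
ledger_inspect <- function(ledger, n) {
  ledger$inspected <- ledger$inspected + as.integer(n)
  ledger
}

#' Summarise an exclusion ledger
#'
#' @param ledger finalized ledger.
#' @return data.frame `reason, count, fraction` plus a `total` and
#'   `percent_excluded` attribute; the percentage is
#'   `100 * excluded / inspected`.
#' @export
exclusion_summary <- function(ledger) {
  total <- sum(ledger$counts)
  out <- data.frame(reason = names(ledger$counts),
                    count = as.integer(ledger$counts),
                    fraction = if (total > 0) ledger$counts / total
                               else rep(0, length(ledger$counts)),
                    row.names = NULL)
  attr(out, "total_excluded") <- total
  attr(out, "inspected") <- ledger$inspected
  attr(out, "percent_excluded") <-
    if (ledger$inspected > 0) 100 * total / ledger$inspected else 0
  out
}

#' Drop strictly negative values
#'
#' Negative rates (or net fluorescences) arise from analytical error and are
#' excluded; zeros are retained.
#'
#' @param values numeric vector.
#' @return list with `values` (kept) and `removed` (indices removed).
#' @export
drop_negative <- function(values) {
  removed <- which(values < 0)
  list(values = if (length(removed)) values[-removed] else values,
       removed = removed)
}

#' Interquartile-range replicate filter
#'
#' Flags values outside the Tukey fences `[Q1 - k*IQR, Q3 + k*IQR]`
#' (quartiles by linear interpolation, R type 7; `k = 1.5`) and removes at
#' most one value: the flagged value farthest from the median, ties broken
#' toward the larger absolute value, then the first index.
#'
#' @param values 2-4 analytical replicates; fewer than 2 values pass
#'   through with a warning.
#' @param k fence multiplier.
#' @return list with `values` (kept) and `removed` (index removed, if any).
#' @export
iqr_replicate_filter <- function(values, k = 1.5) {
  if (length(values) < 2) {
    warning("fewer than 2 replicates: IQR filter passthrough")
    return(list(values = values, removed = integer(0)))
  }
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fence <- c(q[1] - k * iqr, q[2] + k * iqr)
  flagged <- which(values < fence[1] | values > fence[2])
  if (length(flagged) == 0) return(list(values = values, removed = integer(0)))
  med <- median(values)
  dist <- abs(values[flagged] - med)
  cand <- flagged[dist == max(dist)]
  if (length(cand) > 1) {
    amax <- abs(values[cand])
    cand <- cand[amax == max(amax)]
  }
  removed <- cand[1]
  list(values = values[-removed], removed = removed)
}

#' Quality-control reduced rates
#'
#' Applies [drop_negative()] then [iqr_replicate_filter()] within each
#' replicate cell and accumulates an exclusion ledger.
#'
#' @param rates data.frame from [reduce_rates()].
#' @param ledger optional existing ledger to extend.
#' @return list with `rates` (kept rows) and `ledger`.
#' @export
qc_rates <- function(rates, ledger = new_ledger()) {
  ledger <- ledger_inspect(ledger, nrow(rates))
  key <- interaction(rates$enzyme, rates$depth_cm, rates$core,
                     rates$temperature_C, rates$substrate_uM,
                     rates$timepoint_h, drop = TRUE)
  keep <- rep(TRUE, nrow(rates))
  n_neg <- 0L; n_iqr <- 0L
  for (idx in split(seq_len(nrow(rates)), key)) {
    v <- rates$rate_nmol_g_h[idx]
    neg <- which(v < 0)
    n_neg <- n_neg + length(neg)
    if (length(neg)) {
      keep[idx[neg]] <- FALSE
      idx <- idx[-neg]
      v <- v[-neg]
    }
    if (length(v) >= 2) {
      f <- iqr_replicate_filter(v)
      if (length(f$removed)) {
        keep[idx[f$removed]] <- FALSE
        n_iqr <- n_iqr + 1L
      }
    }
  }
  ledger <- ledger_add(ledger, "negative_value", n_neg)
  ledger <- ledger_add(ledger, "iqr_outlier", n_iqr)
  list(rates = rates[keep, , drop = FALSE], ledger = ledger)
}
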
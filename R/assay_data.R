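## Reduction of raw plate fluorescence to quench-corrected activity rates
## per gram dry soil.
##
## Well-level arithmetic follows the standard fluorometric reduction:
##   net = (raw - homogenate_blank) / quench - substrate_blank
##   rate [nmol g-1 h-1] = (net / emission_coef) / (dry_g_in_well * time)
## where emission_coef (fluorescence units per nmol standard in well) and the
## quench coefficient (quenched / unquenched standard-curve slope) are
## estimated per temperature batch, the latter per depth since soil
## homogenates quench depth-dependently.

.assay_roles <- c("sample", "standard", "quench_standard",
                  "homogenate_blank", "substrate_blank")

.assay_cols <- c("enzyme", "depth_cm", "core", "temperature_C",
                 "substrate_uM", "replicate", "timepoint_h", "role",
                 "fluorescence", "standard_nmol")

#' Read a long-format assay table
#'
#' One row per well. Sample wells carry the full factorial coordinates;
#' standards carry `standard_nmol` (amount of fluorophore in the well)
#' instead of `substrate_uM`. Roles: `sample`, `standard`,
#' `quench_standard`, `homogenate_blank`, `substrate_blank`.
#'
#' @param path path to a CSV with columns `enzyme, depth_cm, core,
#'   temperature_C, substrate_uM, replicate, timepoint_h, role,
#'   fluorescence, standard_nmol`.
#' @return a validated `data.frame` of wells.
#' @export
read_assay_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.assay_cols, names(tab))
  if (length(missing_cols) > 0)
    stop("assay table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0) return(tab[, .assay_cols])
  tab <- tab[, .assay_cols]
  validate_assay_table(tab)
  tab
}

#' @keywords internal
validate_assay_table <- function(tab) {
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0)
      stop("assay table parse error at row(s) ",
           paste(utils::head(idx, 5), collapse = ", "), ": ", what)
  }
  bad(!(tab$role %in% .assay_roles), "unknown role")
  bad(!is.na(tab$enzyme) & !(tab$enzyme %in% sek_enzymes), "unknown enzyme")
  bad(!is.na(tab$temperature_C) &
        !(tab$temperature_C %in% sek_temperatures), "unknown temperature")
  bad(!is.na(tab$depth_cm) & !(tab$depth_cm %in% sek_depths), "unknown depth")
  bad(!is.finite(tab$fluorescence), "non-numeric fluorescence")
  smp <- tab$role == "sample"
  bad(smp & (is.na(tab$replicate) | tab$replicate < 1 | tab$replicate > 4),
      "sample replicate must be 1-4")
  ok_conc <- rep(TRUE, nrow(tab))
  ok_conc[smp] <- mapply(function(e, s) s %in% sek_substrates[[e]],
                         tab$enzyme[smp], tab$substrate_uM[smp])
  bad(!ok_conc, "substrate concentration outside the enzyme's series")
  invisible(tab)
}

#' Read the soil context table
#'
#' @param path CSV with columns `depth_cm, core, dry_matter_fraction,
#'   c_fumigated, c_nonfumigated, doc, tdn` (C/N pools in ug g-1 dry soil).
#' @return validated `data.frame`.
#' @export
read_soil_context <- function(path) {
  ctx <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("depth_cm", "core", "dry_matter_fraction",
            "c_fumigated", "c_nonfumigated", "doc", "tdn")
  missing_cols <- setdiff(need, names(ctx))
  if (length(missing_cols) > 0)
    stop("soil context schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (any(ctx$dry_matter_fraction <= 0 | ctx$dry_matter_fraction > 1))
    stop("dry_matter_fraction must lie in (0, 1]")
  ctx
}

#' Default assay geometry
#'
#' 1 g fresh soil blended in 100 mL buffer; 200 uL homogenate + 50 uL
#' substrate per well.
#' @export
assay_geometry <- function(soil_g_per_ml = 1 / 100,
                           well_homogenate_ml = 0.200,
                           well_substrate_ml = 0.050) {
  list(soil_g_per_ml = soil_g_per_ml,
       well_homogenate_ml = well_homogenate_ml,
       well_substrate_ml = well_substrate_ml)
}

#' Fit a fluorescence standard curve
#'
#' Ordinary least squares of fluorescence on amount of standard in the well.
#'
#' @param amount_nmol nmol of MUF or AMC standard in the well.
#' @param fluorescence measured fluorescence (arbitrary units).
#' @return list with `slope` (fl units per nmol), `intercept`, `r_squared`,
#'   `n`.
#' @export
fit_standard_curve <- function(amount_nmol, fluorescence) {
  if (length(amount_nmol) < 3)
    stop("standard curve needs at least 3 points")
  if (length(unique(amount_nmol)) < 2)
    stop("degenerate standard-curve design: all amounts identical")
  fit <- lm(fluorescence ~ amount_nmol)
  ssr <- sum(resid(fit)^2)
  sst <- sum((fluorescence - mean(fluorescence))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (sst > 0) 1 - ssr / sst else 1,
                 n = length(amount_nmol)),
            class = "standard_curve")
}

#' Quench coefficient from paired standard curves
#'
#' Ratio of the quenched (with soil homogenate) to unquenched standard-curve
#' slopes for the same fluorophore and temperature batch.
#'
#' @param unquenched,quenched objects from [fit_standard_curve()].
#' @return scalar quench coefficient (typically in (0, 1]).
#' @export
quench_coefficient <- function(unquenched, quenched) {
  if (unquenched$slope <= 0)
    stop("invalid unquenched standard curve: slope must be > 0")
  quenched$slope / unquenched$slope
}

#' Net fluorescence of a sample well
#'
#' `(raw - homogenate_blank) / quench - substrate_blank`. Vectorised.
#'
#' @param raw raw fluorescence of the sample well.
#' @param homogenate_blank fluorescence of homogenate-only wells.
#' @param substrate_blank fluorescence of substrate-only wells at the same
#'   concentration (measured without homogenate, hence not quenched).
#' @param quench quench coefficient (> 0).
#' @export
net_fluorescence <- function(raw, homogenate_blank, substrate_blank, quench) {
  if (any(quench <= 0)) stop("invalid quench coefficient: must be > 0")
  (raw - homogenate_blank) / quench - substrate_blank
}

#' Activity rate per gram dry soil
#'
#' Converts a net fluorescence to nmol substrate cleaved per gram dry soil
#' per hour, using the unquenched emission coefficient and the mass of dry
#' soil dispensed into the well.
#'
#' @param net net fluorescence (see [net_fluorescence()]); negative values
#'   pass through and are handled by downstream QC.
#' @param emission_coef fluorescence units per nmol standard in the well
#'   (unquenched standard-curve slope).
#' @param dry_matter_fraction g dry soil per g fresh soil.
#' @param incubation_h incubation time in hours.
#' @param geometry assay geometry, see [assay_geometry()].
#' @return rate in nmol g-1 (dry soil) h-1.
#' @export
activity_rate <- function(net, emission_coef, dry_matter_fraction,
                          incubation_h, geometry = assay_geometry()) {
  if (any(incubation_h <= 0)) stop("incubation time must be > 0")
  if (any(emission_coef <= 0)) stop("emission coefficient must be > 0")
  nmol <- net / emission_coef
  dry_g <- geometry$soil_g_per_ml * geometry$well_homogenate_ml *
    dry_matter_fraction
  nmol / (dry_g * incubation_h)
}

#' Per-batch reduction coefficients
#'
#' Computes, for one temperature batch (and one fluorophore / timepoint),
#' the emission coefficient from the unquenched standards, the per-depth
#' quench coefficients from the quenched standards, homogenate blanks per
#' depth x core, and substrate blanks per concentration.
#'
#' @param batch rows of an assay table belonging to one
#'   enzyme x temperature x timepoint batch (controls only are used).
#' @return list with `emission_coef`, `quench` (named by depth),
#'   `homogenate_blank` (data.frame), `substrate_blank` (data.frame).
#' @export
batch_coefficients <- function(batch) {
  std <- batch[batch$role == "standard", ]
  if (nrow(std) < 3) stop("batch has no usable unquenched standards")
  unq <- fit_standard_curve(std$standard_nmol, std$fluorescence)
  qst <- batch[batch$role == "quench_standard", ]
  quench <- vapply(split(qst, qst$depth_cm), function(d) {
    quench_coefficient(unq, fit_standard_curve(d$standard_nmol,
                                               d$fluorescence))
  }, numeric(1))
  hb <- batch[batch$role == "homogenate_blank", ]
  hb_tab <- aggregate(fluorescence ~ depth_cm + core, hb, mean)
  sb <- batch[batch$role == "substrate_blank", ]
  sb_tab <- aggregate(fluorescence ~ substrate_uM, sb, mean)
  list(emission_coef = unq$slope, quench = quench,
       homogenate_blank = hb_tab, substrate_blank = sb_tab)
}

#' Reduce an assay table to activity rates
#'
#' Applies, per enzyme x temperature x timepoint batch, the quench-corrected
#' net-fluorescence reduction and the dry-soil-mass conversion to every
#' sample well.
#'
#' @param assay validated assay table (see [read_assay_table()]).
#' @param soil soil context table (see [read_soil_context()]).
#' @param geometry assay geometry.
#' @return data.frame of sample wells with a `rate_nmol_g_h` column.
#' @export
reduce_rates <- function(assay, soil, geometry = assay_geometry()) {
  smp <- assay[assay$role == "sample", ]
  if (nrow(smp) == 0) {
    smp$rate_nmol_g_h <- numeric(0)
    return(smp)
  }
  key <- interaction(assay$enzyme, assay$temperature_C, assay$timepoint_h,
                     drop = TRUE)
  out <- lapply(split(assay, key), function(batch) {
    cf <- batch_coefficients(batch)
    sw <- batch[batch$role == "sample", ]
    if (nrow(sw) == 0) return(NULL)
    hb_key <- paste(cf$homogenate_blank$depth_cm, cf$homogenate_blank$core)
    hb <- cf$homogenate_blank$fluorescence[
      match(paste(sw$depth_cm, sw$core), hb_key)]
    sb <- cf$substrate_blank$fluorescence[
      match(sw$substrate_uM, cf$substrate_blank$substrate_uM)]
    qc <- cf$quench[as.character(sw$depth_cm)]
    if (anyNA(hb) || anyNA(sb) || anyNA(qc))
      stop("batch is missing blank or quench controls for some sample wells")
    dmf <- soil$dry_matter_fraction[
      match(paste(sw$depth_cm, sw$core), paste(soil$depth_cm, soil$core))]
    if (anyNA(dmf))
      stop("soil context missing for some depth x core combinations")
    net <- net_fluorescence(sw$fluorescence, hb, sb, qc)
    sw$rate_nmol_g_h <- activity_rate(net, cf$emission_coef, dmf,
                                      sw$timepoint_h, geometry)
    sw
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
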
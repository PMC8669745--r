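## Synthetic fluorometric campaign generator.
##
## Generates a ground-truth trait profile (depth-decaying Vmax and Km,
## per-enzyme MMRT temperature response, depth-decaying microbial biomass
## and C/N pools, depth-dependent quenching) and simulates every well of
## the full factorial assay campaign -- samples, standards, quench
## standards, and blanks -- with heteroscedastic lognormal fluorescence
## noise, rare injected negative readings, and occasional single-replicate
## outliers, so that each pipeline stage can be tested against known truth.

#' Campaign configuration
#'
#' Defaults reproduce the full factorial assay design: 3 enzymes x 6 depth
#' intervals x 6 temperatures x 8 substrate concentrations x 4 analytical
#' replicates x 3 cores x 3 incubation timepoints.
#'
#' @param enzymes,depths,temperatures,timepoints factor levels.
#' @param substrates list of concentration series (uM) per enzyme.
#' @param replicates analytical replicates per well condition.
#' @param cores replicate soil cores.
#' @param cv_well proportional (lognormal) fluorescence noise CV.
#' @param p_negative probability a well reading is corrupted below blank
#'   (producing a negative net value).
#' @param p_outlier probability a single replicate is an outlier.
#' @param outlier_factor multiplicative magnitude of injected outliers.
#' @param extract_cv proportional noise CV on soil extraction measurements.
#' @export
campaign_config <- function(enzymes = sek_enzymes, depths = sek_depths,
                            temperatures = sek_temperatures,
                            substrates = sek_substrates,
                            replicates = 4, cores = 3,
                            timepoints = sek_timepoints,
                            cv_well = 0.10, p_negative = 0.008,
                            p_outlier = 0.03, outlier_factor = 3,
                            extract_cv = 0.05) {
  list(enzymes = enzymes, depths = depths, temperatures = temperatures,
       substrates = substrates, replicates = replicates, cores = cores,
       timepoints = timepoints, cv_well = cv_well,
       p_negative = p_negative, p_outlier = p_outlier,
       outlier_factor = outlier_factor, extract_cv = extract_cv)
}

#' Ground-truth trait profile
#'
#' Encodes the depth patterns the pipeline must recover: Vmax/ds decays
#' exponentially with depth midpoint z as `Vmax0 * exp(-z / 22.6 cm)`
#' (a ~96%-class decline by the deepest intervals), Km decays to ~15% of
#' its surface value by ~30 cm and then plateaus, microbial biomass C
#' decays steepest over the upper 30 cm, and each enzyme has an MMRT
#' temperature response with Topt ~ 338 K. Surface magnitudes follow the
#' field ordering AP > BG > LAP for Vmax and LAP > AP > BG for Km.
#'
#' @param config from [campaign_config()].
#' @param seed integer seed (truth generation is deterministic given it).
#' @param vmax_zstar e-folding depth (cm) of the Vmax decline.
#' @return list of class `truth_profile`.
#' @export
make_truth <- function(config = campaign_config(), seed = 1,
                       vmax_zstar = 22.6) {
  if (vmax_zstar <= 0) stop("config error: decay scale must be > 0")
  set.seed(seed)
  z <- sek_depth_mid[config$depths]
  vmax_surf <- c(BG = 400, LAP = 150, AP = 1200)   # nmol g-1 h-1 at 25 C
  km_surf <- c(BG = 80, LAP = 200, AP = 150)       # uM
  kin <- do.call(rbind, lapply(config$enzymes, function(e) {
    data.frame(enzyme = e, depth_cm = config$depths, z = unname(z),
               vmax_ref = vmax_surf[[e]] * exp(-z / vmax_zstar),
               km = km_surf[[e]] * (0.15 + 0.85 * exp(-z / 12)),
               row.names = NULL)
  }))
  ## MMRT shape per enzyme: dH chosen so Topt = 338.05 K; dS normalised so
  ## the curve equals 1 at the 25 C reference (vmax_ref carries magnitude)
  dcp <- c(BG = -790, LAP = -1320, AP = -790)      # J mol-1 K-1
  topt_target <- 338.05
  mmrt <- do.call(rbind, lapply(config$enzymes, function(e) {
    dH <- dcp[[e]] * 315 - topt_target * (dcp[[e]] + .R_GAS)
    ln_ref <- mmrt_lnrate(25 + .C_TO_K, dH, 0, dcp[[e]], T0 = 315)
    data.frame(enzyme = e, dCp = dcp[[e]], dH = dH,
               dS = -.R_GAS * ln_ref, T0 = 315, row.names = NULL)
  }))
  soil <- data.frame(
    depth_cm = config$depths, z = unname(z),
    mbc = 900 * exp(-z / 12) + 30,          # ug C g-1, steepest upper 30 cm
    doc = 250 * exp(-z / 20) + 20,
    tdn = 20 * exp(-z / 20) + 2,
    c_nonfumigated = 60 * exp(-z / 25) + 12,
    dry_matter_fraction = 0.55 + 0.35 * (1 - exp(-z / 30)),
    quench = 0.6 + 0.3 * (z - z[1]) / (z[length(z)] - z[1]),
    homogenate_blank = 80 * exp(-z / 40) + 20,
    row.names = NULL)
  emission <- c(MUF = 450, AMC = 300)       # fl units per nmol in well
  structure(list(kinetics = kin, mmrt = mmrt, soil = soil,
                 emission = emission, seed = seed,
                 vmax_zstar = vmax_zstar, config = config),
            class = "truth_profile")
}

## MMRT-scaled Vmax at temperature T (deg C) for one enzyme x depth
.truth_vmax <- function(truth, enzyme, depth, temperature_C) {
  k <- truth$kinetics
  m <- truth$mmrt[truth$mmrt$enzyme == enzyme, ]
  vref <- k$vmax_ref[k$enzyme == enzyme & k$depth_cm == depth]
  vref * exp(mmrt_lnrate(temperature_C + .C_TO_K, m$dH, m$dS, m$dCp, m$T0))
}

## apparent-rate multiplier vs nominal incubation time: cold assays build
## signal sub-linearly early (equilibration), warm assays saturate after
## ~4 h (substrate depletion / fluorophore loss), so incubation-time
## selection has real work to do
.time_multiplier <- function(timepoint_h, temperature_C) {
  if (temperature_C >= 25) {
    c(`1` = 0.9, `4` = 1, `24` = 4 / 24)[as.character(timepoint_h)]
  } else {
    c(`1` = 0.7, `4` = 0.9, `24` = 1)[as.character(timepoint_h)]
  }
}

## standard series (nmol in a 0.25 mL well) per fluorophore: six levels
## spanning 0.625-20 uM (MUF) and 0.3125-10 uM (AMC)
.standard_series <- function(type) {
  conc <- if (type == "MUF") 20 / 2^(0:5) else 10 / 2^(0:5)
  conc * 0.25
}

#' Simulate one assay plate
#'
#' Sample wells plus the matching standards, quench standards and blank
#' controls for one enzyme x depth x core x temperature x timepoint batch.
#' Fluorescence is built by inverting the reduction arithmetic: expected
#' rate `v(S, T) = Vmax(T) * S / (Km + S)`, times incubation and dry soil
#' mass in the well, times the emission and quench coefficients, plus
#' blanks and multiplicative lognormal noise.
#'
#' @param truth from [make_truth()].
#' @param config from [campaign_config()].
#' @param enzyme,depth,core,temperature,timepoint plate coordinates.
#' @param with_controls which control rows to emit alongside the sample
#'   wells: homogenate blanks belong to each depth x core plate
#'   (`"plate"`), quench standards to each depth within a batch
#'   (`"depth"`), and the unquenched standards and substrate blanks once
#'   per enzyme x temperature x timepoint batch (`"batch"`). Each level
#'   includes the previous ones; `"none"` emits sample wells only.
#' @return data.frame of assay-table rows.
#' @export
simulate_plate <- function(truth, config, enzyme, depth, core,
                           temperature, timepoint,
                           with_controls = c("batch", "depth", "plate",
                                             "none")) {
  with_controls <- match.arg(with_controls)
  s <- truth$soil[truth$soil$depth_cm == depth, ]
  type <- sek_standard_type[[enzyme]]
  emis <- truth$emission[[type]]
  k <- truth$kinetics
  km <- k$km[k$enzyme == enzyme & k$depth_cm == depth]
  vT <- .truth_vmax(truth, enzyme, depth, temperature) *
    .time_multiplier(timepoint, temperature)
  geom <- assay_geometry()
  dry_g <- geom$soil_g_per_ml * geom$well_homogenate_ml *
    s$dry_matter_fraction
  conc <- config$substrates[[enzyme]]
  grid <- expand.grid(substrate_uM = conc,
                      replicate = seq_len(config$replicates))
  v <- vT * grid$substrate_uM / (km + grid$substrate_uM)
  sb_true <- 0.5 + 0.01 * grid$substrate_uM       # substrate autofluorescence
  nmol <- v * dry_g * timepoint
  raw <- ((nmol * emis + sb_true) * s$quench) + s$homogenate_blank
  noise <- function(x, cv) {
    if (cv <= 0) return(x)
    x * rlnorm(length(x), -0.5 * log(1 + cv^2), sqrt(log(1 + cv^2)))
  }
  signal <- raw - s$homogenate_blank
  signal <- noise(signal, config$cv_well)
  out_hit <- runif(nrow(grid)) < config$p_outlier
  signal[out_hit] <- signal[out_hit] *
    (1 + config$outlier_factor * runif(sum(out_hit), 0.5, 1))
  raw <- signal + s$homogenate_blank
  neg_hit <- runif(nrow(grid)) < config$p_negative
  raw[neg_hit] <- s$homogenate_blank - runif(sum(neg_hit), 5, 50)
  wells <- data.frame(enzyme = enzyme, depth_cm = depth, core = core,
                      temperature_C = temperature,
                      substrate_uM = grid$substrate_uM,
                      replicate = grid$replicate,
                      timepoint_h = timepoint, role = "sample",
                      fluorescence = raw, standard_nmol = NA_real_)
  if (with_controls == "none") return(wells)

  std_nmol <- rep(.standard_series(type), each = 2)   # duplicates
  ctrl <- data.frame(enzyme = enzyme, depth_cm = depth, core = core,
                     temperature_C = temperature, substrate_uM = NA,
                     replicate = NA, timepoint_h = timepoint,
                     role = "homogenate_blank",
                     fluorescence = rep(s$homogenate_blank, 2),
                     standard_nmol = NA_real_)
  if (with_controls %in% c("depth", "batch")) {
    ctrl <- rbind(ctrl, data.frame(
      enzyme = enzyme, depth_cm = depth, core = NA,
      temperature_C = temperature, substrate_uM = NA,
      replicate = NA, timepoint_h = timepoint, role = "quench_standard",
      fluorescence = s$homogenate_blank +
        noise(s$quench * emis * std_nmol, config$cv_well / 4),
      standard_nmol = std_nmol))
  }
  if (with_controls == "batch") {
    ctrl <- rbind(
      ctrl,
      data.frame(enzyme = enzyme, depth_cm = NA, core = NA,
                 temperature_C = temperature, substrate_uM = NA,
                 replicate = NA, timepoint_h = timepoint,
                 role = "standard",
                 fluorescence = noise(emis * std_nmol, config$cv_well / 4),
                 standard_nmol = std_nmol),
      data.frame(enzyme = enzyme, depth_cm = NA, core = NA,
                 temperature_C = temperature, substrate_uM = conc,
                 replicate = NA, timepoint_h = timepoint,
                 role = "substrate_blank",
                 fluorescence = 0.5 + 0.01 * conc,
                 standard_nmol = NA_real_))
  }
  rbind(wells, ctrl)
}

#' Simulate a full assay campaign
#'
#' Loops [simulate_plate()] over the whole factorial design, draws the soil
#' context (fumigation extracts with proportional extraction noise), and
#' optionally writes `assay.csv`, `soil.csv`, `truth.json` and
#' `manifest.json` to a directory. Identical seeds produce identical
#' output.
#'
#' @param config from [campaign_config()].
#' @param seed integer seed for all randomness.
#' @param dir optional output directory.
#' @return (invisibly) list with `assay`, `soil`, `truth`, `manifest`.
#' @export
simulate_campaign <- function(config = campaign_config(), seed = 1,
                              dir = NULL) {
  truth <- make_truth(config, seed = seed)
  set.seed(seed + 1)
  ## soil context per depth x core
  soil <- do.call(rbind, lapply(seq_len(config$cores), function(core) {
    s <- truth$soil
    n <- nrow(s)
    rn <- function(x) x * rlnorm(n, 0, config$extract_cv)
    data.frame(depth_cm = s$depth_cm, core = core,
               dry_matter_fraction = s$dry_matter_fraction,
               c_fumigated = rn(s$c_nonfumigated + s$mbc),
               c_nonfumigated = rn(s$c_nonfumigated),
               doc = rn(s$doc), tdn = rn(s$tdn), row.names = NULL)
  }))
  design <- expand.grid(enzyme = config$enzymes, depth = config$depths,
                        core = seq_len(config$cores),
                        temperature = config$temperatures,
                        timepoint = config$timepoints,
                        stringsAsFactors = FALSE)
  ## homogenate blanks per plate; quench standards once per depth in each
  ## batch; unquenched standards + substrate blanks once per batch
  ctl_level <- ifelse(design$core != 1, "plate",
                      ifelse(design$depth == config$depths[1],
                             "batch", "depth"))
  plates <- lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    simulate_plate(truth, config, d$enzyme, d$depth, d$core, d$temperature,
                   d$timepoint, with_controls = ctl_level[i])
  })
  assay <- do.call(rbind, plates)
  rownames(assay) <- NULL
  n_sample <- sum(assay$role == "sample")
  manifest <- list(
    n_sample_wells = n_sample,
    n_fit_units = length(config$enzymes) * length(config$depths) *
      config$cores * length(config$temperatures),
    n_timepoints = length(config$timepoints),
    wells_per_fit_unit = length(config$substrates[[1]]) *
      config$replicates,
    seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(assay, file.path(dir, "assay.csv"), row.names = FALSE)
    write.csv(soil, file.path(dir, "soil.csv"), row.names = FALSE)
    jsonlite::write_json(truth_to_list(truth),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(assay = assay, soil = soil, truth = truth,
                 manifest = manifest))
}

#' Serialise / restore a truth profile
#' @param truth a `truth_profile`.
#' @export
truth_to_list <- function(truth) {
  list(kinetics = truth$kinetics, mmrt = truth$mmrt, soil = truth$soil,
       emission = as.list(truth$emission), seed = truth$seed,
       vmax_zstar = truth$vmax_zstar)
}

#' @param path path to a `truth.json` written by [simulate_campaign()].
#' @rdname truth_to_list
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(kinetics = x$kinetics, mmrt = x$mmrt, soil = x$soil,
                 emission = unlist(x$emission), seed = x$seed,
                 vmax_zstar = x$vmax_zstar),
            class = "truth_profile")
}
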
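#' Scenario configuration for the plate simulator
#'
#' Describes a synthetic extracellular-flux experiment: per-channel baseline
#' rates and noise, per-group and per-phase response multipliers, the
#' injection sequence, plate layout (biological repeats x technical wells)
#' and per-well protein content. [simulate_plate()] turns it into a
#' [plate_record()] whose ground truth is known exactly.
#'
#' The generating model for a measurement at time `t` in phase `p` of group
#' `g` on channel `c` is
#' `value = baseline_c x multiplier_{g,c,p} x (1 + drift x t) + N(0, noise_sd_c)`,
#' clipped at zero (rates are nonnegative).
#'
#' @param channels Named list (`OCR`, `ECAR`, ...); each element a list with
#'   `baseline` (rate) and `noise_sd` (rate, Gaussian SD).
#' @param groups Named list: group -> named list: channel -> named numeric
#'   vector of multipliers over `c("baseline", injections)`.
#' @param injections Character vector of injection event names, in order.
#' @param wells_per_group Technical wells per group within one experiment.
#' @param experiments Number of biological repeats (independent experiments).
#' @param protein_mean,protein_sd Per-well protein content (ug), drawn once
#'   per well.
#' @param measurements_per_phase Measurements in each phase.
#' @param interval_min Minutes between measurements.
#' @param drift_per_min Fractional linear drift per minute (default 0).
#' @param seed Integer seed; identical seeds give identical plates.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(channels, groups, injections = character(),
                            wells_per_group = 2L, experiments = 3L,
                            protein_mean = 10, protein_sd = 1,
                            measurements_per_phase = 3L, interval_min = 6.5,
                            drift_per_min = 0, seed = 1L) {
  stopifnot(wells_per_group >= 1L, experiments >= 1L,
            measurements_per_phase >= 1L, protein_mean > 0, protein_sd >= 0,
            interval_min > 0)
  phases <- c("baseline", injections)
  for (ch in names(channels)) {
    stopifnot(channels[[ch]]$baseline > 0, channels[[ch]]$noise_sd >= 0)
  }
  for (g in names(groups)) for (ch in names(groups[[g]])) {
    m <- groups[[g]][[ch]]
    if (!all(phases %in% names(m)))
      stop("scenario_config: group '", g, "' channel '", ch,
           "' must name multipliers for all phases: ",
           paste(phases, collapse = ", "))
    if (any(m <= 0))
      stop("scenario_config: multipliers must be positive")
  }
  structure(list(channels = channels, groups = groups,
                 injections = injections,
                 wells_per_group = as.integer(wells_per_group),
                 experiments = as.integer(experiments),
                 protein_mean = protein_mean, protein_sd = protein_sd,
                 measurements_per_phase = as.integer(measurements_per_phase),
                 interval_min = interval_min, drift_per_min = drift_per_min,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# flat multiplier vector helper
flat_mult <- function(injections, ...) {
  m <- c(baseline = 1, ...)
  missing <- setdiff(c("baseline", injections), names(m))
  m <- c(m, stats::setNames(rep(1, length(missing)), missing))
  m[c("baseline", injections)]
}

#' Packaged simulation scenarios
#'
#' Named scenario presets anchored to the study conditions they emulate.
#' `lps_acute` encodes the acute TLR4 response: a single mid-run LPS
#' injection raising ECAR 1.5-fold over resting controls with a modest OCR
#' decrease, 3 biological repeats of 2 technical wells, measurement noise 5%
#' of baseline. `polyic` raises aerobic (OCR) metabolism. `il33_treatment`,
#' `il33_kd` and `il33_oe` are mitochondrial stress-test scenarios in which
#' the perturbed group has raised (treatment, overexpression) or reduced
#' (knockdown) FCCP-phase maximal respiration; their `assay = "glyco"`
#' variants raise the glucose-phase ECAR response where glycolysis is
#' increased. `control` is the flat reference scenario (all multipliers 1).
#'
#' @param name One of `control`, `lps_acute`, `polyic`, `il33_treatment`,
#'   `il33_kd`, `il33_oe`.
#' @param assay `"mito"`, `"glyco"` or `"acute"`; default chosen per preset.
#' @param seed Integer seed stored in the config.
#' @return A [scenario_config()].
#' @export
xf_preset <- function(name = c("control", "lps_acute", "polyic",
                               "il33_treatment", "il33_kd", "il33_oe"),
                      assay = NULL, seed = 1L) {
  name <- match.arg(name)
  channels <- list(OCR = list(baseline = 100, noise_sd = 5),
                   ECAR = list(baseline = 20, noise_sd = 1))
  mito_inj <- c("oligomycin", "fccp", "rot_aa")
  glyco_inj <- c("glucose", "oligomycin", "2dg")
  # typical stress-test response profile of healthy RPE cells
  ocr_mito <- function(fccp = 1.6)
    flat_mult(mito_inj, oligomycin = 0.35, fccp = fccp, rot_aa = 0.15)
  ecar_glyco <- function(glucose = 2.5)
    flat_mult(glyco_inj, glucose = glucose, oligomycin = 3.5, `2dg` = 0.6)

  if (is.null(assay))
    assay <- switch(name, lps_acute = , polyic = "acute", "mito")

  if (name == "control") {
    inj <- switch(assay, acute = "vehicle", mito = mito_inj, glyco = glyco_inj)
    groups <- list(control = list(OCR = flat_mult(inj),
                                  ECAR = flat_mult(inj)))
    return(scenario_config(channels, groups, inj, seed = seed))
  }
  if (name %in% c("lps_acute", "polyic")) {
    inj <- if (name == "lps_acute") "lps" else "polyic"
    treated <- if (name == "lps_acute")
      list(OCR = flat_mult(inj, lps = 0.8),
           ECAR = flat_mult(inj, lps = 1.5))
    else
      list(OCR = flat_mult(inj, polyic = 1.3),
           ECAR = flat_mult(inj, polyic = 1.15))
    groups <- stats::setNames(
      list(list(OCR = flat_mult(inj), ECAR = flat_mult(inj)), treated),
      c("control", name))
    return(scenario_config(channels, groups, inj, seed = seed))
  }
  # IL-33 perturbation scenarios: reference group + perturbed group
  ref <- if (name == "il33_kd") "scramble" else "control"
  if (assay == "mito") {
    fccp_alt <- switch(name, il33_treatment = 2.0, il33_oe = 2.0,
                       il33_kd = 0.9)
    groups <- stats::setNames(
      list(list(OCR = ocr_mito(), ECAR = flat_mult(mito_inj)),
           list(OCR = ocr_mito(fccp_alt), ECAR = flat_mult(mito_inj))),
      c(ref, name))
    return(scenario_config(channels, groups, mito_inj, seed = seed))
  }
  glc_alt <- switch(name, il33_treatment = 3.0, il33_oe = 3.0, il33_kd = 3.2)
  groups <- stats::setNames(
    list(list(OCR = flat_mult(glyco_inj), ECAR = ecar_glyco()),
         list(OCR = flat_mult(glyco_inj), ECAR = ecar_glyco(glc_alt))),
    c(ref, name))
  scenario_config(channels, groups, glyco_inj, seed = seed)
}

#' Simulate a plate from a scenario
#'
#' Draws a full [plate_record()] under the scenario's generating model:
#' piecewise-constant phase plateaus (baseline x multiplier), optional linear
#' drift, additive Gaussian measurement noise clipped at zero, and per-well
#' protein content. Identical seeds give identical plates.
#'
#' @param config A [scenario_config()].
#' @param seed Optional override of `config$seed`.
#' @return A [plate_record()] with unsegmented OCR and ECAR traces; the
#'   schedule places each injection after `measurements_per_phase`
#'   measurements of the preceding phase.
#' @export
simulate_plate <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed %||% config$seed)
  mpp <- config$measurements_per_phase
  n_phase <- length(config$injections) + 1L
  n_meas <- mpp * n_phase
  idx <- seq_len(n_meas)
  time <- (idx - 1L) * config$interval_min
  phase_of <- rep(c("baseline", config$injections), each = mpp)
  schedule <- injection_schedule(config$injections,
                                 after_measurement = mpp * seq_along(config$injections))

  traces <- list()
  protein <- numeric(0)
  for (e in seq_len(config$experiments)) {
    for (g in names(config$groups)) {
      for (w in seq_len(config$wells_per_group)) {
        well <- sprintf("E%d_%s_%d", e, g, w)
        protein[well] <- max(stats::rnorm(1, config$protein_mean,
                                          config$protein_sd), 0.1)
        for (ch in names(config$channels)) {
          base <- config$channels[[ch]]$baseline
          sd <- config$channels[[ch]]$noise_sd
          mult <- config$groups[[g]][[ch]][phase_of]
          mu <- base * mult * (1 + config$drift_per_min * time)
          val <- pmax(mu + stats::rnorm(n_meas, 0, sd), 0)
          traces[[length(traces) + 1L]] <-
            flux_trace(well, g, ch, idx, time, val,
                       experiment = sprintf("E%d", e))
        }
      }
    }
  }
  plate_record(traces, protein, schedule,
               meta = list(scenario = config))
}

#' Write / read a plate as CSV plus YAML sidecar
#'
#' The CSV is a wide plate export with columns `Measurement`, `Well`,
#' `Group`, `Experiment`, `Time_min` and one column per channel (`OCR`,
#' `ECAR`). The sidecar holds the injection schedule and per-well protein
#' content.
#'
#' @param plate A [plate_record()].
#' @param csv_path,config_path Output file paths.
#' @name plate_io
#' @export
write_plate <- function(plate, csv_path, config_path) {
  stopifnot(inherits(plate, "plate_record"))
  long <- do.call(rbind, lapply(plate$traces, function(tr) {
    data.frame(Measurement = tr$data$index, Well = tr$well_id,
               Group = tr$group, Experiment = tr$experiment,
               Time_min = tr$data$time, channel = tr$channel,
               value = tr$data$value, stringsAsFactors = FALSE)
  }))
  wide <- stats::reshape(long, direction = "wide", timevar = "channel",
                         idvar = c("Measurement", "Well", "Group",
                                   "Experiment", "Time_min"))
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[order(wide$Well, wide$Measurement), ]
  utils::write.csv(wide, csv_path, row.names = FALSE)
  yaml::write_yaml(
    list(events = lapply(seq_len(nrow(plate$schedule)), function(i)
           list(name = plate$schedule$name[i],
                compound = plate$schedule$compound[i],
                after_measurement = plate$schedule$after_measurement[i])),
         protein_ug = as.list(plate$protein_ug)),
    config_path)
  invisible(c(csv_path, config_path))
}

#' @rdname plate_io
#' @return `read_plate()` returns a [plate_record()].
#' @export
read_plate <- function(csv_path, config_path) {
  wide <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  side <- yaml::read_yaml(config_path)
  schedule <- injection_schedule(
    vapply(side$events, `[[`, character(1), "name"),
    vapply(side$events, function(e) e$compound %||% e$name, character(1)),
    vapply(side$events, function(e) as.integer(e$after_measurement),
           integer(1)))
  protein <- unlist(side$protein_ug)
  channels <- intersect(c("OCR", "ECAR", "PER"), names(wide))
  if (!length(channels))
    stop("read_plate: no OCR/ECAR/PER column in ", csv_path)
  if (!"Experiment" %in% names(wide)) wide$Experiment <- "E1"
  traces <- list()
  for (well in unique(wide$Well)) {
    sub <- wide[wide$Well == well, ]
    sub <- sub[order(sub$Measurement), ]
    for (ch in channels) {
      if (all(is.na(sub[[ch]]))) next
      traces[[length(traces) + 1L]] <-
        flux_trace(well, sub$Group[1], ch, sub$Measurement, sub$Time_min,
                   sub[[ch]], experiment = sub$Experiment[1])
    }
  }
  plate_record(traces, protein, schedule)
}
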
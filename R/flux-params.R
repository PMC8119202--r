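#' Mitochondrial stress-test parameters
#'
#' Decomposes a segmented OCR trace from the oligomycin / FCCP /
#' rotenone+antimycin A protocol into the standard respiration parameters:
#' \describe{
#'   \item{nonmito_respiration}{minimum OCR in the rotenone/antimycin A phase
#'     (the extremal-measurement convention for inhibitor phases).}
#'   \item{basal_respiration}{last baseline OCR (before oligomycin) minus
#'     nonmitochondrial respiration.}
#'   \item{proton_leak}{minimum OCR after oligomycin minus nonmitochondrial
#'     respiration.}
#'   \item{atp_production}{basal respiration minus proton leak.}
#'   \item{maximal_respiration}{maximum OCR after FCCP minus nonmitochondrial
#'     respiration.}
#'   \item{spare_respiratory_capacity_pct}{100 x maximal / basal; flagged
#'     undefined when basal <= 0.}
#'   \item{ocr_ecar_ratio}{first OCR measurement over first ECAR
#'     measurement.}
#' }
#'
#' @param ocr A [flux_trace()] (channel OCR) segmented over phases
#'   `baseline`, `oligomycin`, `fccp`, `rot_aa`.
#' @param ecar_first First ECAR measurement of the same well (for the
#'   OCR/ECAR ratio); `NA` to skip.
#' @param phases Optional renaming of the four expected phase labels.
#' @return A list of class `"mito_stress_params"`.
#' @export
mito_stress_params <- function(ocr, ecar_first = NA_real_,
                               phases = c(baseline = "baseline",
                                          oligomycin = "oligomycin",
                                          fccp = "fccp",
                                          rot_aa = "rot_aa")) {
  stopifnot(inherits(ocr, "flux_trace"))
  base  <- phase_values(ocr, phases[["baseline"]])
  oligo <- phase_values(ocr, phases[["oligomycin"]])
  fccp  <- phase_values(ocr, phases[["fccp"]])
  rotaa <- phase_values(ocr, phases[["rot_aa"]])

  nonmito <- min(rotaa)
  basal   <- base[length(base)] - nonmito
  leak    <- min(oligo) - nonmito
  atp     <- basal - leak
  maximal <- max(fccp) - nonmito
  spare <- if (basal > 0) 100 * maximal / basal else
    flagged("undefined: basal respiration <= 0")
  ratio <- if (is.na(ecar_first)) NA_real_ else if (ecar_first != 0)
    ocr$data$value[1] / ecar_first else
    flagged("undefined: first ECAR measurement is 0")

  structure(list(nonmito_respiration = nonmito,
                 basal_respiration = basal,
                 proton_leak = leak,
                 atp_production = atp,
                 maximal_respiration = maximal,
                 spare_respiratory_capacity_pct = spare,
                 ocr_ecar_ratio = ratio),
            class = "mito_stress_params")
}

#' Glycolysis stress-test parameters
#'
#' Decomposes a segmented ECAR trace from the glucose / oligomycin /
#' 2-deoxyglucose protocol: nonglycolytic acidification (last ECAR before
#' glucose), glycolysis (max ECAR before oligomycin minus nonglycolytic),
#' glycolytic capacity (max ECAR after oligomycin minus nonglycolytic) and
#' glycolytic reserve (capacity minus glycolysis, a signed difference).
#'
#' @param ecar A segmented [flux_trace()] with phases `baseline`, `glucose`,
#'   `oligomycin`, `2dg`.
#' @param phases Optional phase-label renaming.
#' @return A list of class `"glyco_stress_params"`.
#' @export
glyco_stress_params <- function(ecar,
                                phases = c(baseline = "baseline",
                                           glucose = "glucose",
                                           oligomycin = "oligomycin",
                                           dg2 = "2dg")) {
  stopifnot(inherits(ecar, "flux_trace"))
  base  <- phase_values(ecar, phases[["baseline"]])
  glc   <- phase_values(ecar, phases[["glucose"]])
  oligo <- phase_values(ecar, phases[["oligomycin"]])
  phase_values(ecar, phases[["dg2"]])  # protocol completeness check only

  nonglyco <- base[length(base)]
  glycolysis <- max(glc) - nonglyco
  capacity <- max(oligo) - nonglyco
  structure(list(nonglycolytic_acidification = nonglyco,
                 glycolysis = glycolysis,
                 glycolytic_capacity = capacity,
                 glycolytic_reserve = capacity - glycolysis),
            class = "glyco_stress_params")
}

#' Proton-efflux conversion constants
#'
#' ECAR (mpH/min) is converted to a proton efflux rate
#' PER (pmol H+/min) as `PER = ECAR x buffer_factor x chamber_volume x
#' volume_scaling`, and the glycolytic component as
#' `glycoPER = PER - ccf x OCR` where `ccf` is the CO2 contribution factor.
#' All four constants are configurable; `neutral_per_constants()` (scale 1,
#' ccf 0) makes glycoPER coincide with ECAR, which is convenient for unit
#' checks that should not depend on vendor calibration values.
#'
#' @param buffer_factor mmol H+/L/pH of the assay medium.
#' @param chamber_volume Effective measurement chamber volume (uL).
#' @param volume_scaling Dimensionless geometry scaling.
#' @param ccf CO2 contribution factor (pmol H+/pmol O2).
#' @return A list of class `"per_constants"`.
#' @export
per_constants <- function(buffer_factor = 2.6, chamber_volume = 2.28,
                          volume_scaling = 1.6, ccf = 0.61) {
  stopifnot(buffer_factor > 0, chamber_volume > 0, volume_scaling > 0,
            ccf >= 0)
  structure(list(buffer_factor = buffer_factor,
                 chamber_volume = chamber_volume,
                 volume_scaling = volume_scaling, ccf = ccf),
            class = "per_constants")
}

#' @rdname per_constants
#' @export
neutral_per_constants <- function() {
  per_constants(buffer_factor = 1, chamber_volume = 1, volume_scaling = 1,
                ccf = 0)
}

#' Glycolytic rate parameters from paired OCR/ECAR traces
#'
#' Runs the glycolytic-rate protocol arithmetic on a well's paired traces,
#' both segmented over phases `baseline`, `rot_aa`, `2dg`:
#' basal glycolysis (last glycoPER before rotenone/antimycin A), compensatory
#' glycolysis (maximum glycoPER after rotenone/antimycin A),
#' mitoOCR/glycoPER ((last OCR before rot/AA minus minimum OCR after rot/AA)
#' / basal glycolysis) and percentage PER from glycolysis
#' (100 x basal glycolysis / basal PER).
#'
#' @param ocr,ecar Segmented [flux_trace()] objects of the same well sharing
#'   the schedule (matched measurement indices).
#' @param constants A [per_constants()] object.
#' @return A list of class `"glyco_rate_params"` including the derived
#'   `basal_per`.
#' @export
glyco_rate_params <- function(ocr, ecar, constants = per_constants()) {
  stopifnot(inherits(ocr, "flux_trace"), inherits(ecar, "flux_trace"),
            inherits(constants, "per_constants"))
  if (!identical(ecar$data$index, ocr$data$index) ||
      !identical(ecar$data$phase, ocr$data$phase))
    stop("glyco_rate_params: OCR and ECAR traces must share measurement ",
         "indices and phases (well '", ecar$well_id, "')")
  scale <- constants$buffer_factor * constants$chamber_volume *
    constants$volume_scaling
  per <- ecar$data$value * scale
  glycoper <- per - constants$ccf * ocr$data$value

  ph <- ecar$data$phase
  pre <- which(ph == "baseline")
  rot <- which(ph == "rot_aa")
  if (!length(pre)) stop("glyco_rate_params: no baseline phase")
  if (!length(rot)) stop("glyco_rate_params: no rot_aa phase")

  basal_glyc <- glycoper[pre[length(pre)]]
  comp_glyc <- max(glycoper[rot])
  basal_per <- per[pre[length(pre)]]
  mito_ocr <- ocr$data$value[pre[length(pre)]] - min(ocr$data$value[rot])

  ratio <- if (basal_glyc > 0) mito_ocr / basal_glyc else
    flagged("undefined: basal glycolysis <= 0")
  pct <- if (basal_per > 0) 100 * basal_glyc / basal_per else
    flagged("undefined: basal PER <= 0")

  structure(list(basal_glycolysis = basal_glyc,
                 compensatory_glycolysis = comp_glyc,
                 mito_ocr_over_glycoper = ratio,
                 pct_per_from_glycolysis = pct,
                 basal_per = basal_per),
            class = "glyco_rate_params")
}

#' Inhibitor-dependent respiration
#'
#' Pathway-dependent respiration from an acute inhibitor injection (UK5099
#' for MPC-dependent, etomoxir for CPT1-dependent respiration): the last OCR
#' measurement before the injection minus the minimum OCR within the
#' injection's phase. The result is a signed difference; a post-injection
#' rise yields a negative value.
#'
#' @param ocr A segmented [flux_trace()].
#' @param event_name Name of the injection event / phase.
#' @return Rate difference (same units as the trace).
#' @export
inhibitor_dependent_respiration <- function(ocr, event_name) {
  stopifnot(inherits(ocr, "flux_trace"))
  ph <- ocr$data$phase
  rows <- which(ph == event_name)
  if (!length(rows))
    stop("inhibitor_dependent_respiration: no phase '", event_name,
         "'; available: ",
         paste(setdiff(unique(ph), NA), collapse = ", "))
  if (rows[1] == 1L)
    stop("inhibitor_dependent_respiration: no measurement before '",
         event_name, "'")
  ocr$data$value[rows[1] - 1L] - min(ocr$data$value[rows])
}

#' Acute injection response and group fold change
#'
#' For an acute stimulus injection (e.g. LPS or poly(I:C) added mid-run),
#' computes each well's response ratio = mean value within the injection's
#' phase / mean value before the injection, averages technical wells within
#' each (group, experiment) to one biological value, and returns the fold
#' change of the treated group over the control group (ratio of the two
#' biological means).
#'
#' @param traces List of segmented [flux_trace()] objects (one channel, e.g.
#'   ECAR), each carrying `group` and `experiment` labels.
#' @param event_name Name of the stimulus injection event.
#' @param treated,control Group labels to compare.
#' @return The fold change (numeric scalar) with attribute `"responses"`: a
#'   data.frame of the biological (per-experiment) response ratios.
#' @export
acute_injection_response <- function(traces, event_name, treated, control) {
  stopifnot(is.list(traces), length(traces) > 0)
  rows <- lapply(traces, function(tr) {
    ph <- tr$data$phase
    post <- which(ph == event_name)
    if (!length(post))
      stop("acute_injection_response: trace for well '", tr$well_id,
           "' has no phase '", event_name, "'")
    pre <- seq_len(post[1] - 1L)
    if (!length(pre))
      stop("acute_injection_response: no pre-injection measurement in well '",
           tr$well_id, "'")
    pre_mean <- mean(tr$data$value[pre])
    if (pre_mean == 0) {
      warning("acute_injection_response: well '", tr$well_id,
              "' excluded (zero pre-injection mean)")
      return(NULL)
    }
    data.frame(well_id = tr$well_id, group = tr$group,
               experiment = tr$experiment,
               response = mean(tr$data$value[post]) / pre_mean,
               stringsAsFactors = FALSE)
  })
  wells <- do.call(rbind, rows)
  if (is.null(wells) || !nrow(wells))
    stop("acute_injection_response: no usable wells")
  for (g in c(treated, control))
    if (!any(wells$group == g))
      stop("acute_injection_response: no wells in group '", g, "'")
  # technical wells -> one biological value per (group, experiment)
  bio <- aggregate(response ~ group + experiment, data = wells, FUN = mean)
  fold <- mean(bio$response[bio$group == treated]) /
    mean(bio$response[bio$group == control])
  attr(fold, "responses") <- bio
  fold
}

#' Analyze a plate into a tidy parameter table
#'
#' Protein-normalizes and phase-segments every trace of a plate, extracts the
#' parameters of the requested stress test per well, and returns them in long
#' form.
#'
#' @param plate A [plate_record()].
#' @param test One of `"mito"`, `"glyco"`, `"rate"`, `"inhibitor"`.
#' @param constants [per_constants()] for `test = "rate"`.
#' @param event_name Injection name for `test = "inhibitor"`.
#' @param normalize Divide by per-well protein first (default TRUE).
#' @return A data.frame with columns `well_id`, `group`, `experiment`,
#'   `parameter`, `value`, `unit`, `flag`.
#' @export
xf_analyze_plate <- function(plate, test = c("mito", "glyco", "rate",
                                             "inhibitor"),
                             constants = per_constants(),
                             event_name = NULL, normalize = TRUE) {
  test <- match.arg(test)
  stopifnot(inherits(plate, "plate_record"))
  traces <- lapply(plate$traces, function(tr) {
    if (normalize) tr <- normalize_to_protein(tr, plate$protein_ug[[tr$well_id]])
    segment_phases(tr, plate$schedule)
  })
  channel_of <- vapply(traces, function(tr) tr$channel, character(1))
  well_of <- vapply(traces, function(tr) tr$well_id, character(1))
  unit <- if (normalize) "per ug protein" else "raw rate"

  one_row <- function(tr, parameter, value, unit) {
    data.frame(well_id = tr$well_id, group = tr$group,
               experiment = tr$experiment, parameter = parameter,
               value = as.numeric(value), unit = unit,
               flag = flag_reason(value) %||% NA_character_,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in which(if (test == "glyco") channel_of == "ECAR"
                  else channel_of == "OCR")) {
    tr <- traces[[i]]
    params <- switch(test,
      mito = {
        j <- which(channel_of == "ECAR" & well_of == tr$well_id)
        ecar1 <- if (length(j)) traces[[j[1]]]$data$value[1] else NA_real_
        mito_stress_params(tr, ecar_first = ecar1)
      },
      glyco = glyco_stress_params(tr),
      rate = {
        j <- which(channel_of == "ECAR" & well_of == tr$well_id)
        if (!length(j))
          stop("xf_analyze_plate: no ECAR trace for well '", tr$well_id, "'")
        glyco_rate_params(tr, traces[[j[1]]], constants = constants)
      },
      inhibitor = {
        if (is.null(event_name))
          stop("xf_analyze_plate: test = 'inhibitor' needs event_name")
        list(inhibitor_dependent_respiration =
               inhibitor_dependent_respiration(tr, event_name))
      })
    for (p in names(params)) {
      u <- if (grepl("pct|spare", p)) "percent"
           else if (grepl("ratio|over", p)) "dimensionless" else unit
      rows[[length(rows) + 1L]] <- one_row(tr, p, params[[p]], u)
    }
  }
  do.call(rbind, rows)
}
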
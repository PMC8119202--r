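#' Construct a single-well extracellular flux trace
#'
#' A `flux_trace` holds the time-ordered rate measurements of one well on one
#' detection channel of an extracellular flux (Seahorse-type) assay: oxygen
#' consumption rate (OCR, pmol O2/min), extracellular acidification rate
#' (ECAR, mpH/min) or proton efflux rate (PER, pmol H+/min).
#'
#' @param well_id Well identifier (e.g. `"A1"`).
#' @param group Experimental group label.
#' @param channel One of `"OCR"`, `"ECAR"`, `"PER"`.
#' @param index Integer measurement indices, strictly increasing, 1-based.
#' @param time Measurement times in minutes, nondecreasing.
#' @param value Rates, same length as `index`.
#' @param phase Optional per-measurement phase labels (normally assigned by
#'   [segment_phases()]).
#' @param experiment Biological-repeat identifier (independent experiment the
#'   well belongs to); defaults to `"E1"`.
#' @return An object of class `"flux_trace"`: a list with fields `well_id`,
#'   `group`, `experiment`, `channel` and `data` (a data.frame with columns
#'   `index`, `time`, `value`, `phase`).
#' @export
flux_trace <- function(well_id, group, channel = c("OCR", "ECAR", "PER"),
                       index, time, value, phase = NULL,
                       experiment = "E1") {
  channel <- match.arg(channel)
  index <- as.integer(index)
  stopifnot(length(index) == length(time), length(time) == length(value))
  if (length(index) < 1L)
    stop("flux_trace for well '", well_id, "': needs at least one measurement")
  if (any(index < 1L) || any(diff(index) <= 0L))
    stop("flux_trace for well '", well_id,
         "': measurement indices must be >= 1 and strictly increasing")
  if (any(diff(time) < 0))
    stop("flux_trace for well '", well_id, "': times must be nondecreasing")
  if (is.null(phase)) phase <- rep(NA_character_, length(index))
  structure(
    list(well_id = as.character(well_id),
         group = as.character(group),
         experiment = as.character(experiment),
         channel = channel,
         data = data.frame(index = index, time = as.numeric(time),
                           value = as.numeric(value),
                           phase = as.character(phase),
                           stringsAsFactors = FALSE)),
    class = "flux_trace")
}

#' @export
print.flux_trace <- function(x, ...) {
  cat(sprintf("<flux_trace> well %s (%s, %s), %d measurements",
              x$well_id, x$group, x$channel, nrow(x$data)))
  ph <- unique(x$data$phase)
  if (!all(is.na(ph))) cat(", phases:", paste(ph, collapse = " > "))
  cat("\n")
  invisible(x)
}

#' Construct an injection schedule
#'
#' The ordered list of compound injections of a stress-test protocol. Each
#' event happens *after* the stated measurement index, so measurements
#' `after_measurement + 1, ...` belong to that event's phase until the next
#' event.
#'
#' @param name Unique event names (used as phase labels), e.g.
#'   `c("oligomycin", "fccp", "rot_aa")`.
#' @param compound Compound descriptions; defaults to `name`.
#' @param after_measurement Strictly increasing integer indices.
#' @return An `"injection_schedule"`: a data.frame with columns `name`,
#'   `compound`, `after_measurement`.
#' @export
injection_schedule <- function(name = character(), compound = name,
                               after_measurement = integer()) {
  stopifnot(length(name) == length(after_measurement))
  after_measurement <- as.integer(after_measurement)
  if (anyDuplicated(name))
    stop("injection_schedule: event names must be unique")
  if (length(after_measurement) > 1 && any(diff(after_measurement) <= 0L))
    stop("injection_schedule: after_measurement must be strictly increasing")
  structure(
    data.frame(name = as.character(name), compound = as.character(compound),
               after_measurement = after_measurement,
               stringsAsFactors = FALSE),
    class = c("injection_schedule", "data.frame"))
}

#' Standard stress-test schedules
#'
#' Convenience constructors for the classic injection protocols:
#' mitochondrial stress (oligomycin, FCCP, rotenone/antimycin A), glycolysis
#' stress (glucose, oligomycin, 2-deoxyglucose) and glycolytic rate
#' (rotenone/antimycin A, 2-deoxyglucose).
#'
#' @param after Integer vector of `after_measurement` indices, one per event.
#' @name schedules
#' @export
mito_stress_schedule <- function(after = c(3L, 6L, 9L)) {
  injection_schedule(c("oligomycin", "fccp", "rot_aa"),
                     c("oligomycin 1 uM", "FCCP 0.5 uM",
                       "rotenone/antimycin A 1 uM"), after)
}

#' @rdname schedules
#' @export
glyco_stress_schedule <- function(after = c(3L, 6L, 9L)) {
  injection_schedule(c("glucose", "oligomycin", "2dg"),
                     c("glucose 10 mM", "oligomycin 1 uM",
                       "2-deoxyglucose 100 mM"), after)
}

#' @rdname schedules
#' @export
glyco_rate_schedule <- function(after = c(3L, 6L)) {
  injection_schedule(c("rot_aa", "2dg"),
                     c("rotenone/antimycin A 1 uM", "2-deoxyglucose 100 mM"),
                     after)
}

#' Construct a plate record
#'
#' Bundles all traces of a plate with the shared injection schedule and the
#' per-well total protein content used for normalization.
#'
#' @param traces List of [flux_trace()] objects.
#' @param protein_ug Named numeric vector, micrograms of protein per well;
#'   every trace's `well_id` must have an entry.
#' @param schedule An [injection_schedule()].
#' @param meta Free-form list of annotations.
#' @return A `"plate_record"` list.
#' @export
plate_record <- function(traces, protein_ug, schedule, meta = list()) {
  stopifnot(is.list(traces), inherits(schedule, "injection_schedule"))
  wells <- unique(vapply(traces, function(tr) tr$well_id, character(1)))
  missing <- setdiff(wells, names(protein_ug))
  if (length(missing))
    stop("plate_record: no protein entry for well(s): ",
         paste(missing, collapse = ", "))
  if (any(protein_ug[wells] <= 0))
    stop("plate_record: nonpositive protein for well(s): ",
         paste(wells[protein_ug[wells] <= 0], collapse = ", "))
  structure(list(traces = traces, protein_ug = protein_ug,
                 schedule = schedule, meta = meta),
            class = "plate_record")
}

#' @export
print.plate_record <- function(x, ...) {
  ch <- table(vapply(x$traces, function(tr) tr$channel, character(1)))
  cat(sprintf("<plate_record> %d traces (%s), %d injection(s): %s\n",
              length(x$traces),
              paste(names(ch), ch, sep = "=", collapse = ", "),
              nrow(x$schedule), paste(x$schedule$name, collapse = " > ")))
  invisible(x)
}

#' Normalize a trace to protein content
#'
#' Divides every measurement by the well's total protein so rates are
#' expressed per microgram, mirroring BCA-based normalization of raw
#' instrument rates.
#'
#' @param trace A [flux_trace()].
#' @param protein Protein content in micrograms; must be positive.
#' @return The trace with all values divided by `protein`.
#' @export
normalize_to_protein <- function(trace, protein) {
  stopifnot(inherits(trace, "flux_trace"))
  if (!is_number(protein) || protein <= 0)
    stop("normalize_to_protein: nonpositive protein for well '",
         trace$well_id, "'")
  trace$data$value <- trace$data$value / protein
  trace
}

#' Label trace measurements with injection phases
#'
#' Every measurement is labeled `"baseline"` if it precedes the first
#' injection, otherwise with the name of the most recent preceding injection.
#' The labels partition the trace into contiguous phases.
#'
#' @param trace A [flux_trace()].
#' @param schedule An [injection_schedule()]; an empty schedule labels
#'   everything `"baseline"`.
#' @return The trace with its `phase` column filled in.
#' @export
segment_phases <- function(trace, schedule) {
  stopifnot(inherits(trace, "flux_trace"),
            inherits(schedule, "injection_schedule"))
  idx <- trace$data$index
  if (nrow(schedule) && max(schedule$after_measurement) >= max(idx))
    stop("segment_phases: injection after measurement ",
         max(schedule$after_measurement),
         " is beyond the last measurement (", max(idx), ") of well '",
         trace$well_id, "'")
  # findInterval over injection boundaries: 0 -> baseline, k -> k-th event
  k <- findInterval(idx, schedule$after_measurement + 0.5)
  trace$data$phase <- c("baseline", schedule$name)[k + 1L]
  # every declared phase must end up non-empty
  missing <- setdiff(schedule$name, unique(trace$data$phase))
  if (length(missing))
    stop("segment_phases: phase(s) without measurements: ",
         paste(missing, collapse = ", "))
  trace
}

#' Segment every trace of a plate with the plate's schedule
#'
#' @param plate A [plate_record()].
#' @return The plate with all traces segmented.
#' @export
segment_plate <- function(plate) {
  stopifnot(inherits(plate, "plate_record"))
  plate$traces <- lapply(plate$traces, segment_phases, schedule = plate$schedule)
  plate
}

# values of one phase, in measurement order; error if the phase is absent
phase_values <- function(trace, phase) {
  v <- trace$data$value[trace$data$phase == phase]
  if (!length(v))
    stop("trace for well '", trace$well_id, "' (", trace$channel,
         "): required phase '", phase, "' is missing or empty; present: ",
         paste(unique(trace$data$phase), collapse = ", "))
  v
}

has_phase <- function(trace, phase) any(trace$data$phase == phase)
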
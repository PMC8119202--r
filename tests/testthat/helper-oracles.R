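# Independent oracles: literal transcriptions of the stress-test formula
# list, evaluated directly on per-phase value vectors (never through the
# flux_trace machinery), plus small random-input generators.

oracle_mito <- function(base, oligo, fccp, rotaa, first_ocr, first_ecar) {
  nonmito <- min(rotaa)
  basal <- base[length(base)] - nonmito
  leak <- min(oligo) - nonmito
  list(nonmito = nonmito,
       basal = basal,
       leak = leak,
       atp = basal - leak,
       maximal = max(fccp) - nonmito,
       spare_pct = 100 * (max(fccp) - nonmito) / basal,
       ocr_ecar = first_ocr / first_ecar)
}

oracle_glyco <- function(base, glc, oligo) {
  nonglyco <- base[length(base)]
  list(nonglyco = nonglyco,
       glycolysis = max(glc) - nonglyco,
       capacity = max(oligo) - nonglyco,
       reserve = (max(oligo) - nonglyco) - (max(glc) - nonglyco))
}

oracle_rate <- function(ecar_base, ecar_rot, ocr_base, ocr_rot,
                        per_scale, ccf) {
  glycoper_base <- ecar_base * per_scale - ccf * ocr_base
  glycoper_rot <- ecar_rot * per_scale - ccf * ocr_rot
  basal_glyc <- glycoper_base[length(glycoper_base)]
  basal_per <- ecar_base[length(ecar_base)] * per_scale
  list(basal_glycolysis = basal_glyc,
       compensatory = max(glycoper_rot),
       mito_over_glyco = (ocr_base[length(ocr_base)] - min(ocr_rot)) /
         basal_glyc,
       pct_per = 100 * basal_glyc / basal_per)
}

# piecewise-constant trace from per-phase level vectors
trace_from_phases <- function(levels, channel = "OCR", well = "A1",
                              group = "g", mpp = 3L) {
  values <- unlist(lapply(levels, function(v)
    if (length(v) == 1L) rep(v, mpp) else v))
  n <- length(values)
  flux_trace(well, group, channel, seq_len(n), (seq_len(n) - 1) * 6.5,
             values)
}

segment_even <- function(trace, phase_names, mpp = 3L) {
  segment_phases(trace, injection_schedule(
    phase_names, after_measurement = mpp * seq_along(phase_names)))
}

random_mid <- function(n_carbons) {
  f <- stats::rgamma(n_carbons + 1L, shape = 1)
  f / sum(f)
}

# regular-polygon outline of a circle
circle_outline <- function(r, k = 64L, id = "M1", img = "I1", field = 37) {
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  outline_polygon(id, img, cbind(r * cos(th), r * sin(th)), field)
}
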
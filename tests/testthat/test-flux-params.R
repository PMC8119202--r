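mito_trace <- function(levels) {
  seg <- segment_even(trace_from_phases(levels),
                      c("oligomycin", "fccp", "rot_aa"))
}

test_that("mitochondrial stress parameters match the formula list", {
  seg <- mito_trace(list(100, 40, 150, 20))
  p <- mito_stress_params(seg, ecar_first = 10)
  expect_equal(p$nonmito_respiration, 20)
  expect_equal(p$basal_respiration, 80)
  expect_equal(p$proton_leak, 20)
  expect_equal(p$atp_production, 60)
  expect_equal(p$maximal_respiration, 130)
  expect_equal(p$spare_respiratory_capacity_pct, 162.5)
  expect_equal(p$ocr_ecar_ratio, 10)
})

test_that("degenerate and symmetric traces behave per contract", {
  flat <- mito_stress_params(mito_trace(list(20, 20, 20, 20)))
  expect_equal(flat$basal_respiration, 0)
  expect_equal(flat$maximal_respiration, 0)
  expect_true(is_flagged(flat$spare_respiratory_capacity_pct))

  sym <- mito_stress_params(mito_trace(list(100, 40, 100, 20)))
  expect_equal(sym$spare_respiratory_capacity_pct, 100)
})

test_that("a missing phase is an error", {
  seg <- segment_even(trace_from_phases(list(100, 40, 20)),
                      c("oligomycin", "rot_aa"))
  expect_error(mito_stress_params(seg), "fccp")
})

test_that("glycolysis stress parameters match the formula list", {
  seg <- segment_even(trace_from_phases(list(10, 50, 70, 12), "ECAR"),
                      c("glucose", "oligomycin", "2dg"))
  p <- glyco_stress_params(seg)
  expect_equal(p$nonglycolytic_acidification, 10)
  expect_equal(p$glycolysis, 40)
  expect_equal(p$glycolytic_capacity, 60)
  expect_equal(p$glycolytic_reserve, 20)

  # glucose phase at baseline level: zero glycolysis
  p0 <- glyco_stress_params(
    segment_even(trace_from_phases(list(10, 10, 70, 12), "ECAR"),
                 c("glucose", "oligomycin", "2dg")))
  expect_equal(p0$glycolysis, 0)

  # capacity below glycolysis: signed negative reserve
  pn <- glyco_stress_params(
    segment_even(trace_from_phases(list(10, 70, 50, 12), "ECAR"),
                 c("glucose", "oligomycin", "2dg")))
  expect_lt(pn$glycolytic_reserve, 0)
})

test_that("glycolytic rate parameters with neutral constants reduce to ECAR", {
  phases <- c("rot_aa", "2dg")
  ecar <- segment_even(trace_from_phases(list(40, 90, 5), "ECAR"), phases)
  ocr <- segment_even(trace_from_phases(list(100, 20, 20), "OCR"), phases)
  p <- glyco_rate_params(ocr, ecar, neutral_per_constants())
  expect_equal(p$basal_glycolysis, 40)
  expect_equal(p$compensatory_glycolysis, 90)
  expect_equal(p$mito_ocr_over_glycoper, 2.0)
  expect_equal(p$pct_per_from_glycolysis, 100)

  # doubling the buffer scale doubles rates, leaves the percentage unchanged
  doubled <- per_constants(buffer_factor = 2, chamber_volume = 1,
                           volume_scaling = 1, ccf = 0)
  p2 <- glyco_rate_params(ocr, ecar, doubled)
  expect_equal(p2$basal_glycolysis, 2 * p$basal_glycolysis)
  expect_equal(p2$compensatory_glycolysis, 2 * p$compensatory_glycolysis)
  expect_equal(p2$pct_per_from_glycolysis, p$pct_per_from_glycolysis)

  # all-zero ECAR: zero rates, flagged ratios
  ecar0 <- segment_even(trace_from_phases(list(0, 0, 0), "ECAR"), phases)
  p0 <- glyco_rate_params(ocr, ecar0, neutral_per_constants())
  expect_equal(p0$basal_glycolysis, 0)
  expect_equal(p0$compensatory_glycolysis, 0)
  expect_true(is_flagged(p0$mito_ocr_over_glycoper))
  expect_true(is_flagged(p0$pct_per_from_glycolysis))
})

test_that("inhibitor-dependent respiration is a signed before/after difference", {
  seg <- segment_even(trace_from_phases(list(c(120, 125, 130), c(70, 72, 70))),
                      "uk5099")
  expect_equal(inhibitor_dependent_respiration(seg, "uk5099"), 60)

  flat <- segment_even(trace_from_phases(list(100, 100)), "etomoxir")
  expect_equal(inhibitor_dependent_respiration(flat, "etomoxir"), 0)

  rise <- segment_even(trace_from_phases(list(100, 120)), "uk5099")
  expect_equal(inhibitor_dependent_respiration(rise, "uk5099"), -20)

  expect_error(inhibitor_dependent_respiration(seg, "nope"),
               "available.*uk5099")
})

test_that("acute injection fold change aggregates wells then groups", {
  mk <- function(well, group, pre, post)
    segment_even(trace_from_phases(list(pre, post), "ECAR", well, group),
                 "lps")
  traces <- list(mk("T1", "lps", 20, 30), mk("C1", "control", 20, 20))
  expect_equal(acute_injection_response(traces, "lps", "lps", "control"),
               1.5, ignore_attr = TRUE)

  same <- list(mk("T1", "lps", 20, 20), mk("C1", "control", 20, 20))
  expect_equal(acute_injection_response(same, "lps", "lps", "control"),
               1.0, ignore_attr = TRUE)

  # two technical wells x1.4 and x1.6 average to x1.5 before the ratio
  tech <- list(mk("T1", "lps", 20, 28), mk("T2", "lps", 20, 32),
               mk("C1", "control", 20, 20))
  expect_equal(acute_injection_response(tech, "lps", "lps", "control"),
               1.5, ignore_attr = TRUE)

  # zero pre-injection mean excludes the well with a warning
  bad <- list(mk("T1", "lps", 0, 10), mk("T2", "lps", 20, 30),
              mk("C1", "control", 20, 20))
  expect_warning(f <- acute_injection_response(bad, "lps", "lps", "control"),
                 "excluded")
  expect_equal(as.numeric(f), 1.5)
})

test_that("noiseless piecewise traces reproduce the transcribed formulas exactly", {
  set.seed(42)
  for (rep in 1:10) {
    # physiologic ordering: rot/AA < oligomycin < baseline < FCCP
    rotaa <- stats::runif(1, 5, 30)
    oligo <- rotaa + stats::runif(1, 5, 50)
    base <- oligo + stats::runif(1, 5, 100)
    fccp <- base + stats::runif(1, 0, 150)
    lv <- round(c(base, oligo, fccp, rotaa), 2)
    seg <- mito_trace(as.list(lv))
    first_ecar <- round(stats::runif(1, 5, 50), 2)
    p <- mito_stress_params(seg, ecar_first = first_ecar)
    o <- oracle_mito(rep(lv[1], 3), rep(lv[2], 3), rep(lv[3], 3),
                     rep(lv[4], 3), lv[1], first_ecar)
    expect_equal(p$nonmito_respiration, o$nonmito, tolerance = 0)
    expect_equal(p$basal_respiration, o$basal, tolerance = 0)
    expect_equal(p$proton_leak, o$leak, tolerance = 0)
    expect_equal(p$atp_production, o$atp, tolerance = 0)
    expect_equal(p$maximal_respiration, o$maximal, tolerance = 0)
    expect_equal(p$spare_respiratory_capacity_pct, o$spare_pct, tolerance = 0)
    expect_equal(p$ocr_ecar_ratio, o$ocr_ecar, tolerance = 0)
  }
})

test_that("ATP production and proton leak partition basal respiration exactly", {
  set.seed(7)
  for (rep in 1:20) {
    seg <- mito_trace(as.list(stats::runif(4, 1, 300)))
    p <- mito_stress_params(seg)
    expect_identical(p$atp_production + p$proton_leak, p$basal_respiration)
  }
})

test_that("parameters are time-shift invariant and scale equivariant", {
  lv <- list(c(95, 100, 98), c(42, 40, 41), c(150, 155, 149), c(21, 20, 22))
  seg <- mito_trace(lv)
  p <- mito_stress_params(seg, ecar_first = 10)

  shifted <- seg; shifted$data$time <- seg$data$time + 1000
  ps <- mito_stress_params(shifted, ecar_first = 10)
  expect_equal(ps, p)

  scaled <- seg; scaled$data$value <- seg$data$value * 3
  pk <- mito_stress_params(scaled, ecar_first = 30)
  for (nm in c("nonmito_respiration", "basal_respiration", "proton_leak",
               "atp_production", "maximal_respiration"))
    expect_equal(pk[[nm]], 3 * p[[nm]])
  expect_equal(pk$spare_respiratory_capacity_pct,
               p$spare_respiratory_capacity_pct)
  expect_equal(pk$ocr_ecar_ratio, p$ocr_ecar_ratio)
})

test_that("protein normalization commutes with difference parameters", {
  lv <- list(c(95, 100, 98), c(42, 40, 41), c(150, 155, 149), c(21, 20, 22))
  seg <- mito_trace(lv)
  before <- mito_stress_params(normalize_to_protein(seg, 8))
  after <- mito_stress_params(seg)
  for (nm in c("nonmito_respiration", "basal_respiration", "proton_leak",
               "atp_production", "maximal_respiration"))
    expect_equal(before[[nm]], after[[nm]] / 8)
})

test_that("xf_analyze_plate produces a tidy long table", {
  plate <- simulate_plate(xf_preset("il33_kd", seed = 11))
  tab <- xf_analyze_plate(plate, "mito")
  expect_true(all(c("well_id", "group", "parameter", "value", "unit",
                    "flag") %in% names(tab)))
  expect_setequal(unique(tab$group), c("scramble", "il33_kd"))
  expect_equal(sum(tab$parameter == "basal_respiration"),
               length(plate$traces) / 2)
})
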
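#' Aggregate technical replicates to biological values
#'
#' Wells within one experiment are technical repeats; their mean is the
#' biological value of that (experiment, condition). A single-well condition
#' passes through unchanged. Applying the function to an already-aggregated
#' table is a no-op on the values (idempotent).
#'
#' @param table Data.frame with columns `experiment_id`, `condition`,
#'   `value`, optionally `well_id` and `unit`.
#' @return Data.frame with one row per (experiment_id, condition):
#'   `experiment_id`, `condition`, `value`, `n_wells`, `unit`.
#' @export
aggregate_technical <- function(table) {
  need <- c("experiment_id", "condition", "value")
  if (!all(need %in% names(table)))
    stop("aggregate_technical: table needs columns ",
         paste(need, collapse = ", "))
  if (!nrow(table)) stop("aggregate_technical: empty table")
  if (anyNA(table$value)) stop("aggregate_technical: NA values")
  agg <- stats::aggregate(value ~ experiment_id + condition, data = table,
                          FUN = mean)
  cnt <- stats::aggregate(value ~ experiment_id + condition, data = table,
                          FUN = length)
  agg$n_wells <- cnt$value
  agg$unit <- if ("unit" %in% names(table)) table$unit[1] else NA_character_
  agg[order(agg$condition, agg$experiment_id),
      c("experiment_id", "condition", "value", "n_wells", "unit")]
}

#' Substrate consumption / product release from media concentrations
#'
#' Consumption of a substrate (e.g. glucose) = unconditioned-media
#' concentration minus sample concentration; production of a released product
#' (e.g. lactate) = sample minus unconditioned. Negative results are returned
#' as-is with a `flag` attribute.
#'
#' @param sample_conc,unconditioned_conc Concentrations (mM), >= 0.
#' @param mode `"consumption"` or `"production"`.
#' @return Concentration difference (mM), possibly flag-annotated.
#' @export
consumption_production <- function(sample_conc, unconditioned_conc,
                                   mode = c("consumption", "production")) {
  mode <- match.arg(mode)
  stopifnot(sample_conc >= 0, unconditioned_conc >= 0)
  out <- if (mode == "consumption") unconditioned_conc - sample_conc
         else sample_conc - unconditioned_conc
  if (out < 0) attr(out, "flag") <- paste0("negative ", mode)
  out
}

#' Background-subtracted ATP/ADP ratio
#'
#' `(atp_signal - atp_background) / (adp_signal - adp_background)`; a
#' nonpositive net ADP signal makes the ratio undefined ([flagged()]), a
#' negative net ATP signal is flag-annotated but returned.
#'
#' @param atp_signal,atp_background,adp_signal,adp_background Fluorescence
#'   readings.
#' @return The ratio, or a flagged value.
#' @export
atp_adp_ratio <- function(atp_signal, atp_background, adp_signal,
                          adp_background) {
  atp <- atp_signal - atp_background
  adp <- adp_signal - adp_background
  if (adp <= 0) return(flagged("undefined: net ADP signal <= 0"))
  out <- atp / adp
  if (atp < 0) attr(out, "flag") <- "negative net ATP signal"
  out
}

#' Relative gene expression (2^-ddCt)
#'
#' Relative expression of a target gene normalized to a reference gene
#' (beta-actin) and to a control sample:
#' `2^-((ct_target - ct_reference) - (ct_target_ctrl - ct_reference_ctrl))`.
#'
#' @param ct_target,ct_reference Ct values of the treated sample.
#' @param ct_target_ctrl,ct_reference_ctrl Ct values of the control sample.
#' @return Fold expression relative to control.
#' @export
relative_expression <- function(ct_target, ct_reference, ct_target_ctrl,
                                ct_reference_ctrl) {
  stopifnot(is.finite(ct_target), is.finite(ct_reference),
            is.finite(ct_target_ctrl), is.finite(ct_reference_ctrl))
  2^-((ct_target - ct_reference) - (ct_target_ctrl - ct_reference_ctrl))
}

#' Fold change relative to control
#'
#' @param value Measured value.
#' @param control_value Control value; zero gives a flagged result.
#' @return `value / control_value`.
#' @export
fold_change <- function(value, control_value) {
  if (control_value == 0) return(flagged("undefined: zero control value"))
  value / control_value
}

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Compare biological values between conditions
#'
#' Two conditions are compared by an unpaired two-tailed Student's t test
#' (equal-variance by default, Welch optionally); three or more conditions by
#' one-way ANOVA followed by Dunnett's multiple-comparison test of every
#' condition against the control. Dunnett adjustment uses the equicorrelated
#' multivariate-t quantile (computed by randomized quadrature under a fixed
#' local seed, so results are reproducible). Significance is reported at
#' P < 0.05.
#'
#' @param values Named list of numeric vectors, one per condition, each with
#'   >= 2 biological values.
#' @param design `"two_group"` or `"multi_vs_control"`.
#' @param control Control condition name (default: first element).
#' @param var_equal Pooled-variance t test (default TRUE).
#' @return Data.frame with one row per comparison: `comparison`, `effect`
#'   (mean difference, condition minus control), `test`, `statistic`, `df`,
#'   `p_value` (unadjusted), `p_adjusted`, `n_biological`, `significant`.
#' @export
compare_groups <- function(values, design = c("two_group",
                                              "multi_vs_control"),
                           control = names(values)[1], var_equal = TRUE) {
  design <- match.arg(design)
  if (is.null(names(values)) || any(names(values) == ""))
    stop("compare_groups: 'values' must be a fully named list")
  ns <- vapply(values, length, integer(1))
  if (any(ns < 2L))
    stop("compare_groups: every condition needs >= 2 biological values; ",
         paste(names(values)[ns < 2L], collapse = ", "), " do(es) not")
  if (!control %in% names(values))
    stop("compare_groups: unknown control '", control, "'")

  if (design == "two_group") {
    if (length(values) != 2L)
      stop("compare_groups: two_group design needs exactly 2 conditions")
    other <- setdiff(names(values), control)
    tt <- stats::t.test(values[[other]], values[[control]],
                        var.equal = var_equal)
    return(data.frame(
      comparison = paste(other, "-", control),
      effect = mean(values[[other]]) - mean(values[[control]]),
      test = if (var_equal) "t (pooled)" else "t (Welch)",
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, p_adjusted = tt$p.value,
      n_biological = sum(ns), significant = tt$p.value < 0.05,
      stringsAsFactors = FALSE))
  }

  df <- data.frame(
    value = unlist(values, use.names = FALSE),
    condition = factor(rep(names(values), ns),
                       levels = c(control, setdiff(names(values), control))))
  fit <- stats::aov(value ~ condition, data = df)
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett"))
  adj <- with_local_seed(20260921, summary(glht_fit))
  raw <- summary(glht_fit, test = multcomp::adjusted("none"))
  data.frame(
    comparison = names(adj$test$coefficients),
    effect = unname(adj$test$coefficients),
    test = "ANOVA + Dunnett",
    statistic = unname(adj$test$tstat),
    df = stats::df.residual(fit),
    p_value = unname(as.numeric(raw$test$pvalues)),
    p_adjusted = unname(as.numeric(adj$test$pvalues)),
    n_biological = sum(ns),
    significant = unname(as.numeric(adj$test$pvalues)) < 0.05,
    stringsAsFactors = FALSE)
}
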
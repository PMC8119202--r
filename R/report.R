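#' Assemble a pipeline report bundle
#'
#' Writes every supplied result table as a tidy CSV into `dir` and a JSON run
#' manifest recording the inputs, package version, seeds and every
#' configurable analysis convention in force (extremal-measurement phase
#' statistics, PER conversion constants, natural-abundance constants,
#' morphology cutoffs, statistics settings). Identical inputs and seeds give
#' byte-identical tables.
#'
#' @param tables Named list of data.frames (may be empty: manifest-only
#'   bundle).
#' @param dir Output directory (created if needed).
#' @param seed Integer seed(s) used upstream, recorded in the manifest.
#' @param inputs Character vector of input file names/descriptions.
#' @param constants [per_constants()] in force.
#' @param thresholds [morph_thresholds()] in force.
#' @param p13_natural,tracer_purity Natural-abundance correction constants.
#' @param extra Additional manifest entries.
#' @return Invisibly, the manifest list.
#' @export
build_report <- function(tables = list(), dir, seed = NA_integer_,
                         inputs = character(),
                         constants = per_constants(),
                         thresholds = morph_thresholds(),
                         p13_natural = 0.0107, tracer_purity = 0.99,
                         extra = list()) {
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables)))
    stop("build_report: 'tables' must be named")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- c(list(
    package = "metaboflux",
    version = as.character(utils::packageVersion("metaboflux")),
    inputs = as.list(inputs),
    seed = seed,
    tables = as.list(files),
    conventions = list(
      phase_statistic = paste("minimum within inhibitor phases,",
                              "maximum within stimulation phases,",
                              "last measurement before an injection"),
      replicate_policy = paste("technical wells averaged to one biological",
                               "value per experiment before inference;",
                               "mean +/- SD within, SEM across experiments"),
      per_constants = unclass(constants),
      na_correction = list(p13_natural = p13_natural,
                           tracer_purity = tracer_purity,
                           isotopes = "carbon only",
                           solver = "nonnegative least squares"),
      morph_thresholds = as.list(unclass(thresholds)),
      statistics = list(two_group = "unpaired two-tailed pooled-variance t",
                        multi_vs_control = "one-way ANOVA + Dunnett",
                        alpha = 0.05)
    )), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
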
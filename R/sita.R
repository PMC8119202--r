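#' Raw mass-isotopolog spectrum of one metabolite
#'
#' Measured intensities of the M+0 .. M+n mass isotopologs of a metabolite
#' with `n_carbons` carbons, plus the protein content of the sample for
#' abundance normalization.
#'
#' @param metabolite Metabolite name.
#' @param n_carbons Number of carbon atoms.
#' @param intensities Numeric vector of length `n_carbons + 1`, all >= 0,
#'   not all zero (arbitrary units).
#' @param protein_ug Sample protein content (ug).
#' @return An `"isotopolog_spectrum"` object.
#' @export
isotopolog_spectrum <- function(metabolite, n_carbons, intensities,
                                protein_ug = 1) {
  n_carbons <- as.integer(n_carbons)
  stopifnot(n_carbons >= 1L)
  if (length(intensities) != n_carbons + 1L)
    stop("isotopolog_spectrum('", metabolite, "'): need ", n_carbons + 1,
         " intensities (M+0..M+", n_carbons, ")")
  if (any(intensities < 0) || all(intensities == 0))
    stop("isotopolog_spectrum('", metabolite,
         "'): intensities must be >= 0 and not all zero")
  structure(list(metabolite = metabolite, n_carbons = n_carbons,
                 intensities = as.numeric(intensities),
                 protein_ug = protein_ug),
            class = "isotopolog_spectrum")
}

#' Corrected mass-isotopolog distribution (MID)
#'
#' Fractional abundances of M+0 .. M+n after natural-abundance correction;
#' nonnegative and summing to one.
#'
#' @param metabolite Metabolite name.
#' @param fractions Numeric vector, >= 0, summing to 1 (tolerance 1e-9).
#' @return A `"mid_profile"` object.
#' @export
mid_profile <- function(metabolite, fractions) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("mid_profile('", metabolite,
         "'): fractions must be >= 0 and sum to 1")
  structure(list(metabolite = metabolite, fractions = as.numeric(fractions)),
            class = "mid_profile")
}

#' @export
print.mid_profile <- function(x, digits = 4, ...) {
  cat("<mid_profile>", x$metabolite, "\n")
  v <- round(x$fractions, digits)
  names(v) <- paste0("M+", seq_along(v) - 1L)
  print(v)
  invisible(x)
}

# binomial mass-shift kernel of a species with j tracer carbons out of n:
# Binom(j, purity) 13C from the tracer positions + Binom(n-j, p13) from
# natural abundance at the remaining positions
shift_kernel <- function(n, j, p13, purity) {
  tracer <- stats::dbinom(0:j, j, purity)
  natural <- stats::dbinom(0:(n - j), n - j, p13)
  k <- convolve_vec(tracer, natural)
  k[seq_len(n + 1L)]  # length j+1 + n-j+1 - 1 = n+1 already
}

# plain linear convolution of two probability vectors
convolve_vec <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

#' Natural-abundance / tracer-purity correction matrix
#'
#' Column `j` (0-based) is the mass-shift distribution measured for a species
#' carrying `j` tracer-labeled carbons and `n - j` carbons subject to natural
#' 13C abundance: the convolution of Binomial(`j`, `tracer_purity`) and
#' Binomial(`n - j`, `p13_natural`), truncated at M+n. Only carbon isotopes
#' are modeled.
#'
#' @param n_carbons Number of carbons `n`.
#' @param p13_natural Natural 13C abundance (default 0.0107).
#' @param tracer_purity Isotopic purity of the tracer (default 0.99).
#' @return An `(n+1) x (n+1)` matrix; columns sum to 1 (<= 1 if truncation
#'   ever applied).
#' @export
correction_matrix <- function(n_carbons, p13_natural = 0.0107,
                              tracer_purity = 0.99) {
  if (!is_number(p13_natural) || p13_natural < 0 || p13_natural >= 0.5)
    stop("correction_matrix: p13_natural must be in [0, 0.5)")
  if (!is_number(tracer_purity) || tracer_purity <= 0 || tracer_purity > 1)
    stop("correction_matrix: tracer_purity must be in (0, 1]")
  n <- as.integer(n_carbons)
  vapply(0:n, function(j) shift_kernel(n, j, p13_natural, tracer_purity),
         numeric(n + 1L))
}

#' Correct a spectrum for natural abundance
#'
#' Deconvolves the measured isotopolog intensities with the
#' [correction_matrix()] by nonnegative least squares (suppressing the small
#' negative artifacts direct inversion can produce on noisy spectra) and
#' renormalizes to a fractional MID.
#'
#' @param spectrum An [isotopolog_spectrum()].
#' @param p13_natural,tracer_purity Passed to [correction_matrix()].
#' @return A [mid_profile()].
#' @export
correct_natural_abundance <- function(spectrum, p13_natural = 0.0107,
                                      tracer_purity = 0.99) {
  stopifnot(inherits(spectrum, "isotopolog_spectrum"))
  C <- correction_matrix(spectrum$n_carbons, p13_natural, tracer_purity)
  x <- pracma::lsqnonneg(C, spectrum$intensities)$x
  if (sum(x) <= 0)
    stop("correct_natural_abundance('", spectrum$metabolite,
         "'): correction produced an all-zero MID")
  mid_profile(spectrum$metabolite, x / sum(x))
}

#' Labeled / unlabeled pool abundances
#'
#' Splits a metabolite's total pool into its unlabeled (M+0) and labeled
#' (everything above M+0) components, normalized to protein:
#' `unlabeled_c12 = total_pool x M+0 / protein`,
#' `labeled_c13 = total_pool x (1 - M+0) / protein`.
#'
#' @param spectrum The [isotopolog_spectrum()] (supplies `protein_ug`).
#' @param mid The corrected [mid_profile()].
#' @param total_pool Total pool intensity; defaults to the spectrum's summed
#'   intensities.
#' @return List with `metabolite`, `labeled_c13`, `unlabeled_c12`.
#' @export
labeled_abundance <- function(spectrum, mid,
                              total_pool = sum(spectrum$intensities)) {
  stopifnot(inherits(spectrum, "isotopolog_spectrum"),
            inherits(mid, "mid_profile"))
  if (spectrum$protein_ug <= 0)
    stop("labeled_abundance('", spectrum$metabolite,
         "'): protein_ug must be positive")
  m0 <- mid$fractions[1]
  list(metabolite = spectrum$metabolite,
       labeled_c13 = total_pool * (1 - m0) / spectrum$protein_ug,
       unlabeled_c12 = total_pool * m0 / spectrum$protein_ug)
}

# shared core of the two surrogate ratios
surrogate_ratio <- function(citrate, pyruvate, citrate_shift) {
  stopifnot(inherits(citrate, "mid_profile"),
            inherits(pyruvate, "mid_profile"))
  if (length(pyruvate$fractions) < 4L)
    stop("surrogate ratio: pyruvate MID has no M+3 entry")
  pyr3 <- pyruvate$fractions[4]
  if (pyr3 <= 0) return(flagged("undefined: pyruvate M+3 fraction is 0"))
  citrate$fractions[citrate_shift + 1L] / pyr3
}

#' Isotopolog surrogate ratios for PDH and PC activity
#'
#' From [U-13C]-glucose tracing, M+3 pyruvate enters the TCA cycle either via
#' pyruvate dehydrogenase (PDH), yielding an M+2 acetyl unit and hence M+2
#' citrate, or via pyruvate carboxylase (PC), yielding M+3 oxaloacetate and
#' hence M+3 citrate. The citrate M+2 / pyruvate M+3 fraction ratio therefore
#' serves as a surrogate of PDH activity, and citrate M+3 / pyruvate M+3 of
#' PC activity.
#'
#' @param citrate,pyruvate Corrected [mid_profile()] objects.
#' @return The ratio, or a [flagged()] value when pyruvate M+3 is zero.
#' @export
pdh_surrogate <- function(citrate, pyruvate) {
  surrogate_ratio(citrate, pyruvate, 2L)
}

#' @rdname pdh_surrogate
#' @export
pc_surrogate <- function(citrate, pyruvate) {
  surrogate_ratio(citrate, pyruvate, 3L)
}

#' Read / write isotopolog tables
#'
#' Long CSV dialect: columns `metabolite`, `n_carbons`, `mass_shift`
#' (0-based), `intensity`, `sample_id`, `protein_ug`.
#'
#' @param path CSV file path.
#' @return `read_spectra()` returns a named list (by `sample_id`) of named
#'   lists (by metabolite) of [isotopolog_spectrum()] objects.
#' @name sita_io
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "n_carbons", "mass_shift", "intensity")
  if (!all(need %in% names(df)))
    stop("read_spectra: CSV must have columns ", paste(need, collapse = ", "))
  if (!"sample_id" %in% names(df)) df$sample_id <- "S1"
  if (!"protein_ug" %in% names(df)) df$protein_ug <- 1
  out <- list()
  for (s in unique(df$sample_id)) {
    sub_s <- df[df$sample_id == s, ]
    out[[s]] <- list()
    for (m in unique(sub_s$metabolite)) {
      sub <- sub_s[sub_s$metabolite == m, ]
      sub <- sub[order(sub$mass_shift), ]
      n <- sub$n_carbons[1]
      if (!identical(sub$mass_shift, 0:n))
        stop("read_spectra: metabolite '", m, "' sample '", s,
             "': mass shifts must be 0..", n)
      out[[s]][[m]] <- isotopolog_spectrum(m, n, sub$intensity,
                                           sub$protein_ug[1])
    }
  }
  out
}

#' @rdname sita_io
#' @param mids Named list (by sample) of named lists of [mid_profile()]s, or
#'   a single sample's named list.
#' @export
write_mids <- function(mids, path) {
  if (length(mids) && inherits(mids[[1]], "mid_profile"))
    mids <- list(S1 = mids)
  rows <- list()
  for (s in names(mids)) for (m in names(mids[[s]])) {
    fr <- mids[[s]][[m]]$fractions
    rows[[length(rows) + 1L]] <-
      data.frame(metabolite = m, sample_id = s,
                 mass_shift = seq_along(fr) - 1L, mid_fraction = fr,
                 stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Correct all spectra of a samples table and summarize
#'
#' Applies [correct_natural_abundance()] to every spectrum and, where a
#' sample has both citrate and pyruvate, appends the PDH/PC surrogate ratios
#' and per-metabolite labeled/unlabeled abundances.
#'
#' @param samples Output of [read_spectra()].
#' @param p13_natural,tracer_purity Correction constants.
#' @return List with `mids` (nested list of [mid_profile()]) and `summary`
#'   (data.frame: sample, metabolite/ratio, value, flag).
#' @export
sita_correct_samples <- function(samples, p13_natural = 0.0107,
                                 tracer_purity = 0.99) {
  mids <- lapply(samples, function(mets)
    lapply(mets, correct_natural_abundance,
           p13_natural = p13_natural, tracer_purity = tracer_purity))
  rows <- list()
  for (s in names(samples)) {
    for (m in names(samples[[s]])) {
      ab <- labeled_abundance(samples[[s]][[m]], mids[[s]][[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, quantity = c(paste0(m, "_labeled_c13"),
                                    paste0(m, "_unlabeled_c12")),
        value = c(ab$labeled_c13, ab$unlabeled_c12), flag = NA_character_,
        stringsAsFactors = FALSE)
    }
    if (all(c("citrate", "pyruvate") %in% names(mids[[s]]))) {
      pdh <- pdh_surrogate(mids[[s]]$citrate, mids[[s]]$pyruvate)
      pc <- pc_surrogate(mids[[s]]$citrate, mids[[s]]$pyruvate)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s,
        quantity = c("citrate_m2_over_pyruvate_m3",
                     "citrate_m3_over_pyruvate_m3"),
        value = c(as.numeric(pdh), as.numeric(pc)),
        flag = c(flag_reason(pdh) %||% NA_character_,
                 flag_reason(pc) %||% NA_character_),
        stringsAsFactors = FALSE)
    }
  }
  list(mids = mids, summary = do.call(rbind, rows))
}
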
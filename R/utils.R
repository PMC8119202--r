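#' Flagged numeric values
#'
#' Ratio-type parameters (spare respiratory capacity, OCR/ECAR,
#' mitoOCR/glycoPER, ATP/ADP) are undefined when their denominator is zero or
#' negative. Rather than silently propagating `NaN`, such quantities are
#' returned as a *flagged* value: an `NA_real_` carrying a `flag` attribute
#' that names the reason.
#'
#' @param reason Character reason, e.g. `"undefined: basal respiration <= 0"`.
#' @return A length-1 numeric `NA` of class `"flagged"` with attribute `flag`.
#' @export
flagged <- function(reason) {
  structure(NA_real_, flag = reason, class = c("flagged", "numeric"))
}

#' @rdname flagged
#' @param x Object to test.
#' @export
is_flagged <- function(x) inherits(x, "flagged") || !is.null(attr(x, "flag"))

#' @rdname flagged
#' @export
flag_reason <- function(x) attr(x, "flag")

#' @export
print.flagged <- function(x, ...) {
  cat("<flagged> NA (", attr(x, "flag"), ")\n", sep = "")
  invisible(x)
}

# scalar numeric check used by validators
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
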
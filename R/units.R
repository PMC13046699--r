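#' Concentration unit helpers
#'
#' Concentrations in this package carry one of two units, nanomolar
#' (`"nM"`) or micromolar (`"uM"`; the Unicode spelling `"µM"` is
#' accepted and normalized). All isobole arithmetic is done in a common
#' working unit after conversion.
#'
#' @param unit Character unit label.
#' @return `normalize_unit()` returns `"nM"` or `"uM"`.
#' @keywords internal
normalize_unit <- function(unit) {
  u <- as.character(unit)
  u[u %in% c("µM", "μM", "um", "uM", "UM")] <- "uM"
  u[u %in% c("nm", "nM", "NM")] <- "nM"
  bad <- !u %in% c("nM", "uM")
  if (any(bad)) {
    stop("unsupported concentration unit(s): ",
         paste(unique(unit[bad]), collapse = ", "),
         " (allowed: nM, uM)", call. = FALSE)
  }
  u
}

#' Convert concentrations between nM and uM
#'
#' @param x Numeric concentration(s).
#' @param from,to Unit labels (`"nM"` or `"uM"`).
#' @return Numeric vector in the `to` unit.
#' @examples
#' convert_conc(2.06, "nM", "uM")  # 0.00206
#' @export
convert_conc <- function(x, from, to) {
  from <- normalize_unit(from)
  to <- normalize_unit(to)
  factor <- c(nM = 1e-3, uM = 1)
  x * factor[[from]] / factor[[to]]
}
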
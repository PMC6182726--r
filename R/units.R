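#' Concentration unit conversions
#'
#' Convert between mass concentration (ng/mL, equivalently ug/L) and molar
#' concentration (umol/L) using the analyte's molecular weight in g/mol.
#' Since 1 ng/mL = 1 ug/L and MW in g/mol equals ug/umol, the conversion is
#' a plain division: uM = (ng/mL) / MW.
#'
#' @param x numeric vector of concentrations.
#' @param mw molecular weight in g/mol.
#' @return numeric vector in the target unit.
#' @examples
#' ngml_to_uM(277.4, 277.4) # 1 uM
#' @export
ngml_to_uM <- function(x, mw) {
  stopifnot(is.numeric(x), is.numeric(mw), mw > 0)
  x / mw
}

#' @rdname ngml_to_uM
#' @export
uM_to_ngml <- function(x, mw) {
  stopifnot(is.numeric(x), is.numeric(mw), mw > 0)
  x * mw
}

# mg/L -> ng/mL (1 mg/L = 1000 ng/mL)
mgL_to_ngml <- function(x) x * 1000

# trapezoidal area under the curve; used for AUC checks and time averaging
auc_trapz <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 2)
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}
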
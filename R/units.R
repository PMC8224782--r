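#' Concentration unit conversions
#'
#' Convert between mass concentration (ng/mL) and molar concentration
#' (umol/L) using the molecular weight. Internally the package works in
#' hours / umol / umol/L; ng/mL appears only at the I/O boundary.
#'
#' Since 1 ng/mL = 1 ug/L, dividing by the molecular weight in g/mol gives
#' the molar concentration directly in umol/L.
#'
#' @param x numeric vector of concentrations (ng/mL for the forward
#'   direction, umol/L for the inverse).
#' @param mw molecular weight in g/mol; must be a single positive number.
#' @return numeric vector of converted concentrations.
#' @examples
#' conc_ngml_to_umol(501.50, mw = 501.50)  # 1 umol/L
#' conc_umol_to_ngml(conc_ngml_to_umol(123.4, 501.5), 501.5)
#' @export
conc_ngml_to_umol <- function(x, mw) {
  if (!is.numeric(mw) || length(mw) != 1L || !is.finite(mw) || mw <= 0) {
    stop("`mw` must be a single positive number (g/mol)", call. = FALSE)
  }
  x / mw
}

#' @rdname conc_ngml_to_umol
#' @export
conc_umol_to_ngml <- function(x, mw) {
  if (!is.numeric(mw) || length(mw) != 1L || !is.finite(mw) || mw <= 0) {
    stop("`mw` must be a single positive number (g/mol)", call. = FALSE)
  }
  x * mw
}

# mg -> umol for a dose amount
mg_to_umol <- function(mg, mw) mg * 1000 / mw

# solubility mg/mL -> umol/L  (mg/mL = g/L; /mw -> mol/L; *1e6 -> umol/L)
mgml_to_umolL <- function(s, mw) s / mw * 1e6
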
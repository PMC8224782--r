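# Segmented gastrointestinal model primitives: Weibull dissolution,
# pH-dependent luminal solubility, transcellular absorption flux. The
# transit/attrition bookkeeping lives in the ODE right-hand side of the
# engine; these are the pure functions it is built from.

#' Weibull cumulative dissolved fraction
#'
#' `F(t) = 1 - 2^(-(t/t50)^shape)`. The parameterisation anchors the curve at
#' the half-dissolution time: `F(t50) = 0.5` for any shape; `F(0) = 0` and
#' `F` increases monotonically to 1.
#'
#' @param t elapsed time since administration, minutes (vectorised)
#' @param t50 time to 50% dissolved, minutes, > 0
#' @param shape Weibull shape parameter, > 0
#' @return dissolved fraction in [0, 1)
#' @examples
#' weibull_fraction(36, 36, 1.29)    # 0.5 by construction
#' weibull_fraction(2 * 30, 30, 1)   # 0.75
#' @export
weibull_fraction <- function(t, t50, shape) {
  check_range(t50, "t50", 0, open_lower = TRUE)
  check_range(shape, "shape", 0, open_lower = TRUE)
  if (any(t < 0)) stop("negative time in weibull_fraction", call. = FALSE)
  1 - 2^(-(t / t50)^shape)
}

# Weibull dissolution hazard dF/dt / (1 - F), 1/min. Applying this rate to
# the remaining undissolved mass reproduces F(t) exactly in aggregate while
# letting the solid transit between segments.
weibull_hazard <- function(t, t50, shape) {
  ifelse(t <= 0, 0, log(2) * shape / t50 * (pmax(t, 0) / t50)^(shape - 1))
}

#' pH-dependent luminal solubility of a monoprotic base
#'
#' Henderson-Hasselbalch scaling anchored at the reference measurement:
#' `S(pH) = S_ref * (1 + 10^(pKa - pH)) / (1 + 10^(pKa - pH_ref))`.
#' Solubility increases steeply below the pKa (ionised base), so a dose
#' dissolving in the acidic stomach can exceed by orders of magnitude what
#' the near-neutral intestine can keep in solution.
#'
#' @param drug a [drug_parameters()] object (uses `pKa_base`,
#'   `solubility_ref`, `solubility_ref_pH`)
#' @param pH luminal pH in [1, 9] (vectorised)
#' @return solubility in mg/mL
#' @export
luminal_solubility <- function(drug, pH) {
  stopifnot(inherits(drug, "drug_parameters"))
  check_range(pH, "pH", 1, 9)
  drug$solubility_ref *
    (1 + 10^(drug$pKa_base - pH)) /
    (1 + 10^(drug$pKa_base - drug$solubility_ref_pH))
}

#' Transcellular absorption flux from a luminal segment
#'
#' `rate = P * area * c_lumen`, converted to umol/h: permeability in cm/min
#' is converted to cm/h and the cm^3 -> L factor (1/1000) is applied. Linear
#' in each argument.
#'
#' @param P transcellular permeability, cm/min
#' @param area effective absorptive surface area, cm^2
#' @param c_lumen dissolved luminal concentration, umol/L
#' @return absorption rate, umol/h
#' @export
absorption_rate <- function(P, area, c_lumen) {
  check_range(P, "P", 0)
  check_range(area, "area", 0)
  if (any(c_lumen < 0)) stop("negative luminal concentration", call. = FALSE)
  P * 60 * area * c_lumen / 1000
}
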
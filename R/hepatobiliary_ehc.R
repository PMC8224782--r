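# Hepatobiliary handling: saturable enzyme/transporter kinetics, bile
# routing and the meal-triggered gallbladder emptying submodel. The phase
# bookkeeping (filling -> emptying -> refractory -> filling) is driven by the
# engine's event timeline; these functions define the rates and schedules.

#' Saturable (Michaelis-Menten) process rate
#'
#' `rate = kcat * enzyme_amount * c / (km + c)`, shared by CYP3A4 metabolism
#' and MRP2 canalicular transport. `enzyme_amount` is the tissue reference
#' concentration multiplied by the organ volume.
#'
#' @param c_unbound unbound driving concentration, umol/L, >= 0
#' @param kcat catalytic/transport rate constant, 1/min
#' @param enzyme_amount enzyme or transporter amount, umol
#' @param km Michaelis constant, umol/L, > 0
#' @return rate in umol/min
#' @export
saturable_rate <- function(c_unbound, kcat, enzyme_amount, km) {
  if (any(c_unbound < 0)) stop("negative concentration", call. = FALSE)
  check_range(kcat, "kcat", 0)
  check_range(enzyme_amount, "enzyme_amount", 0)
  check_range(km, "km", 0, open_lower = TRUE)
  kcat * enzyme_amount * c_unbound / (km + c_unbound)
}

#' Split hepatic biliary efflux between duodenum and gallbladder
#'
#' During the filling phase a fraction of the canalicular efflux drains
#' continuously to the duodenum and the remainder is stored in the
#' gallbladder. While the gallbladder is contracted or refilling
#' (`phase != "filling"`) it cannot store bile and the whole efflux bypasses
#' it into the duodenum.
#'
#' @param efflux canalicular efflux rate (any amount/time unit)
#' @param continuous_fraction fraction routed continuously to the duodenum
#'   during filling, in [0, 1]
#' @param phase gallbladder phase: `"filling"`, `"emptying"` or
#'   `"refractory"`
#' @return named numeric: `to_duodenum`, `to_gallbladder`
#' @export
bile_split <- function(efflux, continuous_fraction, phase = "filling") {
  check_range(continuous_fraction, "continuous_fraction", 0, 1)
  phase <- match.arg(phase, c("filling", "emptying", "refractory"))
  if (phase == "filling") {
    c(to_duodenum = efflux * continuous_fraction,
      to_gallbladder = efflux * (1 - continuous_fraction))
  } else {
    c(to_duodenum = efflux, to_gallbladder = 0)
  }
}

#' Meal-triggered gallbladder emptying schedule
#'
#' Expands the first-day meal times to an ordered event schedule over the
#' simulation horizon, repeating every 24 h. Dosing is fasted: no emptying
#' event occurs before the first meal time.
#'
#' @param ehc an [ehc_parameters()] object
#' @param horizon simulation end time, hours, > 0
#' @return numeric vector of event times (h), strictly increasing; empty if
#'   the horizon ends before the first meal
#' @export
meal_schedule <- function(ehc, horizon) {
  stopifnot(inherits(ehc, "ehc_parameters"))
  check_range(horizon, "horizon", 0, open_lower = TRUE)
  if (length(ehc$meal_times) == 0L) stop("empty meal list", call. = FALSE)
  days <- seq(0, by = 24, length.out = ceiling(horizon / 24) + 1)
  times <- sort(as.vector(outer(ehc$meal_times, days, `+`)))
  times[times <= horizon]
}

#' Cumulative amount ejected during an emptying event
#'
#' Exponential release: the ejectable amount is
#' `ejection_fraction * content0`, released with half-time
#' `emptying_half_time`, so
#' `ejected(t) = ejection_fraction * content0 * (1 - 2^(-t / half_time))`.
#' At `t = half_time` half of the asymptotic total has been ejected; the
#' asymptote is `ejection_fraction * content0`.
#'
#' @param t_since_event minutes since the emptying event started (vectorised)
#' @param content0 gallbladder content at event start, umol
#' @param ehc an [ehc_parameters()] object
#' @return cumulative ejected amount, umol
#' @export
emptying_event <- function(t_since_event, content0, ehc) {
  stopifnot(inherits(ehc, "ehc_parameters"))
  check_range(content0, "content0", 0)
  if (any(t_since_event < 0)) stop("negative event time", call. = FALSE)
  ehc$ejection_fraction * content0 *
    (1 - 2^(-t_since_event / ehc$emptying_half_time))
}
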
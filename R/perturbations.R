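# Scenario layer: CYP3A4-induction DDI with rifampin, hepatic-impairment
# physiology scaling, and local sensitivity analysis.

#' CYP3A4 induction model (perpetrator)
#'
#' Simplified perpetrator description for induction DDI co-simulation: a
#' one-compartment oral PK model for the perpetrator plus an Emax model on
#' the unbound perpetrator plasma concentration driving CYP3A4 synthesis in
#' liver and gut wall through a turnover model (see
#' [enzyme_turnover_step()]).
#'
#' The defaults describe rifampin 600 mg once daily with induction constants
#' from the published rifampin PBPK/DDI literature (Emax 9, EC50
#' 0.34 umol/L unbound, CYP3A4 turnover half-lives of ~36 h in liver and
#' ~23 h in gut). These are external literature defaults, not fitted here,
#' and are exposed as plain arguments.
#'
#' @param dose perpetrator dose, mg
#' @param interval dosing interval, h
#' @param n_doses number of perpetrator doses
#' @param ka first-order absorption rate constant, 1/h
#' @param cl apparent clearance, L/h
#' @param v volume of distribution, L
#' @param fu perpetrator fraction unbound in plasma
#' @param molecular_weight perpetrator molecular weight, g/mol
#' @param emax maximal fold-increase minus one of CYP3A4 synthesis
#' @param ec50 unbound perpetrator concentration at half-maximal induction,
#'   umol/L
#' @param kdeg_liver,kdeg_gut first-order CYP3A4 degradation rate constants,
#'   1/h
#' @param targets organs whose CYP3A4 is induced
#' @return object of class `induction_model`
#' @export
induction_model <- function(dose = 600, interval = 24, n_doses = 28,
                            ka = 1.15, cl = 7, v = 55, fu = 0.17,
                            molecular_weight = 822.94,
                            emax = 9, ec50 = 0.34,
                            kdeg_liver = log(2) / 36, kdeg_gut = log(2) / 23,
                            targets = c("liver", "gut_wall")) {
  check_range(dose, "dose", 0, open_lower = TRUE)
  check_range(ka, "ka", 0, open_lower = TRUE)
  check_range(cl, "cl", 0, open_lower = TRUE)
  check_range(v, "v", 0, open_lower = TRUE)
  check_range(fu, "fu", 0, 1, open_lower = TRUE)
  check_range(emax, "emax", 0)
  check_range(ec50, "ec50", 0, open_lower = TRUE)
  check_range(kdeg_liver, "kdeg_liver", 0, open_lower = TRUE)
  check_range(kdeg_gut, "kdeg_gut", 0, open_lower = TRUE)
  structure(
    list(dose = dose, interval = interval, n_doses = as.integer(n_doses),
         ka = ka, cl = cl, v = v, fu = fu,
         molecular_weight = molecular_weight,
         emax = emax, ec50 = ec50,
         kdeg_liver = kdeg_liver, kdeg_gut = kdeg_gut, targets = targets),
    class = "induction_model"
  )
}

#' @export
print.induction_model <- function(x, ...) {
  cat(sprintf(
    "<induction_model> %g mg q%gh x%d | Emax %.3g, EC50 %.3g umol/L | kdeg %.3g/%.3g 1/h\n",
    x$dose, x$interval, x$n_doses, x$emax, x$ec50, x$kdeg_liver, x$kdeg_gut
  ))
  invisible(x)
}

#' Induction fold-change of enzyme synthesis
#'
#' `fold = 1 + emax * c / (ec50 + c)` on the unbound perpetrator
#' concentration; 1 at zero concentration, `1 + emax` at saturation.
#'
#' @param c_unbound unbound perpetrator concentration, umol/L, >= 0
#' @param emax maximal fold-increase minus one
#' @param ec50 half-maximal concentration, umol/L
#' @return dimensionless synthesis fold-change (vectorised)
#' @export
induction_fold <- function(c_unbound, emax, ec50) {
  if (any(c_unbound < 0)) stop("negative concentration", call. = FALSE)
  check_range(emax, "emax", 0)
  check_range(ec50, "ec50", 0, open_lower = TRUE)
  1 + emax * c_unbound / (ec50 + c_unbound)
}

#' Enzyme turnover derivative
#'
#' Standard induction turnover: `dE/dt = kdeg * E0 * fold - kdeg * E`. At a
#' constant fold the steady state is `E0 * fold`; after washout the enzyme
#' returns to `E0` with half-life `ln 2 / kdeg`.
#'
#' @param E current enzyme amount (or relative level), > 0
#' @param E0 baseline enzyme amount, > 0
#' @param fold current synthesis fold-change (>= 0)
#' @param kdeg first-order degradation rate constant, 1/h
#' @return dE/dt in units of `E` per hour
#' @export
enzyme_turnover_step <- function(E, E0, fold, kdeg) {
  check_range(E, "E", 0, open_lower = TRUE)
  check_range(E0, "E0", 0, open_lower = TRUE)
  check_range(kdeg, "kdeg", 0, open_lower = TRUE)
  kdeg * E0 * fold - kdeg * E
}

# -- hepatic impairment -------------------------------------------------------

.impairment_table <- list(
  control = list(hematocrit = 0.47, portal = 1.00, renal = 1.00,
                 hepatic_arterial = 1.00, other = 1.00, brain = 1.00,
                 liver_volume = 1.00, cyp3a4_activity = 1.00,
                 protein_scale = 1.00),
  mild = list(hematocrit = 0.39, portal = 0.40, renal = 0.88,
              hepatic_arterial = 1.30, other = 1.75, brain = 1.00,
              liver_volume = 0.81, cyp3a4_activity = 1.00,
              protein_scale = 0.85),
  moderate = list(hematocrit = 0.37, portal = 0.36, renal = 0.65,
                  hepatic_arterial = 2.30, other = 2.25, brain = 1.00,
                  liver_volume = 0.65, cyp3a4_activity = 0.40,
                  protein_scale = 1.25)
)

#' Hepatic impairment scaling factors
#'
#' Physiological scaling for mild and moderate hepatic impairment
#' (Child-Pugh A/B like): haematocrit replacement, portal and renal blood
#' flow reduction, increased hepatic arterial and other-organ flows (brain
#' untouched), reduced liver volume fraction, reduced CYP3A4 activity
#' (moderate grade) and a plasma protein scale factor. The control grade is
#' the identity. For the moderate grade the protein scale factor defaults to
#' 1.25; 1.30 is a documented alternative reading (`moderate_protein_scale`).
#'
#' @param grade `"control"`, `"mild"` or `"moderate"`
#' @param moderate_protein_scale plasma protein scale factor used for the
#'   moderate grade (default 1.25)
#' @return object of class `impairment_scaling`
#' @export
impairment_scaling <- function(grade = c("control", "mild", "moderate"),
                               moderate_protein_scale = 1.25) {
  grade <- match.arg(grade)
  s <- .impairment_table[[grade]]
  if (grade == "moderate") s$protein_scale <- moderate_protein_scale
  structure(c(list(grade = grade), s), class = "impairment_scaling")
}

#' @export
print.impairment_scaling <- function(x, ...) {
  cat(sprintf(
    "<impairment_scaling> %s: hct %.2f | Q portal %.2f renal %.2f ha %.2f other %.2f | liver vol %.2f | CYP3A4 %.2f | protein %.2f\n",
    x$grade, x$hematocrit, x$portal, x$renal, x$hepatic_arterial, x$other,
    x$liver_volume, x$cyp3a4_activity, x$protein_scale
  ))
  invisible(x)
}

#' Apply hepatic-impairment scaling to a physiology
#'
#' Returns a new [physiology_model()] with the haematocrit replaced, each
#' organ blood flow multiplied by its scalar (portal-draining organs by the
#' portal scalar, kidney by the renal scalar, hepatic artery by the
#' hepatic-arterial scalar, brain untouched, remaining organs by the
#' other-organs scalar), the liver volume multiplied by the liver-volume
#' scalar, hepatic and intestinal CYP3A4 concentrations multiplied by the
#' activity scalar, and the plasma protein scale factor set so the engine
#' recomputes the unbound fraction via [scaled_fu()]. Cardiac output is
#' recomputed as the sum of the scaled organ flows. The control grade is a
#' field-wise identity.
#'
#' The impairment protein scale factor follows the clinical narrative it was
#' calibrated to: it scales the *unbound fraction* (mild 0.85 gives a
#' slightly lower fu and a higher Cmax through a smaller distribution
#' volume; moderate 1.25-1.30 gives a higher fu, increased clearance and a
#' larger distribution volume). Since [scaled_fu()] parameterises binding by
#' the binding-protein concentration, the reciprocal of the impairment
#' factor is passed: for fu << 1, `scaled_fu(fu, 1/f)` is `fu * f` to first
#' order.
#'
#' @param physiology a [physiology_model()]
#' @param scaling an [impairment_scaling()]
#' @return scaled [physiology_model()]
#' @export
apply_impairment <- function(physiology, scaling) {
  stopifnot(inherits(physiology, "physiology_model"),
            inherits(scaling, "impairment_scaling"))
  p <- physiology
  org <- p$organs
  mult <- rep(scaling$other, nrow(org))
  mult[org$drains == "portal"] <- scaling$portal
  mult[org$name == "kidney"] <- scaling$renal
  mult[org$name == "liver"] <- scaling$hepatic_arterial
  mult[org$name == "brain"] <- scaling$brain
  mult[org$name == "lung"] <- 1
  org$flow_l_h <- org$flow_l_h * mult
  org$volume_l[org$name == "liver"] <-
    org$volume_l[org$name == "liver"] * scaling$liver_volume
  p$organs <- org
  systemic <- org$drains %in% c("venous", "portal") | org$name == "liver"
  p$cardiac_output_l_h <- sum(org$flow_l_h[systemic])
  p$organs$flow_l_h[org$name == "lung"] <- p$cardiac_output_l_h
  p$hematocrit <- scaling$hematocrit
  p$cyp3a4 <- p$cyp3a4 * scaling$cyp3a4_activity
  # printed factor scales fu; scaled_fu() takes a protein-concentration scale
  p$plasma_protein_scale <- p$plasma_protein_scale / scaling$protein_scale
  validate_physiology(p)
}

# -- DDI co-simulation --------------------------------------------------------

#' Simulate a CYP3A4-induction DDI scenario
#'
#' Co-simulates perpetrator PK, CYP3A4 turnover in liver and gut wall, and
#' the victim PBPK model, and returns both study arms. The perpetrator is
#' dosed from `t = 0`; the victim dose is given after
#' `victim_offset` hours of perpetrator pre-treatment (long enough for the
#' induced enzyme level to approach its steady state). The control arm
#' simulates the identical victim regimen without perpetrator. Exposure
#' ratios are computed with [ddi_ratios()] on the post-victim-dose windows.
#'
#' @param drug,physiology,ehc victim model components
#' @param induction an [induction_model()]
#' @param regimen_with victim [dose_regimen()] for the perpetrator arm
#' @param regimen_without victim regimen for the control arm (defaults to
#'   `regimen_with`)
#' @param victim_offset perpetrator pre-treatment duration, h
#' @param obs_window observation window after the (first) victim dose, h
#' @param options extra [assemble_pbpk()] options (applied to both arms)
#' @param grid_dt output grid, h
#' @param ... passed to [simulate_pbpk()]
#' @return list with `with` and `without` ([simulate_pbpk()] results),
#'   `profile_with`/`profile_without` (post-dose windows, time re-zeroed) and
#'   `ratios` (named vector: `auc_ratio`, `cmax_ratio`)
#' @export
simulate_ddi <- function(drug, physiology, ehc, induction,
                         regimen_with, regimen_without = regimen_with,
                         victim_offset = 168, obs_window = 384,
                         options = list(), grid_dt = 0.25, ...) {
  stopifnot(inherits(induction, "induction_model"))
  t_end <- victim_offset + obs_window
  induction$n_doses <- max(induction$n_doses, ceiling(t_end / induction$interval))

  sys_with <- assemble_pbpk(drug, physiology, ehc,
                            modifyList(options, list(perpetrator = induction)))
  sys_without <- assemble_pbpk(drug, physiology, ehc, options)

  with <- simulate_pbpk(sys_with, regimen_with, t_end,
                        grid_dt = grid_dt, first_dose_time = victim_offset, ...)
  without <- simulate_pbpk(sys_without, regimen_without, t_end,
                           grid_dt = grid_dt, first_dose_time = victim_offset,
                           ...)
  win <- function(r) {
    k <- r$time >= victim_offset
    data.frame(time = r$time[k] - victim_offset, conc = r$conc[k])
  }
  pw <- win(with)
  po <- win(without)
  list(with = with, without = without,
       profile_with = pw, profile_without = po,
       ratios = ddi_ratios(pw, po))
}

# -- local sensitivity --------------------------------------------------------

#' Local sensitivity of an exposure metric to a model parameter
#'
#' Normalised local sensitivity coefficient
#' `S = (dOutput/Output) / (dp/p)` by central finite difference: the
#' parameter is perturbed to `p * (1 +/- delta)`, the scenario re-simulated,
#' and the relative output change divided by the relative parameter change.
#' `S = 1` means proportional response (e.g. AUC with respect to dose under
#' linear kinetics); `S = -1` inverse proportionality (AUC with respect to
#' clearance in a one-compartment model).
#'
#' @param drug,physiology,ehc model components (any may be `NULL` if unused
#'   by the chosen `options`)
#' @param regimen a [dose_regimen()]
#' @param parameter parameter path: `"drug.<field>"`, `"ehc.<field>"`,
#'   `"regimen.dose"`, `"physiology.hematocrit"` or
#'   `"degenerate.<volume_l|clearance_l_h>"`
#' @param output `"auc_last"` or `"cmax"`
#' @param delta relative perturbation in (0, 0.5]
#' @param t_end simulation horizon, h
#' @param options passed to [assemble_pbpk()]
#' @param ... passed to [simulate_pbpk()]
#' @return dimensionless sensitivity coefficient
#' @export
local_sensitivity <- function(drug, physiology, ehc, regimen, parameter,
                              output = c("auc_last", "cmax"), delta = 0.1,
                              t_end = 96, options = list(), ...) {
  output <- match.arg(output)
  check_range(delta, "delta", 0, 0.5, open_lower = TRUE)
  parts <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("parameter must be of the form `component.field`", call. = FALSE)
  }
  comp <- parts[1]; field <- parts[2]

  get_value <- function() {
    switch(comp,
      drug = drug[[field]],
      ehc = ehc[[field]],
      regimen = regimen[[field]],
      physiology = physiology[[field]],
      degenerate = options$degenerate[[field]],
      stop("unknown component `", comp, "`", call. = FALSE)
    )
  }
  base_val <- get_value()
  if (is.null(base_val)) {
    stop("parameter not found: ", parameter, call. = FALSE)
  }

  run <- function(value) {
    d <- drug; e <- ehc; r <- regimen; ph <- physiology; op <- options
    switch(comp,
      drug = { d[[field]] <- value },
      ehc = { e[[field]] <- value },
      regimen = { r[[field]] <- value },
      physiology = { ph[[field]] <- value },
      degenerate = { op$degenerate[[field]] <- value }
    )
    sys <- assemble_pbpk(d, ph, e, op)
    res <- simulate_pbpk(sys, r, t_end, ...)
    if (output == "auc_last") {
      auc_last(res$time, res$conc)
    } else {
      cmax_tmax(data.frame(time = res$time, conc = res$conc))[["cmax"]]
    }
  }
  y0 <- run(base_val)
  up <- run(base_val * (1 + delta))
  dn <- run(base_val * (1 - delta))
  ((up - dn) / y0) / (2 * delta)
}
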
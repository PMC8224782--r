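#' @importFrom stats approx median optim optimize quantile rlnorm rnorm runif sd setNames
#' @importFrom utils modifyList read.csv write.csv
#' @useDynLib cabopbpk, .registration = TRUE
NULL

# -- internal validation helpers ---------------------------------------------

stop_missing <- function(field, where) {
  stop(sprintf("missing mandatory field `%s` in %s", field, where), call. = FALSE)
}

check_range <- function(x, field, lower = -Inf, upper = Inf,
                        open_lower = FALSE, open_upper = FALSE) {
  if (is.null(x) || !is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("field `%s` must be finite numeric", field), call. = FALSE)
  }
  lo_ok <- if (open_lower) all(x > lower) else all(x >= lower)
  hi_ok <- if (open_upper) all(x < upper) else all(x <= upper)
  if (!lo_ok || !hi_ok) {
    stop(sprintf(
      "field `%s` = %s violates invariant %s%s, %s%s", field,
      paste(signif(x, 6), collapse = ","),
      if (open_lower) "(" else "[", lower, upper,
      if (open_upper) ")" else "]"
    ), call. = FALSE)
  }
  x
}

# -- DrugParameters -----------------------------------------------------------

#' Drug parameter set
#'
#' Physicochemical and kinetic constants of the victim compound. The packaged
#' default profile (see [cab_defaults()]) carries the cabozantinib values:
#' MW 501.50 g/mol, base pKa 6.32, logP 4.40, solubility 7.72e-3 mg/mL at
#' pH 6.5, CYP3A4 Michaelis-Menten constants (Km 0.97 umol/L,
#' kcat 0.67 /min), MRP2 transport constants (Km 10 umol/L,
#' kcat 2111.11 /min, liver reference concentration 0.09 umol/L) and a
#' transcellular intestinal permeability of 1.70e-4 cm/min.
#'
#' `fu_plasma` is stored as a *fraction*. Cabozantinib is ~99.7% bound to
#' plasma proteins, so the packaged default is 0.0024 (0.24% unbound). If you
#' supply your own configuration, supply a fraction in (0, 1].
#'
#' @param molecular_weight g/mol
#' @param pKa_base acid dissociation constant of the conjugate acid (base)
#' @param fu_plasma fraction unbound in plasma, (0, 1]
#' @param logP octanol-water log partition coefficient
#' @param solubility_ref aqueous solubility (mg/mL) at `solubility_ref_pH`
#' @param solubility_ref_pH reference pH for `solubility_ref`, in [1, 9]
#' @param km_cyp3a4,kcat_cyp3a4 CYP3A4 Michaelis constant (umol/L) and
#'   catalytic rate constant (1/min)
#' @param km_mrp2,kcat_mrp2 MRP2 Michaelis constant (umol/L) and transport
#'   rate constant (1/min)
#' @param mrp2_ref_conc MRP2 reference concentration, umol protein/L liver
#' @param transcellular_permeability transcellular intestinal permeability,
#'   cm/min
#' @param partition_method tissue partition method tag; only
#'   `"rodgers_rowland"` is implemented
#' @param permeability_method organ exchange mode; `"perfusion_limited"`
#'   (default) or `"permeability_limited"` (requires `organ_permeability`)
#' @param kp_rbc red-blood-cell to plasma-water partition coefficient used for
#'   the blood:plasma ratio; default 0 (drug confined to plasma)
#' @param organ_permeability optional organ permeability-surface product
#'   (L/h) used only in permeability-limited mode
#' @return an object of class `drug_parameters`
#' @export
drug_parameters <- function(molecular_weight, pKa_base, fu_plasma, logP,
                            solubility_ref, solubility_ref_pH,
                            km_cyp3a4, kcat_cyp3a4,
                            km_mrp2, kcat_mrp2, mrp2_ref_conc,
                            transcellular_permeability,
                            partition_method = "rodgers_rowland",
                            permeability_method = "perfusion_limited",
                            kp_rbc = 0,
                            organ_permeability = NULL) {
  mandatory <- c(
    "molecular_weight", "pKa_base", "fu_plasma", "logP", "solubility_ref",
    "solubility_ref_pH", "km_cyp3a4", "kcat_cyp3a4", "km_mrp2", "kcat_mrp2",
    "mrp2_ref_conc", "transcellular_permeability"
  )
  for (f in mandatory) {
    if (eval(call("missing", as.name(f)))) stop_missing(f, "drug_parameters")
  }
  check_range(molecular_weight, "molecular_weight", 0, open_lower = TRUE)
  check_range(pKa_base, "pKa_base", 0, open_lower = TRUE)
  check_range(fu_plasma, "fu_plasma", 0, 1, open_lower = TRUE)
  check_range(logP, "logP", -10, 10)
  check_range(solubility_ref, "solubility_ref", 0, open_lower = TRUE)
  check_range(solubility_ref_pH, "solubility_ref_pH", 1, 9)
  check_range(km_cyp3a4, "km_cyp3a4", 0, open_lower = TRUE)
  check_range(kcat_cyp3a4, "kcat_cyp3a4", 0)
  check_range(km_mrp2, "km_mrp2", 0, open_lower = TRUE)
  check_range(kcat_mrp2, "kcat_mrp2", 0)
  check_range(mrp2_ref_conc, "mrp2_ref_conc", 0)
  check_range(transcellular_permeability, "transcellular_permeability", 0)
  check_range(kp_rbc, "kp_rbc", 0)
  partition_method <- match.arg(partition_method, "rodgers_rowland")
  permeability_method <- match.arg(
    permeability_method, c("perfusion_limited", "permeability_limited")
  )
  if (permeability_method == "permeability_limited" &&
      is.null(organ_permeability)) {
    stop("permeability_limited mode requires `organ_permeability` (L/h)",
         call. = FALSE)
  }
  structure(
    list(
      molecular_weight = molecular_weight, pKa_base = pKa_base,
      fu_plasma = fu_plasma, logP = logP,
      solubility_ref = solubility_ref, solubility_ref_pH = solubility_ref_pH,
      km_cyp3a4 = km_cyp3a4, kcat_cyp3a4 = kcat_cyp3a4,
      km_mrp2 = km_mrp2, kcat_mrp2 = kcat_mrp2, mrp2_ref_conc = mrp2_ref_conc,
      transcellular_permeability = transcellular_permeability,
      partition_method = partition_method,
      permeability_method = permeability_method,
      kp_rbc = kp_rbc,
      organ_permeability = organ_permeability
    ),
    class = "drug_parameters"
  )
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("<drug_parameters>\n")
  cat(sprintf("  MW %.2f g/mol | pKa(base) %.2f | logP %.2f | fu_p %.4g\n",
              x$molecular_weight, x$pKa_base, x$logP, x$fu_plasma))
  cat(sprintf("  solubility %.3g mg/mL at pH %.1f\n",
              x$solubility_ref, x$solubility_ref_pH))
  cat(sprintf("  CYP3A4: Km %.3g umol/L, kcat %.3g /min\n",
              x$km_cyp3a4, x$kcat_cyp3a4))
  cat(sprintf("  MRP2:   Km %.3g umol/L, kcat %.3g /min, ref conc %.3g umol/L\n",
              x$km_mrp2, x$kcat_mrp2, x$mrp2_ref_conc))
  cat(sprintf("  P_trans %.3g cm/min | partition: %s | exchange: %s\n",
              x$transcellular_permeability, x$partition_method,
              x$permeability_method))
  invisible(x)
}

# -- FormulationSpec ----------------------------------------------------------

#' Oral formulation specification
#'
#' Tablets and capsules dissolve along a Weibull profile parameterised by the
#' half-dissolution time `weibull_t50` (minutes) and a shape parameter. An
#' oral solution is treated as instantaneously dissolving in the stomach; its
#' effective gastrointestinal solubility may be scaled down by
#' `solution_solubility_scale` to emulate a partly precipitated suspension.
#'
#' @param kind one of `"solution"`, `"tablet"`, `"capsule"`
#' @param weibull_t50 time to 50% dissolved, minutes (solid forms only),
#'   measured from the end of the disintegration lag
#' @param weibull_shape Weibull shape parameter (solid forms only)
#' @param lag_min disintegration lag before dissolution starts, minutes
#'   (solid forms only). Defaults to 0; the packaged capsule profile uses
#'   15 min for hard-gelatin shell rupture, a standard in-vivo
#'   disintegration time.
#' @param solution_solubility_scale luminal solubility scale in (0, 1]
#'   (solution only)
#' @return object of class `formulation_spec`
#' @export
formulation_spec <- function(kind = c("tablet", "capsule", "solution"),
                             weibull_t50 = NULL, weibull_shape = NULL,
                             lag_min = NULL,
                             solution_solubility_scale = NULL) {
  kind <- match.arg(kind)
  if (kind == "solution") {
    if (!is.null(weibull_t50) || !is.null(weibull_shape) || !is.null(lag_min)) {
      stop("Weibull/lag fields must be absent for a solution", call. = FALSE)
    }
    if (is.null(solution_solubility_scale)) solution_solubility_scale <- 0.8
    check_range(solution_solubility_scale, "solution_solubility_scale", 0, 1,
                open_lower = TRUE)
  } else {
    if (is.null(weibull_t50)) stop_missing("weibull_t50", kind)
    if (is.null(weibull_shape)) stop_missing("weibull_shape", kind)
    if (is.null(lag_min)) lag_min <- 0
    check_range(weibull_t50, "weibull_t50", 0, open_lower = TRUE)
    check_range(weibull_shape, "weibull_shape", 0, open_lower = TRUE)
    check_range(lag_min, "lag_min", 0)
    if (!is.null(solution_solubility_scale)) {
      stop("solution_solubility_scale applies to solutions only", call. = FALSE)
    }
  }
  structure(
    list(kind = kind, weibull_t50 = weibull_t50,
         weibull_shape = weibull_shape, lag_min = lag_min,
         solution_solubility_scale = solution_solubility_scale),
    class = "formulation_spec"
  )
}

#' @export
print.formulation_spec <- function(x, ...) {
  if (x$kind == "solution") {
    cat(sprintf("<formulation_spec> solution (solubility scale %.3g)\n",
                x$solution_solubility_scale))
  } else {
    cat(sprintf("<formulation_spec> %s (Weibull t50 %.4g min, shape %.4g)\n",
                x$kind, x$weibull_t50, x$weibull_shape))
  }
  invisible(x)
}

# -- EHCParameters ------------------------------------------------------------

#' Enterohepatic recirculation parameters
#'
#' Gallbladder emptying and bile-routing constants. During the filling phase a
#' fraction `continuous_fraction` of hepatic biliary output flows straight to
#' the duodenum and the remainder is stored in the gallbladder. A meal
#' triggers an emptying event: the fraction `ejection_fraction` of the stored
#' amount is released into the duodenum with an exponential half-time
#' `emptying_half_time`. For `refill_time` minutes after the event the
#' contracted gallbladder cannot store bile and all hepatic bile output
#' bypasses it.
#'
#' @param emptying_half_time exponential emptying half-time, minutes
#' @param continuous_fraction fraction of bile continuously entering the
#'   duodenum during filling, in [0, 1]
#' @param ejection_fraction fraction of stored bile ejected per event, [0, 1]
#' @param refill_time time to complete gallbladder refilling, minutes
#' @param meal_times first-day meal clock times, hours post-dose, strictly
#'   increasing; the schedule repeats every 24 h
#' @return object of class `ehc_parameters`
#' @export
ehc_parameters <- function(emptying_half_time, continuous_fraction,
                           ejection_fraction, refill_time,
                           meal_times = c(4, 10, 15)) {
  check_range(emptying_half_time, "emptying_half_time", 0, open_lower = TRUE)
  check_range(continuous_fraction, "continuous_fraction", 0, 1)
  check_range(ejection_fraction, "ejection_fraction", 0, 1)
  check_range(refill_time, "refill_time", 0, open_lower = TRUE)
  if (length(meal_times) < 1L) stop("meal_times must be non-empty", call. = FALSE)
  check_range(meal_times, "meal_times", 0, 24)
  if (any(diff(meal_times) <= 0)) {
    stop("meal_times must be strictly increasing", call. = FALSE)
  }
  structure(
    list(emptying_half_time = emptying_half_time,
         continuous_fraction = continuous_fraction,
         ejection_fraction = ejection_fraction,
         refill_time = refill_time, meal_times = meal_times),
    class = "ehc_parameters"
  )
}

#' @export
print.ehc_parameters <- function(x, ...) {
  cat(sprintf(
    "<ehc_parameters> t50 %.4g min | continuous %.2g | ejection %.2g | refill %.4g min\n  meals at %s h (daily)\n",
    x$emptying_half_time, x$continuous_fraction, x$ejection_fraction,
    x$refill_time, paste(x$meal_times, collapse = ", ")
  ))
  invisible(x)
}

# -- DoseRegimen --------------------------------------------------------------

#' Dosing regimen
#'
#' @param dose dose amount, mg; strictly positive for a real regimen
#'   (`dose = 0` is permitted as a null regimen for verification runs)
#' @param formulation a [formulation_spec()] (required for oral dosing)
#' @param route `"oral"` or `"iv"`
#' @param interval dosing interval, hours (required when `n_doses > 1`)
#' @param n_doses number of doses, integer >= 1
#' @return object of class `dose_regimen`
#' @export
dose_regimen <- function(dose, formulation = NULL, route = c("oral", "iv"),
                         interval = 24, n_doses = 1L) {
  route <- match.arg(route)
  check_range(dose, "dose", 0)
  n_doses <- as.integer(n_doses)
  if (is.na(n_doses) || n_doses < 1L) {
    stop("n_doses must be an integer >= 1", call. = FALSE)
  }
  if (n_doses > 1L) check_range(interval, "interval", 0, open_lower = TRUE)
  if (route == "oral") {
    if (is.null(formulation)) stop_missing("formulation", "oral dose_regimen")
    stopifnot(inherits(formulation, "formulation_spec"))
  }
  structure(
    list(dose = dose, formulation = formulation, route = route,
         interval = interval, n_doses = n_doses),
    class = "dose_regimen"
  )
}

#' @export
print.dose_regimen <- function(x, ...) {
  form <- if (x$route == "iv") "iv bolus" else x$formulation$kind
  cat(sprintf("<dose_regimen> %g mg %s x%d q%gh\n",
              x$dose, form, x$n_doses, x$interval))
  invisible(x)
}

# -- PhysiologyModel ----------------------------------------------------------

#' Human physiology model
#'
#' Organ volumes, blood flows, GI segment geometry, haematocrit and
#' enzyme/transporter expression. The packaged baseline (see
#' [cab_defaults()]) is an adult reference individual assembled from standard
#' published reference values; the provenance of each organ row is documented
#' in `inst/extdata/physiology_human.yaml`.
#'
#' @param organs data.frame with columns `name`, `volume_l`, `flow_l_h`,
#'   `drains` (`"venous"` or `"portal"`). The lung is implicit: it receives
#'   the whole cardiac output in series between the venous and arterial pools
#'   and must be present as a row with `drains = "arterial"`.
#' @param gi data.frame with columns `name`, `volume_l` (lumen), `area_cm2`
#'   (effective absorptive surface), `ph`, `transit_h`; first row must be the
#'   stomach, last row is the terminal segment draining to faeces.
#' @param hematocrit haematocrit fraction in (0, 1)
#' @param venous_volume_l,arterial_volume_l blood pool volumes, L
#' @param cyp3a4 named numeric vector of CYP3A4 tissue concentrations
#'   (umol/L), e.g. `c(liver = 4.32, gut_wall = 0.07)`
#' @param plasma_protein_scale binding-protein concentration scale factor
#'   (1 = reference); see [scaled_fu()]
#' @param species species tag; only `"human"` is supported
#' @return object of class `physiology_model`
#' @export
physiology_model <- function(organs, gi, hematocrit,
                             venous_volume_l = 2.6, arterial_volume_l = 1.5,
                             cyp3a4 = c(liver = 4.32, gut_wall = 0.07),
                             plasma_protein_scale = 1,
                             species = "human") {
  species <- match.arg(species, "human")
  organs <- as.data.frame(organs)
  gi <- as.data.frame(gi)
  need <- c("name", "volume_l", "flow_l_h", "drains")
  if (!all(need %in% names(organs))) {
    stop_missing(paste(setdiff(need, names(organs)), collapse = ","), "organs")
  }
  need_gi <- c("name", "volume_l", "area_cm2", "ph", "transit_h")
  if (!all(need_gi %in% names(gi))) {
    stop_missing(paste(setdiff(need_gi, names(gi)), collapse = ","), "gi table")
  }
  check_range(organs$volume_l, "organs$volume_l", 0, open_lower = TRUE)
  check_range(organs$flow_l_h, "organs$flow_l_h", 0, open_lower = TRUE)
  check_range(hematocrit, "hematocrit", 0, 1, open_lower = TRUE,
              open_upper = TRUE)
  check_range(gi$volume_l, "gi$volume_l", 0, open_lower = TRUE)
  check_range(gi$area_cm2, "gi$area_cm2", 0)
  check_range(gi$ph, "gi$ph", 1, 9)
  check_range(gi$transit_h, "gi$transit_h", 0, open_lower = TRUE)
  check_range(plasma_protein_scale, "plasma_protein_scale", 0)
  if (!"liver" %in% organs$name) stop("organs must include a liver", call. = FALSE)
  if (!"gut_wall" %in% organs$name) {
    stop("organs must include a gut_wall", call. = FALSE)
  }
  if (sum(organs$drains == "arterial") != 1L ||
      organs$name[organs$drains == "arterial"] != "lung") {
    stop("exactly one organ (the lung) must drain to `arterial`", call. = FALSE)
  }
  if (gi$name[1] != "stomach") {
    stop("first GI segment must be the stomach", call. = FALSE)
  }
  # systemic flows: everything except lung and the liver row itself; the liver
  # row's flow_l_h is the *hepatic arterial* flow, portal inflow is implied by
  # the portal-draining organs
  systemic <- organs$drains %in% c("venous", "portal") | organs$name == "liver"
  co <- sum(organs$flow_l_h[systemic])
  obj <- structure(
    list(organs = organs, gi = gi, hematocrit = hematocrit,
         venous_volume_l = venous_volume_l,
         arterial_volume_l = arterial_volume_l,
         cardiac_output_l_h = co,
         cyp3a4 = cyp3a4, plasma_protein_scale = plasma_protein_scale,
         species = species),
    class = "physiology_model"
  )
  validate_physiology(obj)
}

validate_physiology <- function(p) {
  systemic <- p$organs$drains %in% c("venous", "portal") |
    p$organs$name == "liver"
  co <- sum(p$organs$flow_l_h[systemic])
  if (abs(co - p$cardiac_output_l_h) > 0.01 * p$cardiac_output_l_h) {
    stop("organ blood flows do not sum to cardiac output within 1%",
         call. = FALSE)
  }
  p
}

#' @export
print.physiology_model <- function(x, ...) {
  cat(sprintf(
    "<physiology_model> %s | %d organs | CO %.1f L/h | hct %.2f | %d GI segments\n",
    x$species, nrow(x$organs), x$cardiac_output_l_h, x$hematocrit, nrow(x$gi)
  ))
  invisible(x)
}

# -- config I/O ---------------------------------------------------------------

drug_from_list <- function(cfg) {
  do.call(drug_parameters, cfg)
}

formulation_from_list <- function(kind, cfg) {
  do.call(formulation_spec, c(list(kind = kind), cfg))
}

physiology_from_list <- function(cfg) {
  organs <- do.call(rbind, lapply(cfg$organs, function(o) {
    data.frame(name = o$name, volume_l = o$volume_l, flow_l_h = o$flow_l_h,
               drains = o$drains, stringsAsFactors = FALSE)
  }))
  gi <- do.call(rbind, lapply(cfg$gi, function(s) {
    data.frame(name = s$name, volume_l = s$volume_l, area_cm2 = s$area_cm2,
               ph = s$ph, transit_h = s$transit_h, stringsAsFactors = FALSE)
  }))
  physiology_model(
    organs = organs, gi = gi, hematocrit = cfg$hematocrit,
    venous_volume_l = cfg$venous_volume_l %||% 2.6,
    arterial_volume_l = cfg$arterial_volume_l %||% 1.5,
    cyp3a4 = unlist(cfg$cyp3a4),
    plasma_protein_scale = cfg$plasma_protein_scale %||% 1,
    species = cfg$species %||% "human"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a model configuration
#'
#' Reads a YAML (canonical) or JSON configuration and returns fully validated
#' model objects. Missing optional sections fall back to the packaged
#' defaults; missing mandatory fields raise a named validation error and
#' out-of-range values raise a range error naming the violated invariant.
#'
#' The configuration has top-level sections `drug`, `formulations`,
#' `physiology`, `ehc` and optionally `regimen`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return a list with elements `drug` ([drug_parameters]), `physiology`
#'   ([physiology_model]), `ehc` ([ehc_parameters]), `formulations` (named
#'   list of [formulation_spec]) and `regimen` ([dose_regimen] or `NULL`)
#' @seealso [cab_defaults()] for the packaged cabozantinib profile,
#'   [save_config()] for the lossless inverse
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  config_from_list(cfg)
}

config_from_list <- function(cfg) {
  if (is.null(cfg$drug)) stop_missing("drug", "config")
  drug <- drug_from_list(cfg$drug)
  forms <- lapply(names(cfg$formulations %||% list()), function(k) {
    formulation_from_list(k, cfg$formulations[[k]])
  })
  names(forms) <- names(cfg$formulations %||% list())
  physiology <- if (is.null(cfg$physiology)) {
    default_physiology()
  } else {
    physiology_from_list(cfg$physiology)
  }
  ehc <- if (is.null(cfg$ehc)) default_ehc() else do.call(ehc_parameters, cfg$ehc)
  regimen <- NULL
  if (!is.null(cfg$regimen)) {
    r <- cfg$regimen
    form <- if (!is.null(r$formulation)) forms[[r$formulation]] else NULL
    regimen <- dose_regimen(dose = r$dose, formulation = form,
                            route = r$route %||% "oral",
                            interval = r$interval %||% 24,
                            n_doses = r$n_doses %||% 1L)
  }
  list(drug = drug, physiology = physiology, ehc = ehc,
       formulations = forms, regimen = regimen)
}

config_to_list <- function(config) {
  drug <- unclass(config$drug)
  drug$organ_permeability <- drug$organ_permeability
  drug <- drug[!vapply(drug, is.null, logical(1))]
  forms <- lapply(config$formulations, function(f) {
    out <- unclass(f)
    out$kind <- NULL
    out[!vapply(out, is.null, logical(1))]
  })
  phys <- config$physiology
  list(
    drug = drug,
    formulations = forms,
    ehc = unclass(config$ehc),
    physiology = list(
      species = phys$species,
      hematocrit = phys$hematocrit,
      venous_volume_l = phys$venous_volume_l,
      arterial_volume_l = phys$arterial_volume_l,
      plasma_protein_scale = phys$plasma_protein_scale,
      cyp3a4 = as.list(phys$cyp3a4),
      organs = lapply(seq_len(nrow(phys$organs)), function(i) {
        as.list(phys$organs[i, , drop = FALSE])
      }),
      gi = lapply(seq_len(nrow(phys$gi)), function(i) {
        as.list(phys$gi[i, , drop = FALSE])
      })
    )
  )
}

#' Save a model configuration
#'
#' Serialises a configuration (as returned by [load_config()] or
#' [cab_defaults()]) to YAML or JSON such that loading it back returns an
#' identical parameter set.
#'
#' @param config configuration list
#' @param path output path ending in `.yaml`, `.yml` or `.json`
#' @return `path`, invisibly
#' @export
save_config <- function(config, path) {
  lst <- config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path, precision = 12)
  }
  invisible(path)
}

#' Packaged cabozantinib defaults
#'
#' Returns the packaged default configuration: the cabozantinib drug profile,
#' tablet/capsule Weibull dissolution and solution formulations, the adult
#' reference physiology and the gallbladder/EHC parameter set.
#'
#' @return a configuration list; see [load_config()]
#' @examples
#' cfg <- cab_defaults()
#' cfg$drug
#' @export
cab_defaults <- function() {
  load_config(system.file("extdata", "cabozantinib.yaml",
                          package = "cabopbpk", mustWork = TRUE))
}

default_physiology <- function() {
  physiology_from_list(
    yaml::read_yaml(system.file("extdata", "physiology_human.yaml",
                                package = "cabopbpk", mustWork = TRUE))
  )
}

default_ehc <- function() {
  do.call(ehc_parameters,
          yaml::read_yaml(system.file("extdata", "ehc.yaml",
                                      package = "cabopbpk", mustWork = TRUE)))
}
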
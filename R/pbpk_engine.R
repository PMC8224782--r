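# Whole-body ODE engine: assembles the organ/blood/GI/gallbladder system,
# integrates it with deSolve::lsoda between discrete events (doses, meals,
# gallbladder reopening), and emits simulation results.
#
# Topology: venous pool -> lung -> arterial pool -> organs -> venous pool;
# gut wall, spleen, pancreas and stomach wall drain into the portal vein
# (implicit, no storage) which joins the hepatic arterial inflow at the
# liver. Organ exchange is perfusion-limited with Rodgers-Rowland partition
# coefficients. Elimination: saturable CYP3A4 metabolism in liver and gut
# wall and the fecal route (unreabsorbed biliary/unabsorbed luminal drug).
# The parent compound has no renal elimination.

#' Assemble the whole-body PBPK system
#'
#' Connects organs by blood flows, attaches the segmented GI tract, the
#' saturable CYP3A4/MRP2 processes and the gallbladder submodel, and
#' precomputes partition coefficients. The returned system is immutable; all
#' scenario variation goes through new `assemble_pbpk()` calls.
#'
#' @param drug a [drug_parameters()] object
#' @param physiology a [physiology_model()] object
#' @param ehc an [ehc_parameters()] object (may be `NULL` when
#'   `options$mrp2 = FALSE`)
#' @param options list of switches:
#'   \describe{
#'     \item{mrp2}{logical, default `TRUE`: MRP2 canalicular efflux active.}
#'     \item{ehc}{logical, default `TRUE`: biliary output is recirculated via
#'       gallbladder/duodenum. With `ehc = FALSE` (and `mrp2 = TRUE`) biliary
#'       output is excreted directly to faeces without reabsorption.}
#'     \item{bile_reabsorption}{fraction of biliary output secreted in a
#'       reabsorbable form, default 0.73. The remainder is excreted with the
#'       faeces. The default is derived from the published with/without-EHC
#'       exposure contrast (factor 2.7) combined with the ratio of the MRP2
#'       and CYP3A4 unbound intrinsic clearances; see the methods vignette.}
#'     \item{perpetrator}{an [induction_model()] for CYP3A4-induction DDI
#'       co-simulation, or `NULL`.}
#'     \item{degenerate}{`list(volume_l =, clearance_l_h =)`: build a
#'       degenerate one-compartment system (iv only) with linear clearance,
#'       used for closed-form verification.}
#'   }
#' @return object of class `pbpk_system`
#' @export
assemble_pbpk <- function(drug, physiology, ehc = NULL, options = list()) {
  stopifnot(inherits(drug, "drug_parameters"))
  opts <- modifyList(
    list(mrp2 = TRUE, ehc = TRUE, bile_reabsorption = 0.73,
         perpetrator = NULL, degenerate = NULL),
    options
  )

  if (!is.null(opts$degenerate)) {
    dg <- opts$degenerate
    check_range(dg$volume_l, "degenerate$volume_l", 0, open_lower = TRUE)
    check_range(dg$clearance_l_h, "degenerate$clearance_l_h", 0)
    return(structure(
      list(kind = "onecomp", drug = drug, degenerate = dg, opts = opts,
           state_names = c("central", "eliminated")),
      class = "pbpk_system"
    ))
  }

  stopifnot(inherits(physiology, "physiology_model"))
  if (opts$mrp2 && opts$ehc && is.null(ehc)) {
    stop("EHC recirculation requires `ehc` parameters", call. = FALSE)
  }
  if (!is.null(ehc)) stopifnot(inherits(ehc, "ehc_parameters"))

  org <- physiology$organs
  if (nrow(org) == 0L) stop("topology error: empty organ set", call. = FALSE)
  # every organ needs an inflow and outflow definition
  if (!all(org$drains %in% c("venous", "portal", "arterial"))) {
    stop("topology error: unknown drainage tag", call. = FALSE)
  }

  fu_eff <- scaled_fu(drug$fu_plasma, physiology$plasma_protein_scale)
  bp <- blood_plasma_ratio(fu_eff, physiology$hematocrit, drug$kp_rbc)
  pset <- kp_rodgers_rowland(drug, tissues = org$name, fu = fu_eff)
  kp <- pset$kp[org$name]

  gi <- physiology$gi
  nseg <- nrow(gi)
  # luminal solubility per segment, umol/L
  sol_umol <- mgml_to_umolL(luminal_solubility(drug, gi$ph),
                            drug$molecular_weight)
  # first-order absorption coefficient per segment (1/h) applied to the
  # dissolved luminal amount: P*60*A/(1000*V)
  kabs <- drug$transcellular_permeability * 60 * gi$area_cm2 /
    (1000 * gi$volume_l)
  ktr <- 1 / gi$transit_h

  liver_i <- which(org$name == "liver")
  gut_i <- which(org$name == "gut_wall")
  lung_i <- which(org$name == "lung")
  portal_i <- which(org$drains == "portal")
  venous_i <- setdiff(which(org$drains == "venous"), liver_i)

  co <- physiology$cardiac_output_l_h
  q_liver_total <- org$flow_l_h[liver_i] + sum(org$flow_l_h[portal_i])

  cyp <- physiology$cyp3a4
  cyp_liver_amt <- unname(cyp["liver"]) * org$volume_l[liver_i]
  cyp_gut_amt <- unname(cyp["gut_wall"]) * org$volume_l[gut_i]
  mrp2_amt <- if (opts$mrp2) drug$mrp2_ref_conc * org$volume_l[liver_i] else 0

  state_names <- c(
    paste0("solid_", gi$name),
    paste0("diss_", gi$name),
    paste0("bile_", gi$name[-1]),
    paste0("prec_", gi$name[-1]),
    paste0("precbile_", gi$name[-1]),
    paste0("cumabs_", gi$name[-1]),
    "cumabs_bile", "fecal", "gallbladder", "gb_ejectable",
    paste0("tissue_", org$name),
    "arterial", "venous", "met_liver", "met_gut",
    "cyp3a4_liver_rel", "cyp3a4_gut_rel", "perp_gut", "perp_central"
  )
  n <- length(state_names)
  ix <- as.list(setNames(seq_len(n), state_names))
  idx <- list(
    solid = seq_len(nseg),
    diss = nseg + seq_len(nseg),
    bile = 2 * nseg + seq_len(nseg - 1),
    prec = 3 * nseg - 1 + seq_len(nseg - 1),
    precb = 4 * nseg - 2 + seq_len(nseg - 1),
    cumabs = 5 * nseg - 3 + seq_len(nseg - 1),
    cumabs_bile = ix$cumabs_bile, fecal = ix$fecal,
    gb = ix$gallbladder, gbe = ix$gb_ejectable,
    tissue = ix$fecal + 2 + seq_len(nrow(org)),
    art = ix$arterial, ven = ix$venous,
    metl = ix$met_liver, metg = ix$met_gut,
    el = ix$cyp3a4_liver_rel, eg = ix$cyp3a4_gut_rel,
    pg = ix$perp_gut, pc = ix$perp_central
  )
  # states that carry victim mass (for the balance check); cumulative
  # absorption counters, the ejectable bookkeeping pool, relative enzyme
  # levels and perpetrator amounts are excluded
  mass_idx <- c(idx$solid, idx$diss, idx$bile, idx$prec, idx$precb,
                idx$fecal, idx$gb, idx$tissue, idx$art, idx$ven,
                idx$metl, idx$metg)

  structure(
    list(
      kind = "whole_body", drug = drug, physiology = physiology, ehc = ehc,
      opts = opts, fu_eff = fu_eff, bp = bp, kp = kp, partition = pset,
      gi = gi, nseg = nseg, sol_umol = sol_umol, kabs = kabs, ktr = ktr,
      org = org, liver_i = liver_i, gut_i = gut_i, lung_i = lung_i,
      portal_i = portal_i, venous_i = venous_i,
      co = co, q_liver_total = q_liver_total,
      cyp_liver_amt = cyp_liver_amt, cyp_gut_amt = cyp_gut_amt,
      mrp2_amt = mrp2_amt,
      kcat_cyp_h = drug$kcat_cyp3a4 * 60,
      kcat_mrp2_h = drug$kcat_mrp2 * 60,
      state_names = state_names, idx = idx, mass_idx = mass_idx
    ),
    class = "pbpk_system"
  )
}

#' @export
print.pbpk_system <- function(x, ...) {
  if (x$kind == "onecomp") {
    cat(sprintf("<pbpk_system> degenerate one-compartment (V %.3g L, CL %.3g L/h)\n",
                x$degenerate$volume_l, x$degenerate$clearance_l_h))
  } else {
    cat(sprintf(
      "<pbpk_system> whole-body: %d organs, %d GI segments | MRP2 %s | EHC %s | DDI %s\n",
      nrow(x$org), x$nseg, if (x$opts$mrp2) "on" else "off",
      if (x$opts$ehc) "on" else "off",
      if (is.null(x$opts$perpetrator)) "off" else "on"
    ))
    cat(sprintf("  fu_eff %.4g | B:P %.3g | CO %.1f L/h\n", x$fu_eff, x$bp, x$co))
  }
  invisible(x)
}

# -- right-hand sides ---------------------------------------------------------

rhs_onecomp <- function(t, y, p) {
  ke <- p$cl / p$v
  list(c(-ke * y[1], ke * y[1]))
}

rhs_whole_body <- function(t, y, p) {
  id <- p$idx
  dy <- numeric(length(y))

  s <- y[id$solid]
  d <- y[id$diss]
  b <- c(0, y[id$bile])          # align bile states with segments (no stomach)
  pr <- c(0, y[id$prec])         # re-precipitated dose-origin drug
  pb <- c(0, y[id$precb])        # re-precipitated bile-origin drug

  ## dissolution hazard, capped at the near-instant rate k_sol: for shape > 1
  ## the Weibull hazard grows without bound long after the dose, where the
  ## residual solid is negligible but the uncapped rate destabilises the
  ## integrator
  hz <- if (p$form_kind == "solution") {
    p$k_sol
  } else {
    min(p$k_sol,
        weibull_hazard((t - p$t_last_dose) * 60 - p$form_lag,
                       p$weibull_t50, p$weibull_shape) * 60)
  }
  dtot <- d + b
  sat <- p$sol_eff * p$gi_vol           # luminal saturation capacity, umol
  clamp <- pmax(0, 1 - dtot / sat)
  diss <- hz * s * clamp
  ## pH-shift precipitation: dissolved drug (dose- or bile-origin) above a
  ## segment's solubility precipitates into fast-redissolving fine-particle
  ## pools; the acidic stomach never saturates in practice and is exempt
  excess <- pmax(0, dtot - sat)
  excess[1] <- 0
  share_d <- d / pmax(dtot, 1e-300)
  prec_d <- p$k_prec * excess * share_d
  prec_b <- p$k_prec * excess - prec_d
  rediss_d <- p$k_prec * pr * clamp
  rediss_b <- p$k_prec * pb * clamp

  ## transit (first order along the segment chain; terminal -> faeces)
  out_s <- p$ktr * s
  out_d <- p$ktr * d
  out_b <- p$ktr * b
  out_p <- p$ktr * pr
  out_pb <- p$ktr * pb
  in_s <- c(0, out_s[-p$nseg])
  in_d <- c(0, out_d[-p$nseg])
  in_b <- c(0, out_b[-p$nseg])
  in_p <- c(0, out_p[-p$nseg])
  in_pb <- c(0, out_pb[-p$nseg])

  ## absorption into the gut wall (dose-origin and bile-origin tracked apart)
  j_d <- p$kabs * d
  j_b <- p$kabs * b

  ds <- -diss - out_s + in_s
  dd <- diss - out_d + in_d - j_d - prec_d + rediss_d
  db <- -out_b + in_b - j_b - prec_b + rediss_b
  dp_ <- prec_d - rediss_d - out_p + in_p
  dpb <- prec_b - rediss_b - out_pb + in_pb

  dy[id$solid] <- ds
  dy[id$diss] <- dd
  dy[id$bile] <- db[-1]
  dy[id$prec] <- dp_[-1]
  dy[id$precb] <- dpb[-1]
  dy[id$cumabs] <- j_d[-1]
  dy[id$cumabs_bile] <- sum(j_b)
  fecal_in <- out_s[p$nseg] + out_d[p$nseg] + out_b[p$nseg] +
    out_p[p$nseg] + out_pb[p$nseg]

  ## blood and organs
  a <- y[id$tissue]
  c_art <- y[id$art] / p$v_art
  c_ven <- y[id$ven] / p$v_ven
  c_out <- a / p$org_vol * p$bp / p$kp     # organ outflow blood concentration

  dy[id$tissue] <- p$org_q * (c_art - c_out)
  dy[id$tissue][p$lung_i] <- p$co * (c_ven - c_out[p$lung_i])

  ## unbound intracellular driving concentrations (plasma-referenced)
  cu_liver <- p$fu * (a[p$liver_i] / p$org_vol[p$liver_i]) / p$kp[p$liver_i]
  cu_gut <- p$fu * (a[p$gut_i] / p$org_vol[p$gut_i]) / p$kp[p$gut_i]

  e_liver <- y[id$el]
  e_gut <- y[id$eg]
  met_liver <- p$kcat_cyp_h * e_liver * p$cyp_liver_amt * cu_liver /
    (p$km_cyp + cu_liver)
  met_gut <- p$kcat_cyp_h * e_gut * p$cyp_gut_amt * cu_gut /
    (p$km_cyp + cu_gut)
  bile_eff <- p$kcat_mrp2_h * p$mrp2_amt * cu_liver / (p$km_mrp2 + cu_liver)

  ## gut wall gains absorbed drug, loses gut-wall metabolism
  dy[id$tissue][p$gut_i] <- dy[id$tissue][p$gut_i] + sum(j_d) + sum(j_b) -
    met_gut

  ## liver: hepatic artery + portal inflow, canalicular efflux, metabolism
  portal_in <- sum(p$org_q[p$portal_i] * c_out[p$portal_i])
  dy[id$tissue][p$liver_i] <-
    p$org_q[p$liver_i] * c_art + portal_in -
    p$q_liver_total * c_out[p$liver_i] - met_liver - bile_eff

  ## bile routing / gallbladder; the non-reabsorbable share of biliary
  ## output goes to faeces, the rest enters the recirculation loop
  to_duo <- 0
  if (bile_eff > 0 || y[id$gbe] > 0) {
    if (!p$ehc_on) {
      dy[id$fecal] <- dy[id$fecal] + bile_eff
    } else {
      bile_keep <- p$bile_reabs * bile_eff
      dy[id$fecal] <- dy[id$fecal] + bile_eff - bile_keep
      if (p$gb_filling) {
        to_duo <- bile_keep * p$cont_frac
        dy[id$gb] <- bile_keep * (1 - p$cont_frac)
      } else {
        eject <- p$k_empty * y[id$gbe]
        to_duo <- bile_keep + eject
        dy[id$gb] <- -eject
        dy[id$gbe] <- -eject
      }
    }
  }
  if (to_duo > 0) dy[id$bile][1] <- dy[id$bile][1] + to_duo

  dy[id$fecal] <- dy[id$fecal] + fecal_in
  dy[id$metl] <- met_liver
  dy[id$metg] <- met_gut

  ## arterial / venous pools (lung in series)
  dy[id$art] <- p$co * c_out[p$lung_i] - p$co * c_art
  dy[id$ven] <- sum(p$org_q[p$venous_i] * c_out[p$venous_i]) +
    p$q_liver_total * c_out[p$liver_i] - p$co * c_ven

  ## perpetrator PK and CYP3A4 turnover
  if (p$has_perp) {
    ag <- y[id$pg]
    ac <- y[id$pc]
    dy[id$pg] <- -p$perp_ka * ag
    dy[id$pc] <- p$perp_ka * ag - p$perp_cl / p$perp_v * ac
    cu_perp <- p$perp_fu * ac / p$perp_v
    fold <- 1 + p$perp_emax * cu_perp / (p$perp_ec50 + cu_perp)
    dy[id$el] <- p$perp_kdeg_liver * (fold - e_liver)
    dy[id$eg] <- p$perp_kdeg_gut * (fold - e_gut)
  }

  list(dy)
}

# -- event timeline -----------------------------------------------------------

build_timeline <- function(system, regimen, t_end, first_dose_time) {
  dose_times <- first_dose_time +
    seq(0, by = regimen$interval, length.out = regimen$n_doses)
  dose_times <- dose_times[dose_times < t_end]
  ev <- data.frame(time = dose_times, type = "dose", meal = NA_real_)

  ehc_active <- system$kind == "whole_body" && system$opts$mrp2 &&
    system$opts$ehc && !is.null(system$ehc)
  if (ehc_active) {
    meals <- first_dose_time +
      meal_schedule(system$ehc, max(t_end - first_dose_time, 1e-9))
    meals <- meals[meals < t_end]
    if (length(meals)) {
      reopen <- meals + system$ehc$refill_time / 60
      keep <- reopen < t_end
      ev <- rbind(ev, data.frame(time = meals, type = "meal", meal = meals))
      if (any(keep)) {
        ev <- rbind(ev, data.frame(time = reopen[keep], type = "reopen",
                                   meal = meals[keep]))
      }
    }
  }
  if (system$kind == "whole_body" && !is.null(system$opts$perpetrator)) {
    pm <- system$opts$perpetrator
    pt <- seq(0, by = pm$interval, length.out = pm$n_doses)
    pt <- pt[pt < t_end]
    ev <- rbind(ev, data.frame(time = pt, type = "perp_dose", meal = NA_real_))
  }
  ev[order(ev$time, match(ev$type, c("reopen", "meal", "dose", "perp_dose"))), ]
}

# -- simulate -----------------------------------------------------------------

#' Simulate a dosing scenario
#'
#' Integrates the assembled system with `deSolve::lsoda`. Discrete events
#' (dose administrations, meal-triggered gallbladder emptying, end of the
#' gallbladder refractory window, perpetrator doses) are handled by
#' restarting the integrator, which keeps the discrete gallbladder/dose
#' logic exact. Output is returned on a regular grid plus the exact event
#' times.
#'
#' @param system a [assemble_pbpk()] system
#' @param regimen a [dose_regimen()]
#' @param t_end simulation horizon, h
#' @param grid_dt output grid spacing, h (default 0.1)
#' @param first_dose_time time of the first dose, h (default 0; used by the
#'   DDI layer to give the perpetrator a pre-treatment phase)
#' @param rtol,atol solver tolerances
#' @param engine `"compiled"` (the C right-hand side, default) or `"R"`
#'   (the reference implementation in R); both produce the same trajectories
#'   and are cross-checked in the test suite
#' @return object of class `pbpk_result` with elements `time` (h), `conc`
#'   (venous plasma, ng/mL), `conc_umol` (umol/L), `states` (matrix of
#'   compartment amounts, umol), `events` (event log data.frame),
#'   `administered` (cumulative administered dose at each time, umol),
#'   `system`, `regimen`
#' @export
simulate_pbpk <- function(system, regimen, t_end, grid_dt = 0.1,
                          first_dose_time = 0, rtol = 1e-8, atol = 1e-9,
                          engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  stopifnot(inherits(system, "pbpk_system"), inherits(regimen, "dose_regimen"))
  check_range(t_end, "t_end", 0, open_lower = TRUE)
  drug <- system$drug
  dose_umol <- mg_to_umol(regimen$dose, drug$molecular_weight)

  if (system$kind == "onecomp") {
    if (regimen$route != "iv") {
      stop("degenerate one-compartment system supports iv dosing only",
           call. = FALSE)
    }
    return(simulate_onecomp(system, regimen, t_end, grid_dt, first_dose_time,
                            rtol, atol))
  }

  ev <- build_timeline(system, regimen, t_end, first_dose_time)
  parms <- base_parms(system, regimen)

  n <- length(system$state_names)
  y <- numeric(n)
  names(y) <- system$state_names
  y[system$idx$el] <- 1
  y[system$idx$eg] <- 1

  bounds <- sort(unique(c(0, ev$time, t_end)))
  out_t <- numeric(0)
  out_y <- NULL
  admin <- numeric(0)
  administered <- 0
  last_meal <- -Inf
  log_rows <- list()

  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]
    t1 <- bounds[k + 1]
    here <- ev[abs(ev$time - t0) < 1e-12, , drop = FALSE]
    for (r in seq_len(nrow(here))) {
      e <- here[r, ]
      if (e$type == "dose") {
        if (regimen$route == "oral") {
          y[system$idx$solid[1]] <- y[system$idx$solid[1]] + dose_umol
          parms$t_last_dose <- t0
        } else {
          y[system$idx$ven] <- y[system$idx$ven] + dose_umol
        }
        administered <- administered + dose_umol
        log_rows[[length(log_rows) + 1]] <-
          data.frame(time = t0, type = "dose", amount = dose_umol)
      } else if (e$type == "meal") {
        content <- y[system$idx$gb]
        y[system$idx$gbe] <- system$ehc$ejection_fraction * content
        parms$gb_filling <- FALSE
        last_meal <- e$meal
        log_rows[[length(log_rows) + 1]] <-
          data.frame(time = t0, type = "gallbladder_emptying",
                     amount = unname(y[system$idx$gbe]))
      } else if (e$type == "reopen") {
        if (abs(e$meal - last_meal) < 1e-9) {   # not superseded by a later meal
          parms$gb_filling <- TRUE
          y[system$idx$gbe] <- 0
          log_rows[[length(log_rows) + 1]] <-
            data.frame(time = t0, type = "gallbladder_refilled", amount = 0)
        }
      } else if (e$type == "perp_dose") {
        pm <- system$opts$perpetrator
        y[system$idx$pg] <- y[system$idx$pg] +
          mg_to_umol(pm$dose, pm$molecular_weight)
        log_rows[[length(log_rows) + 1]] <-
          data.frame(time = t0, type = "perpetrator_dose",
                     amount = mg_to_umol(pm$dose, pm$molecular_weight))
      }
    }

    times <- sort(unique(c(seq(t0, t1, by = grid_dt), t1)))
    sol <- integrate_segment(y, times, parms, rtol, atol, engine)
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf("solver failed to converge; last accepted time %.4g h",
                   max(sol[, 1])), call. = FALSE)
    }
    y <- sol[nrow(sol), -1]
    keep <- if (k == 1) seq_len(nrow(sol)) else -1L
    out_t <- c(out_t, sol[keep, 1])
    out_y <- rbind(out_y, sol[keep, -1, drop = FALSE])
    admin <- c(admin, rep(administered, length(sol[keep, 1])))
  }

  conc_umol <- (out_y[, system$idx$ven] / system$physiology$venous_volume_l) /
    system$bp
  events <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(time = numeric(0), type = character(0), amount = numeric(0))

  structure(
    list(time = out_t,
         conc = conc_umol * drug$molecular_weight,
         conc_umol = conc_umol,
         states = out_y, events = events, administered = admin,
         system = system, regimen = regimen,
         first_dose_time = first_dose_time),
    class = "pbpk_result"
  )
}

base_parms <- function(system, regimen) {
  form <- regimen$formulation
  sol_eff <- system$sol_umol
  form_kind <- if (regimen$route == "iv") "none" else form$kind
  if (form_kind == "solution") {
    sol_eff <- sol_eff * form$solution_solubility_scale
  }
  perp <- system$opts$perpetrator
  list(
    idx = system$idx, nseg = system$nseg,
    gi_vol = system$gi$volume_l, sol_eff = sol_eff,
    kabs = system$kabs, ktr = system$ktr,
    form_kind = form_kind,
    weibull_t50 = if (form_kind %in% c("tablet", "capsule")) form$weibull_t50 else 1,
    weibull_shape = if (form_kind %in% c("tablet", "capsule")) form$weibull_shape else 1,
    form_lag = if (form_kind %in% c("tablet", "capsule")) form$lag_min %||% 0 else 0,
    k_sol = 100,                       # 1/h: near-instant dissolution (solution)
    k_prec = 10,                       # 1/h: precipitation / redissolution
    t_last_dose = 0,
    org_vol = system$org$volume_l, org_q = system$org$flow_l_h,
    drain_tags = system$org$drains,
    kp = unname(system$kp), bp = system$bp, fu = system$fu_eff,
    lung_i = system$lung_i, liver_i = system$liver_i, gut_i = system$gut_i,
    portal_i = system$portal_i, venous_i = system$venous_i,
    co = system$co, q_liver_total = system$q_liver_total,
    v_art = system$physiology$arterial_volume_l,
    v_ven = system$physiology$venous_volume_l,
    kcat_cyp_h = system$kcat_cyp_h, km_cyp = system$drug$km_cyp3a4,
    cyp_liver_amt = system$cyp_liver_amt, cyp_gut_amt = system$cyp_gut_amt,
    kcat_mrp2_h = system$kcat_mrp2_h, km_mrp2 = system$drug$km_mrp2,
    mrp2_amt = system$mrp2_amt,
    ehc_on = isTRUE(system$opts$ehc),
    bile_reabs = system$opts$bile_reabsorption,
    gb_filling = TRUE,
    cont_frac = if (!is.null(system$ehc)) system$ehc$continuous_fraction else 0,
    k_empty = if (!is.null(system$ehc)) {
      log(2) / (system$ehc$emptying_half_time / 60)
    } else 0,
    has_perp = !is.null(perp),
    perp_ka = perp$ka %||% 0, perp_cl = perp$cl %||% 0,
    perp_v = perp$v %||% 1, perp_fu = perp$fu %||% 1,
    perp_emax = perp$emax %||% 0, perp_ec50 = perp$ec50 %||% 1,
    perp_kdeg_liver = perp$kdeg_liver %||% 0,
    perp_kdeg_gut = perp$kdeg_gut %||% 0
  )
}

# flatten the per-segment parameter list into the layout the compiled
# right-hand side expects (see src/pbpk_rhs.c)
pbpk_parms_vector <- function(p) {
  drains_code <- ifelse(p$drain_tags == "portal", 1,
                        ifelse(p$drain_tags == "arterial", 2, 0))
  c(
    length(p$gi_vol), length(p$org_vol), p$lung_i, p$liver_i, p$gut_i,
    switch(p$form_kind, none = 0, solution = 1, 2),
    p$k_sol, p$k_prec, p$weibull_t50, p$weibull_shape, p$form_lag,
    p$t_last_dose, p$bp, p$fu, p$co, p$q_liver_total, p$v_art, p$v_ven,
    p$kcat_cyp_h, p$km_cyp, p$cyp_liver_amt, p$cyp_gut_amt,
    p$kcat_mrp2_h, p$km_mrp2, p$mrp2_amt,
    as.numeric(p$ehc_on), p$bile_reabs, as.numeric(p$gb_filling),
    p$cont_frac, p$k_empty,
    as.numeric(p$has_perp), p$perp_ka, p$perp_cl, p$perp_v, p$perp_fu,
    p$perp_emax, p$perp_ec50, p$perp_kdeg_liver, p$perp_kdeg_gut,
    p$gi_vol, p$sol_eff, p$kabs, p$ktr,
    p$org_vol, p$org_q, drains_code, p$kp
  )
}

integrate_segment <- function(y, times, parms, rtol, atol, engine) {
  if (engine == "compiled") {
    pv <- pbpk_parms_vector(parms)
    .C("set_pbpk_parms", as.double(pv), as.integer(length(pv)),
       PACKAGE = "cabopbpk")
    deSolve::lsoda(y, times, func = "derivs_pbpk", parms = NULL,
                   dllname = "cabopbpk", rtol = rtol, atol = atol)
  } else {
    deSolve::lsoda(y, times, rhs_whole_body, parms, rtol = rtol, atol = atol)
  }
}

simulate_onecomp <- function(system, regimen, t_end, grid_dt, first_dose_time,
                             rtol, atol) {
  dg <- system$degenerate
  dose_umol <- mg_to_umol(regimen$dose, system$drug$molecular_weight)
  dose_times <- first_dose_time +
    seq(0, by = regimen$interval, length.out = regimen$n_doses)
  dose_times <- dose_times[dose_times < t_end]
  bounds <- sort(unique(c(0, dose_times, t_end)))
  y <- c(central = 0, eliminated = 0)
  out_t <- numeric(0)
  out_y <- NULL
  admin <- numeric(0)
  administered <- 0
  log_rows <- list()
  p <- list(cl = dg$clearance_l_h, v = dg$volume_l)
  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    if (any(abs(dose_times - t0) < 1e-12)) {
      y["central"] <- y["central"] + dose_umol
      administered <- administered + dose_umol
      log_rows[[length(log_rows) + 1]] <-
        data.frame(time = t0, type = "dose", amount = dose_umol)
    }
    times <- sort(unique(c(seq(t0, t1, by = grid_dt), t1)))
    sol <- deSolve::lsoda(y, times, rhs_onecomp, p, rtol = rtol, atol = atol)
    y <- sol[nrow(sol), -1]
    keep <- if (k == 1) seq_len(nrow(sol)) else -1L
    out_t <- c(out_t, sol[keep, 1])
    out_y <- rbind(out_y, sol[keep, -1, drop = FALSE])
    admin <- c(admin, rep(administered, length(sol[keep, 1])))
  }
  conc_umol <- out_y[, 1] / dg$volume_l
  structure(
    list(time = out_t, conc = conc_umol * system$drug$molecular_weight,
         conc_umol = conc_umol, states = out_y,
         events = do.call(rbind, log_rows), administered = admin,
         system = system, regimen = regimen,
         first_dose_time = first_dose_time),
    class = "pbpk_result"
  )
}

#' @export
print.pbpk_result <- function(x, ...) {
  cm <- cmax_tmax(data.frame(time = x$time, conc = x$conc))
  cat(sprintf(
    "<pbpk_result> %g mg %s | t %.4g..%.4g h | Cmax %.4g ng/mL at %.3g h | AUC_last %.5g ng*h/mL\n",
    x$regimen$dose,
    if (x$regimen$route == "iv") "iv" else x$regimen$formulation$kind,
    min(x$time), max(x$time), cm[["cmax"]], cm[["tmax"]],
    auc_last(x$time, x$conc)
  ))
  invisible(x)
}

#' @export
as.data.frame.pbpk_result <- function(x, ...) {
  data.frame(time_h = x$time, conc_ng_ml = x$conc)
}

#' Global mass-balance error of a simulation
#'
#' Relative deviation between the administered amount and the sum of all
#' drug-carrying compartments plus cumulative metabolised and fecally
#' excreted amounts, at every output time after the first dose.
#'
#' @param result a [simulate_pbpk()] result
#' @return maximum relative mass-balance error (dimensionless)
#' @export
mass_balance_error <- function(result) {
  stopifnot(inherits(result, "pbpk_result"))
  if (result$system$kind == "onecomp") {
    total <- rowSums(result$states)
  } else {
    total <- rowSums(result$states[, result$system$mass_idx, drop = FALSE])
  }
  ok <- result$administered > 0
  if (!any(ok)) return(0)
  max(abs(total[ok] - result$administered[ok]) / result$administered[ok])
}

#' Per-segment cumulative fraction-of-dose absorbed
#'
#' Fraction of the administered oral dose absorbed in each intestinal
#' segment over time. Only dose-origin drug is counted: drug recirculated in
#' bile is tracked separately by the engine, so each curve is nondecreasing
#' and their sum is bounded by 1.
#'
#' @param result a [simulate_pbpk()] result from an oral regimen
#' @return data.frame with `time` and one column per intestinal segment,
#'   plus `total`
#' @export
fraction_absorbed <- function(result) {
  stopifnot(inherits(result, "pbpk_result"))
  if (result$system$kind == "onecomp" || result$regimen$route != "oral") {
    stop("fraction_absorbed applies to oral whole-body simulations only",
         call. = FALSE)
  }
  sys <- result$system
  dose_total <- max(result$administered)
  f <- result$states[, sys$idx$cumabs, drop = FALSE] / dose_total
  colnames(f) <- sys$gi$name[-1]
  out <- data.frame(time = result$time, f, total = rowSums(f))
  out
}

#' Population simulation with inter-individual variability
#'
#' Simulates an ensemble of virtual individuals drawn by
#' [sample_population()] and summarises the plasma profiles by the pointwise
#' geometric mean and geometric standard deviation band, the convention used
#' for population PBPK plots.
#'
#' @param drug,physiology,ehc model components (base individual)
#' @param regimen a [dose_regimen()]
#' @param t_end horizon, h
#' @param pop a [population_spec()]
#' @param options passed to [assemble_pbpk()]
#' @param grid_dt output grid, h
#' @param ... passed to [simulate_pbpk()]
#' @return object of class `pbpk_population`: list with `time`, `conc`
#'   (individuals x time matrix, ng/mL), `geo_mean`, `geo_sd`, `individuals`
#'   (the sampled parameter sets) and the first individual's full result
#' @export
simulate_population <- function(drug, physiology, ehc, regimen, t_end, pop,
                                options = list(), grid_dt = 0.25, ...) {
  stopifnot(inherits(pop, "population_spec"))
  inds <- sample_population(pop)
  results <- vector("list", length(inds))
  conc <- NULL
  for (i in seq_along(inds)) {
    mod <- apply_individual(drug, physiology, inds[[i]])
    sys <- assemble_pbpk(mod$drug, mod$physiology, ehc, options)
    res <- simulate_pbpk(sys, regimen, t_end, grid_dt = grid_dt, ...)
    if (is.null(conc)) conc <- matrix(0, length(inds), length(res$time))
    conc[i, ] <- res$conc
    results[[i]] <- if (i == 1L) res else NULL
  }
  logc <- log(pmax(conc, .Machine$double.xmin))
  gsd <- if (nrow(logc) > 1) exp(apply(logc, 2, sd)) else
    rep(1, ncol(logc))
  structure(
    list(time = results[[1]]$time, conc = conc,
         geo_mean = exp(colMeans(logc)),
         geo_sd = gsd,
         individuals = inds, first = results[[1]]),
    class = "pbpk_population"
  )
}

#' @export
print.pbpk_population <- function(x, ...) {
  cat(sprintf("<pbpk_population> n = %d, t %.4g..%.4g h\n",
              nrow(x$conc), min(x$time), max(x$time)))
  invisible(x)
}

# apply an individual's multipliers (from sample_population) to the base
# drug/physiology pair
apply_individual <- function(drug, physiology, ind) {
  wr <- ind$weight / ind$weight_ref
  phys <- physiology
  phys$organs$volume_l <- phys$organs$volume_l * wr^1.0
  phys$organs$flow_l_h <- phys$organs$flow_l_h * wr^0.75 * ind$mult$flows
  systemic <- phys$organs$drains %in% c("venous", "portal") |
    phys$organs$name == "liver"
  phys$cardiac_output_l_h <- sum(phys$organs$flow_l_h[systemic])
  d <- drug
  d$kcat_cyp3a4 <- d$kcat_cyp3a4 * ind$mult$kcat_cyp3a4
  d$kcat_mrp2 <- d$kcat_mrp2 * ind$mult$kcat_mrp2
  list(drug = d, physiology = phys)
}
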
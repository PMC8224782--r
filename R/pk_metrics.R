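# Noncompartmental analysis and model-evaluation statistics: trapezoidal
# AUC, Cmax/Tmax, average steady-state concentration, percent prediction
# errors, mean relative deviation, fold-deviation fractions, DDI exposure
# ratios, and least-squares parameter estimation for recovery tests.

#' Observed concentration-time profile
#'
#' Container for an observed (or synthetic "observed") plasma profile with
#' study metadata. Times must be strictly increasing, concentrations
#' non-negative, and at least two points are required.
#'
#' @param time time points, h
#' @param conc concentrations, ng/mL
#' @param study_id study identifier
#' @param arm arm label
#' @param dose dose, mg
#' @param formulation formulation tag
#' @return object of class `observed_profile` (a data.frame with `time` and
#'   `conc` columns and metadata attributes)
#' @export
observed_profile <- function(time, conc, study_id = "study", arm = "arm",
                             dose = NA_real_, formulation = NA_character_) {
  if (length(time) != length(conc)) {
    stop("time and conc must have equal length", call. = FALSE)
  }
  if (length(time) < 2L) stop("a profile needs >= 2 points", call. = FALSE)
  if (any(diff(time) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(conc < 0)) stop("negative concentrations", call. = FALSE)
  structure(
    data.frame(time = time, conc = conc),
    study_id = study_id, arm = arm, dose = dose, formulation = formulation,
    class = c("observed_profile", "data.frame")
  )
}

#' Area under the curve to the last observation
#'
#' Linear trapezoidal rule over all points. Additive over contiguous time
#' partitions.
#'
#' @param time strictly increasing time points, h (or a profile/data.frame
#'   with `time` and `conc` columns, with `conc` omitted)
#' @param conc concentrations
#' @return AUC in conc * time units (ng*h/mL for ng/mL input)
#' @export
auc_last <- function(time, conc) {
  if (missing(conc)) {
    conc <- time$conc
    time <- time$time
  }
  if (length(time) < 2L) stop("AUC needs >= 2 points", call. = FALSE)
  if (any(diff(time) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  sum(diff(time) * (head(conc, -1) + tail(conc, -1)) / 2)
}

#' Peak concentration and its time
#'
#' `cmax` is the maximum observed point; `tmax` its time (ties resolved to
#' the earliest).
#'
#' @param profile data.frame with `time` and `conc` columns
#' @return named numeric vector `c(cmax = , tmax = )`
#' @export
cmax_tmax <- function(profile) {
  i <- which.max(profile$conc)
  c(cmax = profile$conc[i], tmax = profile$time[i])
}

#' Average steady-state concentration over a dosing interval
#'
#' `Css = AUC_tau / tau` over the last simulated dosing interval, computed
#' only once steady state is detected: at least 5 complete intervals must be
#' simulated and the AUC of the last two successive intervals must agree
#' within 1%.
#'
#' @param result a [simulate_pbpk()] result of a multiple-dose regimen (or a
#'   data.frame with `time`/`conc` plus explicit `dose_times`)
#' @param tau dosing interval, h (defaults to the regimen interval)
#' @param dose_times optional explicit dose times, h
#' @return average steady-state concentration, ng/mL
#' @export
css_average <- function(result, tau = NULL, dose_times = NULL) {
  if (inherits(result, "pbpk_result")) {
    tau <- tau %||% result$regimen$interval
    dose_times <- result$events$time[result$events$type == "dose"]
    prof <- data.frame(time = result$time, conc = result$conc)
  } else {
    if (is.null(tau) || is.null(dose_times)) {
      stop("tau and dose_times are required for plain profiles", call. = FALSE)
    }
    prof <- result
  }
  t_max <- max(prof$time)
  complete <- dose_times[dose_times + tau <= t_max + 1e-9]
  if (length(complete) < 5L) {
    stop("steady state not reached: need >= 5 complete dosing intervals",
         call. = FALSE)
  }
  interval_auc <- function(t0) {
    k <- prof$time >= t0 - 1e-9 & prof$time <= t0 + tau + 1e-9
    auc_last(prof$time[k], prof$conc[k])
  }
  n <- length(complete)
  auc_prev <- interval_auc(complete[n - 1])
  auc_lastint <- interval_auc(complete[n])
  if (abs(auc_lastint - auc_prev) / auc_prev > 0.01) {
    stop(sprintf(
      "steady state not reached: successive-interval AUC change %.2f%% > 1%%",
      100 * abs(auc_lastint - auc_prev) / auc_prev), call. = FALSE)
  }
  auc_lastint / tau
}

#' Percent prediction errors
#'
#' Per-point percent prediction error
#' `PE_i = (pred_i - obs_i) / obs_i * 100`, the mean prediction error (MPE,
#' bias) and the mean absolute prediction error (MAPE, precision).
#' Observed zeros (below-quantification points) are excluded and counted.
#'
#' @param pred predicted concentrations
#' @param obs observed concentrations (same length)
#' @return list with `pe` (vector, %), `mpe` (%), `mape` (%), `n`,
#'   `n_excluded`
#' @export
prediction_errors <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("pred and obs must have equal length", call. = FALSE)
  }
  keep <- obs > 0
  n_excl <- sum(!keep)
  pred <- pred[keep]; obs <- obs[keep]
  if (!length(obs)) stop("no usable observed points (all zero)", call. = FALSE)
  pe <- (pred - obs) / obs * 100
  list(pe = pe, mpe = mean(pe), mape = mean(abs(pe)),
       n = length(pe), n_excluded = n_excl)
}

#' Mean relative deviation
#'
#' `MRD = 10^x` with `x = sqrt(mean((log10 pred - log10 obs)^2))` (root mean
#' square of the decadic log deviations). MRD = 1 for a perfect prediction;
#' values <= 2 are conventionally considered adequate. Symmetric in
#' pred/obs and invariant to a common rescaling of both vectors.
#'
#' @param pred,obs strictly positive concentration vectors of equal length
#' @return dimensionless MRD >= 1
#' @export
mrd <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("pred and obs must have equal length", call. = FALSE)
  }
  if (any(pred <= 0) || any(obs <= 0)) {
    stop("MRD requires strictly positive concentrations", call. = FALSE)
  }
  10^sqrt(mean((log10(pred) - log10(obs))^2))
}

#' DDI exposure ratios
#'
#' `AUC_last` and `Cmax` of the victim given with the perpetrator divided by
#' the victim given alone.
#'
#' @param with_perp profile (data.frame with `time`, `conc`) or a list with
#'   precomputed `auc_last` and `cmax` elements, perpetrator arm
#' @param alone same, control arm
#' @return named numeric vector `c(auc_ratio =, cmax_ratio =)`
#' @export
ddi_ratios <- function(with_perp, alone) {
  summarise <- function(x) {
    if (is.list(x) && !is.data.frame(x) && !is.null(x$auc_last)) {
      c(auc = x$auc_last, cmax = x$cmax)
    } else {
      c(auc = auc_last(x$time, x$conc), cmax = cmax_tmax(x)[["cmax"]])
    }
  }
  a <- summarise(with_perp)
  b <- summarise(alone)
  if (any(b == 0)) stop("zero denominator in DDI ratio", call. = FALSE)
  c(auc_ratio = unname(a["auc"] / b["auc"]),
    cmax_ratio = unname(a["cmax"] / b["cmax"]))
}

#' Fractions of predictions within fold-deviation bounds
#'
#' Fraction of points with `max(pred/obs, obs/pred) <= threshold`, for the
#' conventional 2-fold and 1.25-fold goodness-of-fit bounds. The bound is
#' inclusive: a point exactly at the threshold counts as within.
#'
#' @param pred,obs strictly positive concentration vectors of equal length
#' @return named numeric vector `c(within_2fold =, within_1.25fold =)`
#' @export
fold_fractions <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("pred and obs must have equal length", call. = FALSE)
  }
  if (any(pred <= 0) || any(obs <= 0)) {
    stop("fold fractions require strictly positive values", call. = FALSE)
  }
  fold <- pmax(pred / obs, obs / pred)
  c(within_2fold = mean(fold <= 2),
    within_1.25fold = mean(fold <= 1.25))
}

#' Full evaluation report for predicted vs observed profiles
#'
#' Bundles the standard evaluation statistics: per-point percent errors,
#' MPE, MAPE, MRD, fold-deviation fractions and predicted/observed
#' `AUC_last` and `Cmax` ratios.
#'
#' @param pred predicted profile (data.frame `time`, `conc`); evaluated at
#'   the observed times by linear interpolation if the grids differ
#' @param obs observed profile ([observed_profile()] or data.frame)
#' @return object of class `evaluation_report`
#' @export
evaluate_predictions <- function(pred, obs) {
  pc <- if (isTRUE(all.equal(pred$time, obs$time))) {
    pred$conc
  } else {
    approx(pred$time, pred$conc, xout = obs$time, rule = 2)$y
  }
  keep <- obs$conc > 0
  pe <- prediction_errors(pc, obs$conc)
  structure(
    list(pe = pe$pe, mpe = pe$mpe, mape = pe$mape,
         mrd = mrd(pc[keep], obs$conc[keep]),
         folds = fold_fractions(pc[keep], obs$conc[keep]),
         auc_ratio = auc_last(obs$time, pc) / auc_last(obs$time, obs$conc),
         cmax_ratio = cmax_tmax(data.frame(time = obs$time, conc = pc))[["cmax"]] /
           cmax_tmax(obs)[["cmax"]],
         n = pe$n, n_excluded = pe$n_excluded),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  n = %d (excluded: %d)\n", x$n, x$n_excluded))
  cat(sprintf("  MPE %.1f%% | MAPE %.1f%% | MRD %.3f\n", x$mpe, x$mape, x$mrd))
  cat(sprintf("  within 2-fold: %.1f%% | within 1.25-fold: %.1f%%\n",
              100 * x$folds[["within_2fold"]],
              100 * x$folds[["within_1.25fold"]]))
  cat(sprintf("  AUC_last ratio %.3f | Cmax ratio %.3f\n",
              x$auc_ratio, x$cmax_ratio))
  invisible(x)
}

#' Local maxima of a concentration profile
#'
#' Identifies interior local maxima with a prominence filter, used to detect
#' enterohepatic secondary peaks. A point is reported when it is the maximum
#' of a centred window and exceeds the deepest trough separating it from the
#' global maximum by the given relative prominence.
#'
#' @param time,conc profile vectors
#' @param after ignore maxima at or before this time, h
#' @param prominence minimal relative prominence (fraction of Cmax)
#' @return data.frame `time`, `conc` of the detected secondary maxima
#' @export
secondary_peaks <- function(time, conc, after = 0, prominence = 0.005) {
  n <- length(conc)
  if (n < 3L) return(data.frame(time = numeric(0), conc = numeric(0)))
  cmax <- max(conc)
  imax <- which.max(conc)
  cand <- which(diff(sign(diff(conc))) < 0) + 1L
  cand <- cand[time[cand] > after & cand != imax]
  keep <- vapply(cand, function(i) {
    lo <- min(i, imax); hi <- max(i, imax)
    trough <- min(conc[lo:hi])
    (conc[i] - trough) >= prominence * cmax
  }, logical(1))
  cand <- cand[keep]
  data.frame(time = time[cand], conc = conc[cand])
}

# -- parameter estimation -----------------------------------------------------

#' Least-squares parameter estimation against observed profiles
#'
#' Minimises the sum of squared decadic-log deviations
#' `sum((log10 pred - log10 obs)^2)` over one or more free model parameters
#' with a bounded local optimiser (golden-section [stats::optimize()] for a
#' single parameter, `L-BFGS-B` [stats::optim()] otherwise). Deterministic
#' given the start point. Zero observed concentrations are excluded.
#'
#' @param objective_fn function(named parameter vector) returning a
#'   predicted profile `data.frame(time, conc)` on the observed time grid;
#'   typically a closure around [assemble_pbpk()]/[simulate_pbpk()]
#' @param profiles an [observed_profile()] or list of them
#' @param free named list of parameter bounds: `list(name = c(lower, upper))`
#' @param start named numeric start values (defaults to the bound midpoints)
#' @return list with `estimates` (named numeric), `objective` (minimised
#'   value), `convergence` (0 = success) and `details`
#' @export
fit_parameters <- function(objective_fn, profiles, free, start = NULL) {
  if (inherits(profiles, "observed_profile") || is.data.frame(profiles)) {
    profiles <- list(profiles)
  }
  if (!length(free)) stop("no free parameters given", call. = FALSE)
  bounds <- do.call(rbind, free)
  if (any(!is.finite(bounds))) stop("bounds must be finite", call. = FALSE)
  pn <- names(free)
  if (is.null(start)) start <- setNames(rowMeans(bounds), pn)

  obj <- function(theta) {
    names(theta) <- pn
    sse <- 0
    takes_profile <- length(formals(objective_fn)) >= 2L
    for (prof in profiles) {
      pred <- if (takes_profile) objective_fn(theta, prof) else objective_fn(theta)
      keep <- prof$conc > 0 & pred$conc > 0
      if (!any(keep)) return(1e10)
      sse <- sse +
        sum((log10(pred$conc[keep]) - log10(prof$conc[keep]))^2)
    }
    if (!is.finite(sse)) 1e10 else sse
  }

  if (length(pn) == 1L) {
    o <- optimize(obj, lower = bounds[1, 1], upper = bounds[1, 2],
                  tol = .Machine$double.eps^0.35)
    list(estimates = setNames(o$minimum, pn), objective = o$objective,
         convergence = 0L, details = o)
  } else {
    o <- optim(unlist(start), obj, method = "L-BFGS-B",
               lower = bounds[, 1], upper = bounds[, 2])
    if (o$convergence != 0) {
      warning("optimizer reported non-convergence (code ", o$convergence,
              "); returning best-so-far", call. = FALSE)
    }
    list(estimates = setNames(o$par, pn), objective = o$value,
         convergence = o$convergence, details = o)
  }
}

#' @importFrom utils head tail
NULL
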
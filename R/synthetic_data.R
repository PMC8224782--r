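# Virtual populations and synthetic "observed" study data. The generator
# emulates the statistical structure the analysis assumes for single-dose
# oral studies: lognormal inter-individual variability on enzyme/transporter
# turnover and flows, multiplicative lognormal residual noise, LLOQ
# censoring, and the enterohepatic secondary-peak structure produced by the
# model itself.

#' Virtual population specification
#'
#' @param n number of individuals, >= 1
#' @param weight_range body weight range, kg (uniform draw)
#' @param age_range age range, years (uniform draw; demographic metadata)
#' @param height_range height range, cm (demographic metadata)
#' @param sex `"male"`, `"female"` or `"both"`
#' @param cv named list of lognormal coefficients of variation for
#'   parameter multipliers: `kcat_cyp3a4`, `kcat_mrp2`, `flows`
#' @param weight_ref reference body weight of the base individual, kg;
#'   organ volumes scale with (weight/weight_ref)^1 and flows with
#'   (weight/weight_ref)^0.75
#' @param seed RNG seed
#' @return object of class `population_spec`
#' @export
population_spec <- function(n = 100,
                            weight_range = c(60, 95),
                            age_range = c(20, 50),
                            height_range = c(160, 190),
                            sex = "both",
                            cv = list(kcat_cyp3a4 = 0.3, kcat_mrp2 = 0.3,
                                      flows = 0.15),
                            weight_ref = 73.96,
                            seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  for (r in list(weight_range, age_range, height_range)) {
    if (length(r) != 2L || r[1] > r[2] || any(r <= 0)) {
      stop("impossible covariate range", call. = FALSE)
    }
  }
  if (any(unlist(cv) < 0)) stop("CVs must be >= 0", call. = FALSE)
  sex <- match.arg(sex, c("both", "male", "female"))
  structure(
    list(n = n, weight_range = weight_range, age_range = age_range,
         height_range = height_range, sex = sex,
         cv = modifyList(list(kcat_cyp3a4 = 0, kcat_mrp2 = 0, flows = 0), cv),
         weight_ref = weight_ref, seed = as.integer(seed)),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf(
    "<population_spec> n = %d | weight %g-%g kg | CV: cyp %.2g, mrp2 %.2g, flows %.2g | seed %d\n",
    x$n, x$weight_range[1], x$weight_range[2],
    x$cv$kcat_cyp3a4, x$cv$kcat_mrp2, x$cv$flows, x$seed
  ))
  invisible(x)
}

#' Residual noise model for synthetic observations
#'
#' @param sigma lognormal residual standard deviation (log scale), >= 0
#' @param lloq lower limit of quantification, ng/mL (values below are
#'   censored), >= 0
#' @param schedule sampling time schedule, h
#' @return object of class `noise_model`
#' @export
noise_model <- function(sigma = 0.1, lloq = 1,
                        schedule = c(0.5, 1, 2, 3, 4, 5, 8, 12, 24, 48, 72,
                                     96, 168, 240, 336, 504)) {
  check_range(sigma, "sigma", 0)
  check_range(lloq, "lloq", 0)
  if (any(diff(schedule) <= 0) || any(schedule < 0)) {
    stop("schedule must be nonnegative and strictly increasing", call. = FALSE)
  }
  structure(list(sigma = sigma, lloq = lloq, schedule = schedule),
            class = "noise_model")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Draw a virtual population
#'
#' Reproducibly draws individual parameter sets: anthropometrics uniform
#' within the stated ranges, organ volumes scaled linearly and blood flows
#' allometrically (exponent 0.75) with body weight, and lognormal multipliers
#' (median 1) with the stated CVs on `kcat_cyp3a4`, `kcat_mrp2` and flows.
#'
#' @param spec a [population_spec()]
#' @return list of individual parameter sets; each has `weight`, `age`,
#'   `height`, `sex`, `weight_ref` and `mult` (named multipliers)
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n), function(i) {
      sdlog <- function(cv) sqrt(log(1 + cv^2))
      draw <- function(cv) if (cv > 0) rlnorm(1, 0, sdlog(cv)) else 1
      list(
        id = i,
        weight = runif(1, spec$weight_range[1], spec$weight_range[2]),
        age = runif(1, spec$age_range[1], spec$age_range[2]),
        height = runif(1, spec$height_range[1], spec$height_range[2]),
        sex = if (spec$sex == "both") {
          sample(c("male", "female"), 1)
        } else spec$sex,
        weight_ref = spec$weight_ref,
        mult = list(
          kcat_cyp3a4 = draw(spec$cv$kcat_cyp3a4),
          kcat_mrp2 = draw(spec$cv$kcat_mrp2),
          flows = draw(spec$cv$flows)
        )
      )
    })
  })
}

#' Synthesize an "observed" study dataset
#'
#' Simulates each virtual individual under the given regimen, samples the
#' plasma profile at the schedule, applies multiplicative lognormal residual
#' noise, censors observations below the LLOQ (set to zero), and returns the
#' profiles together with a ground-truth record of every individual's
#' generating parameters, enabling parameter-recovery tests.
#'
#' @param drug,physiology,ehc base model components
#' @param regimen a [dose_regimen()]
#' @param pop a [population_spec()]
#' @param noise a [noise_model()]
#' @param seed residual-noise seed (population draws use `pop$seed`)
#' @param options passed to [assemble_pbpk()]
#' @param grid_dt simulation output grid, h
#' @param ... passed to [simulate_pbpk()]
#' @return list with `profiles` (list of [observed_profile()]),
#'   `ground_truth` (data.frame of generating parameters per individual)
#'   and `t_end`
#' @export
synthesize_study <- function(drug, physiology, ehc, regimen, pop, noise,
                             seed = 1L, options = list(), grid_dt = 0.25,
                             ...) {
  stopifnot(inherits(noise, "noise_model"))
  t_end <- max(noise$schedule)
  inds <- sample_population(pop)
  profiles <- vector("list", length(inds))
  gt <- vector("list", length(inds))
  with_seed(seed, {
    for (i in seq_along(inds)) {
      mod <- apply_individual(drug, physiology, inds[[i]])
      sys <- assemble_pbpk(mod$drug, mod$physiology, ehc, options)
      res <- simulate_pbpk(sys, regimen, t_end, grid_dt = grid_dt, ...)
      if (max(noise$schedule) > max(res$time) + 1e-9) {
        stop("sampling schedule extends beyond the simulated horizon",
             call. = FALSE)
      }
      ctrue <- approx(res$time, res$conc, xout = noise$schedule, rule = 2)$y
      eps <- if (noise$sigma > 0) {
        exp(rnorm(length(ctrue), 0, noise$sigma))
      } else rep(1, length(ctrue))
      cobs <- ctrue * eps
      cobs[cobs < noise$lloq] <- 0
      profiles[[i]] <- observed_profile(
        noise$schedule, cobs,
        study_id = "synthetic", arm = sprintf("ind%03d", i),
        dose = regimen$dose,
        formulation = if (regimen$route == "iv") "iv" else
          regimen$formulation$kind
      )
      gt[[i]] <- data.frame(
        id = i, weight = inds[[i]]$weight,
        kcat_cyp3a4 = mod$drug$kcat_cyp3a4,
        kcat_mrp2 = mod$drug$kcat_mrp2,
        flow_mult = inds[[i]]$mult$flows
      )
    }
  })
  list(profiles = profiles, ground_truth = do.call(rbind, gt), t_end = t_end)
}

# -- profile CSV I/O ----------------------------------------------------------

#' Write observed profiles to CSV
#'
#' Schema: `study_id, arm, time_h, conc_ng_ml, dose_mg, formulation` — one
#' row per observation, profiles identified by (study_id, arm). The round
#' trip through [read_profile_csv()] is lossless.
#'
#' @param profiles an [observed_profile()] or list of them
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_profile_csv <- function(profiles, path) {
  if (inherits(profiles, "observed_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(
      study_id = attr(p, "study_id"), arm = attr(p, "arm"),
      time_h = p$time, conc_ng_ml = p$conc,
      dose_mg = attr(p, "dose"), formulation = attr(p, "formulation"),
      stringsAsFactors = FALSE
    )
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read observed profiles from CSV
#'
#' Inverse of [write_profile_csv()]. Malformed rows (missing fields,
#' non-numeric values, non-increasing times within a profile) raise errors
#' naming the offending line.
#'
#' @param path CSV file path
#' @return list of [observed_profile()] objects
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty profile file: ", path, call. = FALSE)
  need <- c("study_id", "arm", "time_h", "conc_ng_ml", "dose_mg",
            "formulation")
  if (!all(need %in% names(raw))) {
    stop("missing column(s): ", paste(setdiff(need, names(raw)),
                                      collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(raw$time_h) | !is.finite(raw$conc_ng_ml))
  if (length(bad)) {
    stop("malformed numeric value at data line ", bad[1] + 1L, call. = FALSE)
  }
  key <- paste(raw$study_id, raw$arm, sep = "\r")
  lapply(split(seq_len(nrow(raw)), key)[unique(key)], function(ii) {
    d <- raw[ii, ]
    if (any(diff(d$time_h) <= 0)) {
      stop("non-monotone times for arm `", d$arm[1], "` near data line ",
           ii[which(diff(d$time_h) <= 0)[1] + 1L] + 1L, call. = FALSE)
    }
    observed_profile(d$time_h, d$conc_ng_ml, study_id = d$study_id[1],
                     arm = d$arm[1], dose = d$dose_mg[1],
                     formulation = d$formulation[1])
  })
}

#' Generate the packaged demo study fixture
#'
#' Emits a small seeded synthetic study (three single-dose tablet arms,
#' n individuals each) used by examples and the test suite, plus its
#' ground-truth sidecar.
#'
#' @param dir output directory
#' @param doses dose arms, mg
#' @param n individuals per arm
#' @param seed RNG seed
#' @return named character vector of the files written
#' @export
make_fixtures <- function(dir = tempdir(), doses = c(20, 60, 140), n = 8,
                          seed = 20260101L) {
  cfg <- cab_defaults()
  files <- c()
  all_profiles <- list()
  gts <- list()
  for (d in doses) {
    reg <- dose_regimen(d, cfg$formulations$tablet, "oral")
    st <- synthesize_study(
      cfg$drug, cfg$physiology, cfg$ehc, reg,
      population_spec(n = n, seed = seed + d),
      noise_model(sigma = 0.1, lloq = 0.5,
                  schedule = c(0.5, 1, 2, 3, 4, 5, 8, 12, 24, 48, 72, 96)),
      seed = seed + d + 1L
    )
    st$profiles <- lapply(st$profiles, function(p) {
      attr(p, "arm") <- sprintf("%dmg_%s", d, attr(p, "arm"))
      p
    })
    all_profiles <- c(all_profiles, st$profiles)
    gt <- st$ground_truth
    gt$dose_mg <- d
    gts[[as.character(d)]] <- gt
  }
  prof_file <- file.path(dir, "synthetic_study.csv")
  gt_file <- file.path(dir, "synthetic_study_truth.csv")
  write_profile_csv(all_profiles, prof_file)
  write.csv(do.call(rbind, gts), gt_file, row.names = FALSE)
  c(profiles = prof_file, ground_truth = gt_file)
}
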
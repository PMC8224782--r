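test_that("population sampling is reproducible, sized and range-respecting", {
  spec <- population_spec(n = 25, seed = 99)
  pop1 <- sample_population(spec)
  pop2 <- sample_population(spec)
  expect_length(pop1, 25)
  expect_identical(pop1, pop2)
  pop3 <- sample_population(population_spec(n = 25, seed = 100))
  expect_false(identical(pop1, pop3))
  w <- vapply(pop1, `[[`, numeric(1), "weight")
  expect_true(all(w >= 60 & w <= 95))
  # zero CVs: all multipliers exactly one
  pop0 <- sample_population(
    population_spec(n = 5, cv = list(kcat_cyp3a4 = 0, kcat_mrp2 = 0,
                                     flows = 0), seed = 1)
  )
  m <- t(vapply(pop0, function(i) unlist(i$mult), numeric(3)))
  expect_true(all(m == 1))
  expect_error(population_spec(n = 0), "n must be")
  expect_error(population_spec(weight_range = c(90, 60)), "range")
})

test_that("lognormal multipliers have median one and the requested spread", {
  spec <- population_spec(n = 2000, cv = list(kcat_cyp3a4 = 0.3), seed = 5)
  pop <- sample_population(spec)
  m <- vapply(pop, function(i) i$mult$kcat_cyp3a4, numeric(1))
  # law-of-large-numbers check on the log scale
  expect_equal(mean(log(m)), 0, tolerance = 3 * sqrt(log(1.09)) / sqrt(2000))
  expect_equal(sd(log(m)), sqrt(log(1 + 0.3^2)), tolerance = 0.02)
})

test_that("synthetic studies are deterministic, censored, and noise-free at sigma 0", {
  cfg <- cab_cfg()
  reg <- dose_regimen(60, cfg$formulations$tablet, "oral")
  nm <- noise_model(sigma = 0, lloq = 0,
                    schedule = c(1, 2, 4, 8, 12, 24))
  pop1 <- population_spec(n = 1, weight_range = c(73.96, 73.96),
                          cv = list(kcat_cyp3a4 = 0, kcat_mrp2 = 0, flows = 0),
                          seed = 3)
  st <- synthesize_study(cfg$drug, cfg$physiology, cfg$ehc, reg, pop1, nm,
                         seed = 3, grid_dt = 0.25)
  ref <- simulate_pbpk(default_system(), reg, 24, grid_dt = 0.25)
  expect_equal(st$profiles[[1]]$conc,
               approx(ref$time, ref$conc, xout = nm$schedule)$y,
               tolerance = 1e-10)
  expect_equal(st$ground_truth$kcat_cyp3a4, cfg$drug$kcat_cyp3a4)
  # determinism under (spec, seed)
  st2 <- synthesize_study(cfg$drug, cfg$physiology, cfg$ehc, reg, pop1, nm,
                          seed = 3, grid_dt = 0.25)
  expect_identical(st$profiles, st2$profiles)
  # LLOQ censoring sets sub-quantification observations to zero
  nm2 <- noise_model(sigma = 0, lloq = 1e6, schedule = c(1, 2, 4))
  stc <- synthesize_study(cfg$drug, cfg$physiology, cfg$ehc, reg, pop1, nm2,
                          seed = 3, grid_dt = 0.5)
  expect_true(all(stc$profiles[[1]]$conc == 0))
  # schedule beyond horizon is impossible by construction (t_end = max(schedule)),
  # and the generator flags invalid schedules
  expect_error(noise_model(schedule = c(4, 2)), "increasing")
})

test_that("residual log-noise is centred (law of large numbers)", {
  set.seed(123)
  draws <- rnorm(1e4, 0, 0.1)
  expect_lt(abs(mean(draws)), 3 * 0.1 / sqrt(1e4))
})

test_that("profile CSV round trip is lossless and validation is line-aware", {
  cfg <- cab_cfg()
  p1 <- observed_profile(c(1, 2, 4), c(10, 8, 5), study_id = "s1", arm = "a",
                         dose = 60, formulation = "tablet")
  p2 <- observed_profile(c(0.5, 3), c(2, 7), study_id = "s1", arm = "b",
                         dose = 20, formulation = "capsule")
  path <- file.path(tempdir(), "profiles.csv")
  write_profile_csv(list(p1, p2), path)
  back <- read_profile_csv(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$time, p1$time)
  expect_equal(back[[1]]$conc, p1$conc)
  expect_equal(attr(back[[2]], "dose"), 20)
  unlink(path)

  # non-monotone times are rejected with a line reference
  bad <- file.path(tempdir(), "bad.csv")
  writeLines(c("study_id,arm,time_h,conc_ng_ml,dose_mg,formulation",
               "s,x,1,10,60,tablet", "s,x,1,9,60,tablet"), bad)
  expect_error(read_profile_csv(bad), "non-monotone")
  unlink(bad)
  # empty input is an explicit error
  empty <- file.path(tempdir(), "empty.csv")
  writeLines("study_id,arm,time_h,conc_ng_ml,dose_mg,formulation", empty)
  expect_error(read_profile_csv(empty), "empty")
  unlink(empty)
})

test_that("the default study scenario shows a post-meal secondary peak", {
  cfg <- cab_cfg()
  r <- simulate_pbpk(default_system(),
                     dose_regimen(140, cfg$formulations$tablet, "oral"),
                     48, grid_dt = 0.1)
  peaks <- secondary_peaks(r$time, r$conc, after = 4)
  expect_gt(nrow(peaks), 0)
  # at least one secondary maximum within a few hours of a meal event
  meals <- meal_schedule(cfg$ehc, 48)
  expect_true(any(vapply(peaks$time, function(tp) {
    any(tp > meals & tp < meals + 3)
  }, logical(1))))
})
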
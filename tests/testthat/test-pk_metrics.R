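test_that("trapezoidal AUC: triangles, constants, partitions and a closed form", {
  expect_equal(auc_last(c(0, 10), c(5, 5)), 50)
  expect_equal(auc_last(c(0, 1), c(0, 2)), 1)
  # additivity over contiguous partitions
  tt <- sort(runif(30, 0, 24))
  cc <- runif(30, 1, 100)
  expect_equal(auc_last(tt, cc),
               auc_last(tt[1:12], cc[1:12]) + auc_last(tt[12:30], cc[12:30]))
  # dense exponential decay vs analytic integral
  tt <- seq(0, 10, by = 0.01)
  cc <- 100 * exp(-0.3 * tt)
  expect_equal(auc_last(tt, cc), 100 / 0.3 * (1 - exp(-3)), tolerance = 1e-4)
  expect_error(auc_last(1, 5), ">= 2 points")
  expect_error(auc_last(c(0, 0), c(1, 1)), "increasing")
})

test_that("Cmax/Tmax with earliest-tie rule; monotone profile peaks at start", {
  expect_equal(cmax_tmax(data.frame(time = c(0, 1, 2), conc = c(1, 5, 3))),
               c(cmax = 5, tmax = 1))
  expect_equal(cmax_tmax(data.frame(time = c(0, 1, 2), conc = c(5, 5, 3))),
               c(cmax = 5, tmax = 0))
  expect_equal(cmax_tmax(data.frame(time = 1:4, conc = c(9, 7, 5, 3)))[["tmax"]],
               1)
})

test_that("Css requires detected steady state and matches superposition", {
  # constant concentration: Css equals it
  prof <- data.frame(time = seq(0, 144, by = 0.5), conc = 7)
  expect_equal(css_average(prof, tau = 24, dose_times = seq(0, 120, by = 24)), 7)
  # one-compartment multiple dosing vs the closed-form superposition
  sys <- onecomp_system(v = 40, cl = 2)          # t1/2 = 13.9 h
  reg <- dose_regimen(100, route = "iv", interval = 24, n_doses = 10)
  r <- simulate_pbpk(sys, reg, 240, grid_dt = 0.05)
  css <- css_average(r)
  expect_equal(css, 1e8 / (2 * 24 * 1e3), tolerance = 5e-3)
  mw <- cab_cfg()$drug$molecular_weight
  expected <- onecomp_superposition(r$time, 100e3 / mw, 40, 2, 24, 10) * mw
  # at an exact dose instant the engine reports the pre-dose state; compare
  # away from the jump points
  dose_times <- seq(0, by = 24, length.out = 10)
  away <- !vapply(r$time, function(t) any(abs(t - dose_times) < 1e-9),
                  logical(1))
  expect_equal(r$conc[away], unname(expected[away]), tolerance = 1e-4)
  # too few intervals -> diagnostic error
  r2 <- simulate_pbpk(sys, dose_regimen(100, route = "iv", interval = 24,
                                        n_doses = 3), 72, grid_dt = 0.1)
  expect_error(css_average(r2), ">= 5")
  # intervals present but still accumulating -> steady-state error
  slow <- onecomp_system(v = 400, cl = 1)        # t1/2 = 277 h
  r3 <- simulate_pbpk(slow, dose_regimen(100, route = "iv", interval = 24,
                                         n_doses = 7), 168, grid_dt = 0.1)
  expect_error(css_average(r3), "steady state not reached")
})

test_that("prediction errors follow their definitions and exclude zeros", {
  pe <- prediction_errors(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pe$pe, c(0, 0, 0))
  expect_equal(pe$mpe, 0)
  expect_equal(pe$mape, 0)
  pe <- prediction_errors(c(2, 0.5), c(1, 1))
  expect_equal(pe$pe, c(100, -50))
  expect_equal(pe$mpe, 25)
  expect_equal(pe$mape, 75)
  # MAPE >= |MPE| on random vectors
  set.seed(42)
  for (i in 1:20) {
    p <- runif(15, 0.1, 10); o <- runif(15, 0.1, 10)
    r <- prediction_errors(p, o)
    expect_gte(r$mape, abs(r$mpe))
  }
  z <- prediction_errors(c(1, 2, 3), c(1, 0, 3))
  expect_equal(z$n, 2)
  expect_equal(z$n_excluded, 1)
  expect_error(prediction_errors(1:3, 1:2), "equal length")
})

test_that("MRD: identity, decade shift, hand example, symmetry, scale invariance", {
  expect_equal(mrd(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(mrd(10 * c(1, 5, 9), c(1, 5, 9)), 10)
  # hand evaluation: x = sqrt(mean(log10(1/2)^2, log10(2)^2)) = 0.30103
  expect_equal(mrd(c(1, 10), c(2, 5)), 2.0)
  set.seed(7)
  p <- runif(10, 0.5, 5); o <- runif(10, 0.5, 5)
  expect_equal(mrd(p, o), mrd(o, p))
  expect_equal(mrd(p, o), mrd(1000 * p, 1000 * o))
  expect_gte(mrd(p, o), 1)
  expect_error(mrd(c(1, -1), c(1, 1)), "positive")
})

test_that("DDI ratios from profiles and from printed exposure summaries", {
  prof <- data.frame(time = 0:10, conc = 10 * exp(-0.2 * (0:10)))
  expect_equal(unname(ddi_ratios(prof, prof)), c(1, 1))
  r <- ddi_ratios(list(auc_last = 13624.61, cmax = 480.46),
                  list(auc_last = 59738.08, cmax = 551.17))
  expect_equal(round(r[["auc_ratio"]], 2), 0.23)
  expect_equal(round(r[["cmax_ratio"]], 2), 0.87)
  expect_error(ddi_ratios(prof, data.frame(time = 0:2, conc = c(0, 0, 0))),
               "zero denominator")
})

test_that("fold fractions count inclusively at the boundary", {
  expect_equal(unname(fold_fractions(c(1, 2, 3), c(1, 2, 3))), c(1, 1))
  expect_equal(fold_fractions(c(1, 1, 1, 3), c(1, 1, 1, 1))[["within_2fold"]],
               0.75)
  # exactly 2-fold counts as within (closed bound)
  expect_equal(fold_fractions(2, 1)[["within_2fold"]], 1)
  expect_equal(fold_fractions(1.25, 1)[["within_1.25fold"]], 1)
  expect_equal(fold_fractions(1.26, 1)[["within_1.25fold"]], 0)
})

test_that("evaluation report bundles the statistics coherently", {
  obs <- observed_profile(c(1, 2, 4, 8, 24), c(100, 80, 60, 40, 10))
  pred <- data.frame(time = c(1, 2, 4, 8, 24), conc = c(110, 75, 65, 35, 12))
  rep <- evaluate_predictions(pred, obs)
  expect_gte(rep$mape, abs(rep$mpe))
  expect_gte(rep$mrd, 1)
  expect_lte(rep$mrd, 2)
  expect_equal(unname(rep$folds[["within_2fold"]]), 1)
})

test_that("parameter fitting recovers a known decay constant", {
  tt <- c(0.5, 1, 2, 4, 8, 16, 24)
  truth <- 0.25
  obs <- observed_profile(tt, 100 * exp(-truth * tt))
  fit <- fit_parameters(
    function(theta) data.frame(time = tt, conc = 100 * exp(-theta[["k"]] * tt)),
    obs, free = list(k = c(0.01, 2))
  )
  expect_equal(unname(fit$estimates[["k"]]), truth, tolerance = 1e-4)
  expect_lt(fit$objective, 1e-10)
  # two-parameter variant through the bounded multivariate path
  obs2 <- observed_profile(tt, 80 * exp(-0.1 * tt))
  fit2 <- fit_parameters(
    function(theta) data.frame(time = tt,
                               conc = theta[["c0"]] * exp(-theta[["k"]] * tt)),
    obs2, free = list(c0 = c(10, 200), k = c(0.01, 1)),
    start = c(c0 = 50, k = 0.3)
  )
  expect_equal(unname(fit2$estimates), c(80, 0.1), tolerance = 1e-3)
})
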
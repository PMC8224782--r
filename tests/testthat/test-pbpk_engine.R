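test_that("assembly validates topology and elimination routes", {
  cfg <- cab_cfg()
  sys <- default_system()
  # no renal elimination of parent: the state layout has no urinary sink;
  # the only cumulative elimination states are liver/gut metabolism and the
  # fecal route, and they account for all mass lost from the body
  expect_false(any(grepl("urine|renal", sys$state_names)))
  r <- sim_tablet_96h()
  sink_ix <- c(r$system$idx$metl, r$system$idx$metg, r$system$idx$fecal)
  sinks <- r$states[nrow(r$states), sink_ix]
  body <- sum(r$states[nrow(r$states), setdiff(r$system$mass_idx, sink_ix)])
  expect_equal(unname(max(r$administered) - body), unname(sum(sinks)),
               tolerance = 1e-6)
  expect_true(all(sinks > 0))
  # empty organ set is a topology error
  broken <- cfg$physiology
  broken$organs <- broken$organs[0, ]
  expect_error(assemble_pbpk(cfg$drug, broken, cfg$ehc), "empty organ set|liver")
})

test_that("zero dose yields an identically zero profile", {
  cfg <- cab_cfg()
  r <- simulate_pbpk(default_system(),
                     dose_regimen(0, cfg$formulations$tablet, "oral"),
                     24, grid_dt = 0.5)
  expect_equal(max(abs(r$conc)), 0)
})

test_that("with all clearance processes disabled an iv bolus is conserved", {
  cfg <- cab_cfg()
  d <- cfg$drug
  d$kcat_cyp3a4 <- 0
  sys <- assemble_pbpk(d, cfg$physiology, cfg$ehc, list(mrp2 = FALSE))
  r <- simulate_pbpk(sys, dose_regimen(100, route = "iv"), 48, grid_dt = 0.5)
  total <- rowSums(r$states[, sys$mass_idx])
  expect_equal(max(abs(total - max(r$administered))) / max(r$administered), 0,
               tolerance = 1e-6)
})

test_that("the degenerate one-compartment limit matches closed forms", {
  sys <- onecomp_system(v = 50, cl = 3)
  reg <- dose_regimen(100, route = "iv")
  r <- simulate_pbpk(sys, reg, 400, grid_dt = 0.1)
  # C(0) = D/V : 100 mg / 50 L = 2000 ng/mL
  expect_equal(r$conc[1], 2000, tolerance = 1e-3)
  # AUC_inf = D/CL = 100 mg / 3 L/h = 33333 ng*h/mL (400 h ~ 35 half-lives)
  expect_equal(auc_last(r$time, r$conc), 1e8 / 3 / 1e3, tolerance = 1e-3)
  # whole profile against the analytic solution
  dose_umol <- 100 * 1000 / cab_cfg()$drug$molecular_weight
  expected <- onecomp_conc(r$time, dose_umol, 50, 3) *
    cab_cfg()$drug$molecular_weight
  expect_equal(r$conc, unname(expected), tolerance = 1e-4)
  expect_error(simulate_pbpk(sys, dose_regimen(100, cab_cfg()$formulations$tablet,
                                               "oral"), 24),
               "iv dosing only")
})

test_that("AUC is dose-proportional below enzyme and solubility saturation", {
  cfg <- cab_cfg()
  sys <- default_system()
  r1 <- simulate_pbpk(sys, dose_regimen(0.5, cfg$formulations$tablet, "oral"),
                      96, grid_dt = 0.5)
  r2 <- simulate_pbpk(sys, dose_regimen(1, cfg$formulations$tablet, "oral"),
                      96, grid_dt = 0.5)
  ratio <- auc_last(r2$time, r2$conc) / auc_last(r1$time, r1$conc)
  expect_equal(ratio, 2, tolerance = 0.01)
})

test_that("halving solver tolerances leaves AUC essentially unchanged", {
  cfg <- cab_cfg()
  reg <- dose_regimen(140, cfg$formulations$tablet, "oral")
  r1 <- simulate_pbpk(default_system(), reg, 48, grid_dt = 0.5)
  r2 <- simulate_pbpk(default_system(), reg, 48, grid_dt = 0.5,
                      rtol = 5e-9, atol = 5e-10)
  a1 <- auc_last(r1$time, r1$conc)
  a2 <- auc_last(r2$time, r2$conc)
  expect_lt(abs(a1 - a2) / a2, 1e-3)
})

test_that("fraction_absorbed rejects iv regimens", {
  r <- simulate_pbpk(default_system(), dose_regimen(100, route = "iv"), 12,
                     grid_dt = 0.5)
  expect_error(fraction_absorbed(r), "oral")
})

test_that("population simulation is seeded, sized and degenerate-consistent", {
  cfg <- cab_cfg()
  reg <- dose_regimen(60, cfg$formulations$tablet, "oral")
  # no variability, n = 1: summary equals the single trajectory
  pop0 <- population_spec(n = 1, weight_range = c(73.96, 73.96),
                          cv = list(kcat_cyp3a4 = 0, kcat_mrp2 = 0, flows = 0),
                          seed = 7)
  p0 <- simulate_population(cfg$drug, cfg$physiology, cfg$ehc, reg, 24, pop0,
                            grid_dt = 0.5)
  single <- simulate_pbpk(default_system(), reg, 24, grid_dt = 0.5)
  expect_equal(unname(p0$geo_mean), unname(single$conc), tolerance = 1e-8)
  expect_equal(unname(p0$geo_sd), rep(1, length(p0$time)))
  # same seed twice: identical ensembles; different seed: different
  pop <- population_spec(n = 4, seed = 11)
  pa <- simulate_population(cfg$drug, cfg$physiology, cfg$ehc, reg, 24, pop,
                            grid_dt = 0.5)
  pb <- simulate_population(cfg$drug, cfg$physiology, cfg$ehc, reg, 24, pop,
                            grid_dt = 0.5)
  expect_identical(pa$conc, pb$conc)
  pop2 <- population_spec(n = 4, seed = 12)
  pc <- simulate_population(cfg$drug, cfg$physiology, cfg$ehc, reg, 24, pop2,
                            grid_dt = 0.5)
  expect_false(identical(pa$conc, pc$conc))
})

test_that("compiled and reference right-hand sides produce identical trajectories", {
  cfg <- cab_cfg()
  reg <- dose_regimen(140, cfg$formulations$capsule, "oral")
  rC <- simulate_pbpk(default_system(), reg, 30, grid_dt = 0.5,
                      engine = "compiled")
  rR <- simulate_pbpk(default_system(), reg, 30, grid_dt = 0.5, engine = "R")
  expect_equal(rC$conc, rR$conc, tolerance = 1e-6)
  expect_equal(rC$states, rR$states, tolerance = 1e-6)
  # and with the perpetrator co-simulation active
  sysp <- assemble_pbpk(cfg$drug, cfg$physiology, cfg$ehc,
                        list(perpetrator = induction_model(n_doses = 3)))
  pC <- simulate_pbpk(sysp, reg, 30, grid_dt = 0.5, engine = "compiled")
  pR <- simulate_pbpk(sysp, reg, 30, grid_dt = 0.5, engine = "R")
  expect_equal(pC$conc, pR$conc, tolerance = 1e-6)
})
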
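test_that("impairment scaling carries the published grade factors", {
  m <- impairment_scaling("moderate")
  expect_equal(m$cyp3a4_activity, 0.40)
  expect_equal(m$protein_scale, 1.25)
  expect_equal(m$hematocrit, 0.37)
  mi <- impairment_scaling("mild")
  expect_equal(mi$portal, 0.40)
  expect_equal(mi$hematocrit, 0.39)
  expect_equal(mi$liver_volume, 0.81)
  # documented alternative reading of the moderate protein factor
  alt <- impairment_scaling("moderate", moderate_protein_scale = 1.30)
  expect_equal(alt$protein_scale, 1.30)
})

test_that("impairment application scales the physiology and is identity for control", {
  cfg <- cab_cfg()
  ph0 <- cfg$physiology
  ctrl <- apply_impairment(ph0, impairment_scaling("control"))
  expect_equal(ctrl$organs, ph0$organs)
  expect_equal(ctrl$hematocrit, 0.47)
  expect_equal(ctrl$cyp3a4, ph0$cyp3a4)
  expect_equal(ctrl$plasma_protein_scale, ph0$plasma_protein_scale)

  mod <- apply_impairment(ph0, impairment_scaling("moderate"))
  g <- function(p, n) p$organs$flow_l_h[p$organs$name == n]
  expect_equal(g(mod, "gut_wall"), g(ph0, "gut_wall") * 0.36)
  expect_equal(g(mod, "kidney"), g(ph0, "kidney") * 0.65)
  expect_equal(g(mod, "liver"), g(ph0, "liver") * 2.30)
  expect_equal(g(mod, "brain"), g(ph0, "brain"))
  expect_equal(mod$organs$volume_l[mod$organs$name == "liver"],
               ph0$organs$volume_l[ph0$organs$name == "liver"] * 0.65)
  expect_equal(unname(mod$cyp3a4["liver"]), unname(ph0$cyp3a4["liver"]) * 0.40)
  # cardiac output recomputed as the sum of scaled flows; invariants hold
  systemic <- mod$organs$drains %in% c("venous", "portal") |
    mod$organs$name == "liver"
  expect_equal(mod$cardiac_output_l_h, sum(mod$organs$flow_l_h[systemic]))
  expect_true(all(mod$organs$flow_l_h > 0))
  expect_true(mod$hematocrit > 0 && mod$hematocrit < 1)
  # impairment factors scale fu in the direction of the clinical narrative
  fu0 <- scaled_fu(cfg$drug$fu_plasma, ctrl$plasma_protein_scale)
  fu_mild <- scaled_fu(cfg$drug$fu_plasma,
                       apply_impairment(ph0, impairment_scaling("mild"))$plasma_protein_scale)
  fu_mod <- scaled_fu(cfg$drug$fu_plasma, mod$plasma_protein_scale)
  expect_lt(fu_mild, fu0)   # mild: slightly lower unbound fraction
  expect_gt(fu_mod, fu0)    # moderate: higher unbound fraction
})

test_that("induction fold and enzyme turnover have the stated fixed points", {
  expect_equal(induction_fold(0, 9, 0.34), 1)
  expect_equal(induction_fold(0.34, 9, 0.34), 1 + 4.5)
  expect_equal(induction_fold(1e9, 9, 0.34), 10, tolerance = 1e-6)
  expect_equal(enzyme_turnover_step(5, 5, 1, 0.02), 0)
  # fixed point at E0 * fold
  expect_equal(enzyme_turnover_step(25, 5, 5, 0.02), 0)
  # washout follows the closed-form exponential with half-life ln2/kdeg
  kdeg <- 0.05
  E0 <- 1
  E <- 4
  tt <- seq(0, 100, by = 0.5)
  num <- deSolve::lsoda(c(E = E), tt,
                        function(t, y, p) list(enzyme_turnover_step(y, E0, 1, kdeg)),
                        NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(num[, "E"], E0 + (E - E0) * exp(-kdeg * tt), tolerance = 1e-6)
})

test_that("DDI co-simulation reduces exposure iff induction is active", {
  cfg <- cab_cfg()
  reg <- dose_regimen(140, cfg$formulations$capsule, "oral")
  # emax = 0: both arms identical
  ddi0 <- simulate_ddi(cfg$drug, cfg$physiology, cfg$ehc,
                       induction_model(emax = 0),
                       reg, victim_offset = 24, obs_window = 48,
                       grid_dt = 0.5)
  expect_equal(unname(ddi0$ratios), c(1, 1), tolerance = 1e-6)
  # any induction lowers AUC
  ddi1 <- simulate_ddi(cfg$drug, cfg$physiology, cfg$ehc,
                       induction_model(),
                       reg, victim_offset = 24, obs_window = 48,
                       grid_dt = 0.5)
  expect_lt(ddi1$ratios[["auc_ratio"]], 1)
  expect_lt(mass_balance_error(ddi1$with), 1e-6)
})

test_that("local sensitivities match analytic values in degenerate configs", {
  cfg <- cab_cfg()
  opts <- list(degenerate = list(volume_l = 40, clearance_l_h = 2))
  reg <- dose_regimen(100, route = "iv")
  s_dose <- local_sensitivity(cfg$drug, NULL, NULL, reg, "regimen.dose",
                              output = "auc_last", t_end = 400,
                              options = opts, grid_dt = 0.5)
  expect_equal(s_dose, 1, tolerance = 1e-3)
  # AUC = D/CL: the exact coefficient is -1; with a central difference at
  # relative step d the expected estimate is -1/(1 - d^2)
  delta <- 0.02
  s_cl <- local_sensitivity(cfg$drug, NULL, NULL, reg,
                            "degenerate.clearance_l_h",
                            output = "auc_last", delta = delta, t_end = 2000,
                            options = opts, grid_dt = 1)
  expect_equal(s_cl, -1 / (1 - delta^2), tolerance = 1e-3)
  expect_error(
    local_sensitivity(cfg$drug, NULL, NULL, reg, "drug.not_a_field",
                      t_end = 10, options = opts),
    "not found"
  )
})

test_that("sensitivity to an inactive pathway parameter is zero", {
  cfg <- cab_cfg()
  reg <- dose_regimen(60, cfg$formulations$tablet, "oral")
  s <- local_sensitivity(cfg$drug, cfg$physiology, cfg$ehc, reg,
                         "drug.kcat_mrp2", output = "auc_last",
                         t_end = 24, options = list(mrp2 = FALSE),
                         grid_dt = 0.5)
  expect_equal(s, 0)
})
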
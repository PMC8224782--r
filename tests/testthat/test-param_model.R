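test_that("packaged default profile carries every published model constant", {
  cfg <- cab_cfg()
  d <- cfg$drug
  # one assertion per printed symbol of the drug/absorption/EHC parameter set
  expect_equal(d$molecular_weight, 501.50)
  expect_equal(d$pKa_base, 6.32)
  expect_equal(d$fu_plasma, 0.0024)   # 0.24% unbound (99.7%+ bound drug)
  expect_equal(d$logP, 4.40)
  expect_equal(d$solubility_ref, 7.72e-3)
  expect_equal(d$solubility_ref_pH, 6.5)
  expect_equal(d$km_cyp3a4, 0.97)
  expect_equal(d$kcat_cyp3a4, 0.67)
  expect_equal(d$km_mrp2, 10)
  expect_equal(d$kcat_mrp2, 2111.11)
  expect_equal(d$mrp2_ref_conc, 0.09)
  expect_equal(d$transcellular_permeability, 1.70e-4)
  expect_equal(d$partition_method, "rodgers_rowland")
  expect_equal(cfg$formulations$tablet$weibull_t50, 36.00)
  expect_equal(cfg$formulations$tablet$weibull_shape, 1.29)
  expect_equal(cfg$formulations$capsule$weibull_t50, 45.00)
  expect_equal(cfg$formulations$capsule$weibull_shape, 5.00)
  expect_equal(cfg$ehc$emptying_half_time, 41.44)
  expect_equal(cfg$ehc$continuous_fraction, 0.1)
  expect_equal(cfg$ehc$ejection_fraction, 0.45)
  expect_equal(cfg$ehc$refill_time, 241)
})

test_that("validation rejects out-of-range and missing parameters", {
  cfg <- cab_cfg()
  d <- unclass(cfg$drug)
  d$organ_permeability <- NULL
  bad <- d; bad$fu_plasma <- 0
  expect_error(do.call(drug_parameters, bad), "fu_plasma")
  bad <- d; bad$fu_plasma <- 1.5
  expect_error(do.call(drug_parameters, bad), "fu_plasma")
  bad <- d; bad$km_cyp3a4 <- -1
  expect_error(do.call(drug_parameters, bad), "km_cyp3a4")
  bad <- d; bad$solubility_ref_pH <- 12
  expect_error(do.call(drug_parameters, bad), "solubility_ref_pH")
  bad <- d; bad$molecular_weight <- NULL
  expect_error(do.call(drug_parameters, bad), "molecular_weight")

  expect_error(formulation_spec("tablet", weibull_t50 = 36), "weibull_shape")
  expect_error(formulation_spec("solution", weibull_t50 = 36), "absent")
  expect_error(formulation_spec("tablet", weibull_t50 = -1, weibull_shape = 1),
               "weibull_t50")
  expect_error(ehc_parameters(41.44, 0.1, 1.2, 241), "ejection_fraction")
  expect_error(ehc_parameters(41.44, 0.1, 0.45, 241, meal_times = c(4, 4)),
               "increasing")
  expect_error(dose_regimen(-5, route = "iv"), "dose")
  expect_error(dose_regimen(60, route = "oral"), "formulation")
})

test_that("physiology invariants hold and are enforced", {
  cfg <- cab_cfg()
  ph <- cfg$physiology
  systemic <- ph$organs$drains %in% c("venous", "portal") |
    ph$organs$name == "liver"
  expect_equal(sum(ph$organs$flow_l_h[systemic]), ph$cardiac_output_l_h,
               tolerance = 0.01)
  expect_true(ph$hematocrit > 0 && ph$hematocrit < 1)
  expect_true(all(ph$gi$transit_h > 0))
  broken <- ph
  broken$organs$flow_l_h[2] <- broken$organs$flow_l_h[2] * 2
  expect_error(cabopbpk:::validate_physiology(broken), "cardiac output")
})

test_that("configurations round-trip losslessly through YAML and JSON", {
  cfg <- cab_cfg()
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("cfg_roundtrip.", ext))
    save_config(cfg, path)
    back <- load_config(path)
    expect_equal(back$drug, cfg$drug)
    expect_equal(back$ehc, cfg$ehc)
    expect_equal(back$formulations, cfg$formulations)
    expect_equal(back$physiology$organs, cfg$physiology$organs)
    expect_equal(back$physiology$gi, cfg$physiology$gi)
    expect_equal(back$physiology$hematocrit, cfg$physiology$hematocrit)
    unlink(path)
  }
})

test_that("concentration unit conversions are exact and compose to identity", {
  expect_equal(conc_ngml_to_umol(501.50, 501.50), 1.0)
  expect_equal(conc_ngml_to_umol(0, 501.50), 0)
  expect_equal(conc_umol_to_ngml(conc_ngml_to_umol(123.4, 501.5), 501.5),
               123.4)
  expect_error(conc_ngml_to_umol(1, 0), "mw")
  expect_error(conc_ngml_to_umol(1, -5), "mw")
})
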
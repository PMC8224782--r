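# Shared fixtures. Expensive default simulations are computed once per test
# run and memoised in this environment.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

cab_cfg <- function() fixture("cfg", cab_defaults())

default_system <- function() {
  cfg <- cab_cfg()
  fixture("sys_default", assemble_pbpk(cfg$drug, cfg$physiology, cfg$ehc))
}

# 140 mg tablet, default EHC model, 96 h: the workhorse simulation
sim_tablet_96h <- function() {
  fixture("sim_tablet_96h", {
    cfg <- cab_cfg()
    simulate_pbpk(default_system(),
                  dose_regimen(140, cfg$formulations$tablet, "oral"),
                  96, grid_dt = 0.25)
  })
}

# same regimen without recirculation (biliary output direct to faeces)
sim_tablet_96h_noehc <- function() {
  fixture("sim_tablet_96h_noehc", {
    cfg <- cab_cfg()
    sys <- assemble_pbpk(cfg$drug, cfg$physiology, cfg$ehc, list(ehc = FALSE))
    simulate_pbpk(sys, dose_regimen(140, cfg$formulations$tablet, "oral"),
                  96, grid_dt = 0.25)
  })
}

# same regimen with the biliary pathway disabled entirely
sim_tablet_96h_nomrp2 <- function() {
  fixture("sim_tablet_96h_nomrp2", {
    cfg <- cab_cfg()
    sys <- assemble_pbpk(cfg$drug, cfg$physiology, cfg$ehc, list(mrp2 = FALSE))
    simulate_pbpk(sys, dose_regimen(140, cfg$formulations$tablet, "oral"),
                  96, grid_dt = 0.25)
  })
}

sim_formulation_30h <- function(kind) {
  fixture(paste0("sim_", kind, "_30h"), {
    cfg <- cab_cfg()
    simulate_pbpk(default_system(),
                  dose_regimen(140, cfg$formulations[[kind]], "oral"),
                  30, grid_dt = 0.25)
  })
}

onecomp_system <- function(v = 50, cl = 3) {
  cfg <- cab_cfg()
  assemble_pbpk(cfg$drug, NULL, NULL,
                list(degenerate = list(volume_l = v, clearance_l_h = cl)))
}
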
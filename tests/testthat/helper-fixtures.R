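# Shared fixtures: a round-number congener, environment and a small food web
# used across the unit tests. All fixtures are built in code.

h_congener <- function(...) {
  args <- utils::modifyList(
    list(name = "PCB-x", kow_ref = 1e6, koa_a = 3000, koa_b = -2,
         henry_ref = 20, t_ref = 298.15, du_aw = 5e4, du_ow = -2e4,
         tmf = 2, lifetime_air = 100, lifetime_water = 1000,
         lifetime_sediment = 10000),
    list(...))
  do.call(fug_congener, args)
}

h_air <- function(...) {
  args <- utils::modifyList(
    list(volume = 1e9, temp = 280, aerosol_frac = 1e-10, area_aw = 1e6,
         mtc_air = 50, mtc_water = 0.5, rain_rate = 0.002,
         dry_dep_vel = 1e-8, scavenging = 5e-6, adv_in = 1e8,
         adv_out = 1e8),
    list(...))
  do.call(fug_air, args)
}

h_water <- function(...) {
  args <- utils::modifyList(
    list(volume = 1e7, temp = 285, susp_frac = NULL, susp_density = 1500,
         susp_oc = 0.1, area_ws = 1e6, adv_flow = 1e4, dep_vel = 0.003,
         resusp_vel = 0.001, mtc_ws = 2e-4),
    list(...))
  do.call(fug_water, args)
}

h_sediment <- function(...) {
  args <- utils::modifyList(
    list(volume = 1e5, solid_frac = 0.1, solid_density = 2400,
         solid_oc = 0.03, burial_flow = 0, depth = 0.1),
    list(...))
  do.call(fug_sediment, args)
}

# 3-species fixture: producer + pelagic grazer + benthic grazer, with fixed
# population volumes; exercises pelagic/benthic gill coupling and the
# dietary three-way split.
h_web3 <- function() {
  sp <- dplyr::bind_rows(
    fug_species("alga", "producer", lipid_frac = 0.01, body_mass = 1e-12,
                density = 1000, gill_clearance = 8, metabolic_rate = 1e-3,
                max_age = 0.2, assimilation = 0.9, pop_volume = 20,
                lifetime = 5),
    fug_species("daphnia", "pelagic", lipid_frac = 0.02, body_mass = 1e-7,
                density = 1000, gill_clearance = 4, metabolic_rate = 5e-4,
                max_age = 2, assimilation = 0.7, pop_volume = 3),
    fug_species("worm", "benthic", lipid_frac = 0.03, body_mass = 5e-6,
                density = 1050, gill_clearance = 2, metabolic_rate = 2e-4,
                max_age = 3, assimilation = 0.75, pop_volume = 2)
  )
  diet <- matrix(0, 3, 3, dimnames = list(sp$name, sp$name))
  diet["daphnia", "alga"] <- 1
  diet["worm", "alga"] <- 1
  fug_foodweb(sp, diet)
}

h_scenario3 <- function(...) {
  args <- utils::modifyList(
    list(congener = h_congener(), air = h_air(), water = h_water(),
         sediment = h_sediment(), foodweb = h_web3(),
         forcing = fug_forcing(air_temp = 280, water_temp = 285,
                               inflow_fug_air = 2e-9,
                               inflow_fug_water = 5e-8,
                               emission = c(water = 0.1))),
    list(...))
  do.call(fug_scenario, args)
}

# independent trophic-level oracle: damped fixed-point iteration of
# TL = 1 + P TL
h_tl_fixed_point <- function(diet, iters = 200) {
  tl <- rep(1, nrow(diet))
  for (i in seq_len(iters)) tl <- 1 + as.numeric(diet %*% tl)
  tl
}
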
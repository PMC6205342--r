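# Deterministic "toy lake" scenario generator: a small, self-consistent
# stand-in ecosystem (synthetic; not a calibrated real lake) used for tests,
# examples and randomized consistency studies.

.toy_congener <- function(jit, runf) {
  log_kow <- runf(6.5, 7.1)
  fug_congener(
    name = "PCB-153-like",
    kow_ref = 10^log_kow,
    koa_a = jit(4000, 0.05), koa_b = -3.5,
    henry_ref = jit(20, 0.15), t_ref = 298.15,
    du_aw = jit(6e4, 0.1), du_ow = -2e4,
    tmf = runf(1.6, 2.6),
    lifetime_air = jit(170, 0.15), lifetime_water = jit(5500, 0.15),
    lifetime_sediment = jit(17000, 0.15)
  )
}

# species template; diets reference earlier species only, one apex per web
.toy_species_template <- function(n_species) {
  rows <- list(
    phyto = list(fug_species("phytoplankton", "producer", lipid_frac = 0.005,
                             body_mass = 1e-12, gill_clearance = 10,
                             metabolic_rate = 1e-3, max_age = 0.2,
                             assimilation = 0.9, lifetime = 5),
                 diet = NULL),
    zoo = list(fug_species("zooplankton", "pelagic", lipid_frac = 0.02,
                           body_mass = 1e-7, gill_clearance = 5,
                           metabolic_rate = 5e-4, max_age = 2,
                           assimilation = 0.72),
               diet = c(phytoplankton = 1)),
    forage = list(fug_species("forage_fish", "pelagic", lipid_frac = 0.05,
                              body_mass = 0.02, gill_clearance = 1.2,
                              metabolic_rate = 1e-4, max_age = 18,
                              assimilation = 0.8),
                  diet = c(zooplankton = 1)),
    benthos = list(fug_species("benthic_invert", "benthic", lipid_frac = 0.03,
                               body_mass = 5e-6, gill_clearance = 2,
                               metabolic_rate = 2e-4, max_age = 3,
                               assimilation = 0.75),
                   diet = c(phytoplankton = 1)),
    predator = list(fug_species("predator_fish", "pelagic", lipid_frac = 0.15,
                                body_mass = 2, gill_clearance = 0.8,
                                metabolic_rate = 5e-5, max_age = 30,
                                assimilation = 0.85),
                    diet = c(forage_fish = 1)),
    minnow = list(fug_species("minnow", "pelagic", lipid_frac = 0.04,
                              body_mass = 0.005, gill_clearance = 1.5,
                              metabolic_rate = 1.2e-4, max_age = 12,
                              assimilation = 0.78),
                  diet = c(zooplankton = 0.7, phytoplankton = 0.3)),
    amphipod = list(fug_species("amphipod", "benthic", lipid_frac = 0.025,
                                body_mass = 1e-5, gill_clearance = 2,
                                metabolic_rate = 2e-4, max_age = 3,
                                assimilation = 0.75),
                    diet = c(phytoplankton = 1)),
    mysid = list(fug_species("mysid", "pelagic", lipid_frac = 0.03,
                             body_mass = 5e-5, gill_clearance = 3,
                             metabolic_rate = 3e-4, max_age = 4,
                             assimilation = 0.75),
                 diet = c(zooplankton = 0.5, phytoplankton = 0.5))
  )
  # keep the chain connected and a single apex for every n
  order_for <- list(
    `3` = c("phyto", "zoo", "forage"),
    `4` = c("phyto", "zoo", "benthos", "forage"),
    `5` = c("phyto", "zoo", "benthos", "forage", "predator"),
    `6` = c("phyto", "zoo", "benthos", "minnow", "forage", "predator"),
    `7` = c("phyto", "zoo", "benthos", "amphipod", "minnow", "forage",
            "predator"),
    `8` = c("phyto", "zoo", "benthos", "amphipod", "mysid", "minnow",
            "forage", "predator")
  )
  diets_for <- list(
    `4` = list(forage_fish = c(zooplankton = 0.8, benthic_invert = 0.2)),
    `5` = list(forage_fish = c(zooplankton = 0.8, benthic_invert = 0.2)),
    `6` = list(forage_fish = c(zooplankton = 0.75, benthic_invert = 0.25),
               predator_fish = c(forage_fish = 0.7, minnow = 0.3)),
    `7` = list(forage_fish = c(zooplankton = 0.65, benthic_invert = 0.2,
                               amphipod = 0.15),
               predator_fish = c(forage_fish = 0.7, minnow = 0.3)),
    `8` = list(forage_fish = c(zooplankton = 0.65, benthic_invert = 0.2,
                               amphipod = 0.15),
               predator_fish = c(forage_fish = 0.6, minnow = 0.25,
                                 mysid = 0.15))
  )
  keys <- order_for[[as.character(n_species)]]
  sp <- dplyr::bind_rows(lapply(rows[keys], `[[`, 1))
  diet <- matrix(0, n_species, n_species,
                 dimnames = list(sp$name, sp$name))
  overrides <- diets_for[[as.character(n_species)]]
  for (k in keys) {
    nm <- rows[[k]][[1]]$name
    d <- overrides[[nm]] %||% rows[[k]]$diet
    if (!is.null(d)) diet[nm, names(d)] <- d
  }
  list(species = sp, diet = diet)
}

.toy_seasonal <- function(mean_k, amp, years) {
  brk <- c(0, 90, 180, 270)
  t <- as.vector(outer(brk, 365 * (0:(years - 1)), `+`))
  v <- rep(mean_k + amp * c(-1, 0.2, 1, 0.1), years)
  data.frame(time = c(t, 365 * years), value = c(v, v[1]))
}

#' Generate a deterministic toy-lake scenario
#'
#' Builds a small synthetic lake ecosystem: a PCB-153-like congener, air /
#' water / sediment compartments sized like a 10 km2, 10 m deep lake with a
#' 0.1 m bio-active sediment layer (10 % dry residual), and a 3-8 species
#' food web (phytoplankton to predatory fish, with benthic invertebrates
#' feeding at the sediment). Parameters are jittered reproducibly around
#' realistic values by `seed`; the same seed always returns an identical
#' scenario. Producer biomass comes from the energy-mass estimate and is kept
#' inside the observed 0.01-1 g m^-3 phytoplankton density range; consumer
#' populations are closed with [balance_populations()], the apex maximum age
#' being set from the growth/mortality identity so that its imbalance is
#' below 1 % of growth. Infeasible random draws are re-drawn (bounded, with a
#' message).
#'
#' @param seed Integer seed; drives all randomisation.
#' @param n_species Number of species, 3-8 (default 5: phytoplankton,
#'   zooplankton, benthic invertebrate, forage fish, predator fish).
#' @param depth_scale,area_scale Multiplicative scale factors on the nominal
#'   10 m depth and 10 km2 area.
#' @param seasonal Use a piecewise-linear seasonal temperature forcing
#'   instead of constant temperatures.
#' @param closed Make the system closed: no emission, no inflow fugacity,
#'   and advection, reaction, burial and metabolic degradation excluded.
#'   Total chemical mass is then conserved exactly.
#' @param exchange_only Keep only bidirectional diffusive exchanges (implies
#'   `closed`; also excludes feeding, metabolism, mortality and all one-way
#'   deposition pathways). Such a system relaxes to a common fugacity.
#' @param years Horizon (years) covered by the seasonal forcing grid.
#' @return A [fug_scenario()].
#' @examples
#' scn <- make_toy_lake(seed = 1)
#' steady_state(scn)$fugacity
#' @export
make_toy_lake <- function(seed = 1, n_species = 5, depth_scale = 1,
                          area_scale = 1, seasonal = FALSE, closed = FALSE,
                          exchange_only = FALSE, years = 30) {
  if (!n_species %in% 3:8) {
    abort("`n_species` must be between 3 and 8.",
          class = "fugapop_validation_error")
  }
  withr::with_seed(seed, {
    for (attempt in 1:20) {
      scn <- tryCatch(
        .toy_lake_draw(n_species, depth_scale, area_scale, seasonal, closed,
                       exchange_only, years),
        fugapop_infeasible_error = function(e) NULL
      )
      if (!is.null(scn)) break
      message("toy-lake draw ", attempt,
              " infeasible (negative population); re-drawing.")
    }
    if (is.null(scn)) {
      abort("could not draw a feasible toy lake in 20 attempts.",
            class = "fugapop_infeasible_error")
    }
    scn
  })
}

.toy_lake_draw <- function(n_species, depth_scale, area_scale, seasonal,
                           closed, exchange_only, years) {
  jit <- function(x, rel) x * stats::runif(1, 1 - rel, 1 + rel)
  runf <- function(a, b) stats::runif(1, a, b)

  congener <- .toy_congener(jit, runf)
  area <- 1e7 * area_scale
  depth_w <- 10 * depth_scale * stats::runif(1, 0.85, 1.15)
  ta_mean <- 281 + runf(-1.5, 1.5)
  tw_mean <- 285 + runf(-1.5, 1.5)

  air <- fug_air(
    volume = area * 1000, temp = ta_mean,
    aerosol_frac = jit(2e-11, 0.3), area_aw = area,
    mtc_air = jit(70, 0.2), mtc_water = jit(0.7, 0.2),
    # dry_dep_vel and scavenging are aerosol-volumetric (particle velocity /
    # scavenging ratio times the ~2e-11 aerosol volume fraction), because the
    # deposition D-values carry the full aerosol-phase capacity Z_aer
    rain_rate = jit(0.0024, 0.2), dry_dep_vel = jit(5e-9, 0.2),
    scavenging = jit(4e-6, 0.2),
    adv_in = area * 1000, adv_out = area * 1000
  )
  water <- fug_water(
    volume = area * depth_w, temp = tw_mean,
    susp_frac = NULL, # derived from the 70/30 loading split
    susp_density = jit(1500, 0.1), susp_oc = jit(0.1, 0.2),
    area_ws = area, adv_flow = area * depth_w / jit(730, 0.2),
    dep_vel = jit(0.004, 0.25), resusp_vel = jit(0.0015, 0.25),
    mtc_ws = jit(2.4e-4, 0.25)
  )
  sediment <- fug_sediment(
    solid_frac = 0.1, solid_density = jit(2400, 0.05),
    solid_oc = jit(0.03, 0.2), burial_flow = 0, depth = 0.1,
    area_ws = area
  )

  tpl <- .toy_species_template(n_species)
  sp <- tpl$species
  for (col in c("body_mass", "gill_clearance", "metabolic_rate")) {
    sp[[col]] <- sp[[col]] * stats::runif(nrow(sp), 0.9, 1.1)
  }
  sp$max_age <- sp$max_age * stats::runif(nrow(sp), 0.9, 1.1)

  # apex maximum age from the growth = mortality identity at the reference
  # temperature, so the unclosed apex balance stays below 1 % of growth
  tw_c <- tw_mean - 273.15
  apex <- which(!(sp$name %in% colnames(tpl$diet)[colSums(tpl$diet) > 0]) &
                  rowSums(tpl$diet) > 0)
  kg_apex <- growth_rate(tw_c, sp$body_mass[apex])
  sp$max_age[apex] <- signif(
    (.const$mortality_annual_coef / (.const$days_per_year * kg_apex)) ^
      (-1 / .const$mortality_exponent), 5)

  # primary producer standing stock from the energy-mass estimate
  energy <- fug_energy(
    solar_flux = jit(170, 0.15), photosyn_eff = 0.03,
    coverage = runf(0.15, 0.25), transport_factor = 0.05,
    carbon_prod = 5e-5, carbon_frac = 0.45, area = area
  )
  m_phyto <- primary_producer_biomass(energy, sp$lifetime[1])     # grams
  dens <- m_phyto / water$volume                                  # g m^-3
  if (dens < 0.01 || dens > 1) {
    abort("phytoplankton density outside 0.01-1 g/m3.",
          class = "fugapop_infeasible_error")
  }
  sp$pop_volume[1] <- m_phyto / (sp$density[1] * 1000)            # m^3

  web <- fug_foodweb(sp, tpl$diet)
  bal <- balance_populations(web, tw_c)
  sp$pop_volume <- bal$pop_volume
  web <- fug_foodweb(sp, tpl$diet)

  if (seasonal) {
    air_t <- .toy_seasonal(ta_mean, 12, years)
    wat_t <- .toy_seasonal(tw_mean, 8, years)
  } else {
    air_t <- ta_mean
    wat_t <- tw_mean
  }
  if (closed || exchange_only) {
    forcing <- fug_forcing(air_temp = air_t, water_temp = wat_t)
  } else {
    forcing <- fug_forcing(
      air_temp = air_t, water_temp = wat_t,
      inflow_fug_air = jit(5e-10, 0.3), inflow_fug_water = jit(2e-8, 0.3),
      emission = c(water = jit(0.5, 0.3))
    )
  }
  exclude <- character()
  if (closed || exchange_only) {
    # metabolism and reaction are degradation exits, advection and burial
    # boundary flows: all must be off for the system to conserve mass
    exclude <- c("advection", "reaction", "burial", "metabolism")
  }
  if (exchange_only) {
    exclude <- c(exclude, "feeding", "mortality", "deposition")
  }
  fug_scenario(congener, air, water, sediment, foodweb = web,
               forcing = forcing,
               options = fug_options(exclude = exclude))
}
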
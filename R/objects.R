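# Validated constructors for the model's domain objects. Each check names the
# offending field so configuration errors point at a config path.

.check <- function(ok, field, msg, where = NULL) {
  if (!isTRUE(ok)) {
    path <- if (is.null(where)) field else paste0(where, "$", field)
    abort(paste0("Invalid value for `", path, "`: ", msg),
          class = "fugapop_validation_error")
  }
  invisible(TRUE)
}

.num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

#' Congener physicochemical properties
#'
#' Bundle of chemical properties for one PCB congener (or any hydrophobic
#' organic with the same partitioning behaviour), including the parameters of
#' its temperature dependence.
#'
#' @param name Congener label.
#' @param kow_ref Octanol-water partition coefficient (dimensionless) at the
#'   reference temperature. Held temperature-independent by default; see
#'   [kow_at()].
#' @param koa_a,koa_b Parameters of log10 K_OA = a/T + b with `a` in kelvin.
#' @param henry_ref Henry's law constant at `t_ref` (Pa m^3 mol^-1).
#' @param t_ref Reference temperature (K).
#' @param du_aw Internal-energy change of phase transfer air to water
#'   (J mol^-1), used in the van't Hoff correction of H.
#' @param du_ow Internal-energy change octanol to water (J mol^-1). Stored but
#'   unused unless the temperature correction of K_OW is switched on.
#' @param tmf Trophic magnification factor (dimensionless, > 0); governs the
#'   gut-feces partition of absorbed dietary chemical.
#' @param lifetime_air,lifetime_water,lifetime_sediment First-order reaction
#'   lifetimes per compartment (days); `Inf` disables the reaction.
#' @return An object of class `fug_congener`.
#' @examples
#' pcb153 <- fug_congener("PCB-153", kow_ref = 10^6.9, koa_a = 4000,
#'   koa_b = -3.5, henry_ref = 20, du_aw = 6e4, tmf = 2,
#'   lifetime_air = 170, lifetime_water = 5500, lifetime_sediment = 17000)
#' @export
fug_congener <- function(name, kow_ref, koa_a, koa_b, henry_ref,
                         t_ref = 298.15, du_aw = 0, du_ow = 0, tmf = 1,
                         lifetime_air = Inf, lifetime_water = Inf,
                         lifetime_sediment = Inf) {
  .check(is.character(name) && length(name) == 1, "name", "must be a string",
         "congener")
  for (f in c("kow_ref", "henry_ref", "t_ref", "tmf")) {
    v <- get(f)
    .check(.num1(v) && v > 0, f, "must be a positive number", "congener")
  }
  for (f in c("koa_a", "koa_b", "du_aw", "du_ow")) {
    .check(.num1(get(f)), f, "must be a finite number", "congener")
  }
  for (f in c("lifetime_air", "lifetime_water", "lifetime_sediment")) {
    v <- get(f)
    .check(is.numeric(v) && length(v) == 1 && !is.na(v) && v > 0, f,
           "must be a positive lifetime in days (Inf allowed)", "congener")
  }
  structure(
    list(name = name, kow_ref = kow_ref, koa_a = koa_a, koa_b = koa_b,
         henry_ref = henry_ref, t_ref = t_ref, du_aw = du_aw, du_ow = du_ow,
         tmf = tmf, lifetime_air = lifetime_air,
         lifetime_water = lifetime_water,
         lifetime_sediment = lifetime_sediment),
    class = "fug_congener"
  )
}

#' Air compartment geometry and transfer parameters
#'
#' @param volume Air volume V_A (m^3).
#' @param temp Air temperature (K); the dynamic engine overrides this with the
#'   forcing series.
#' @param aerosol_frac Volume fraction of aerosol (dimensionless, `[0, 1)`).
#' @param area_aw Air-water interface area (m^2).
#' @param mtc_air,mtc_water Air-side and water-side film mass-transfer
#'   coefficients of the two-film volatilisation model (m day^-1).
#' @param rain_rate Rain rate U_Q (m day^-1).
#' @param dry_dep_vel Aerosol dry-deposition velocity v_Q (m day^-1).
#' @param scavenging Dimensionless wet scavenging ratio U_R.
#' @param adv_in,adv_out Advective air inflow / outflow (m^3 day^-1).
#' @return An object of class `fug_air`.
#' @export
fug_air <- function(volume, temp, aerosol_frac = 0, area_aw,
                    mtc_air, mtc_water, rain_rate = 0, dry_dep_vel = 0,
                    scavenging = 0, adv_in = 0, adv_out = 0) {
  .check(.num1(volume) && volume > 0, "volume", "must be > 0", "air")
  .check(.num1(temp) && temp > 0, "temp", "must be > 0 K", "air")
  .check(.num1(aerosol_frac) && aerosol_frac >= 0 && aerosol_frac < 1,
         "aerosol_frac", "must be in [0, 1)", "air")
  .check(.num1(area_aw) && area_aw > 0, "area_aw", "must be > 0", "air")
  for (f in c("mtc_air", "mtc_water", "rain_rate", "dry_dep_vel",
              "scavenging", "adv_in", "adv_out")) {
    v <- get(f)
    .check(.num1(v) && v >= 0, f, "must be >= 0", "air")
  }
  structure(
    list(volume = volume, temp = temp, aerosol_frac = aerosol_frac,
         area_aw = area_aw, mtc_air = mtc_air, mtc_water = mtc_water,
         rain_rate = rain_rate, dry_dep_vel = dry_dep_vel,
         scavenging = scavenging, adv_in = adv_in, adv_out = adv_out),
    class = "fug_air"
  )
}

#' Water compartment geometry and transfer parameters
#'
#' @param volume Water volume V_W (m^3).
#' @param temp Water temperature (K); shared by sediment and biota.
#' @param susp_frac Volume fraction of suspended sediment. Defaults to `NULL`,
#'   in which case it is derived from the 70/30 dissolved/particulate loading
#'   split via [tau2_from_split()].
#' @param susp_density Suspended-sediment particle density (kg m^-3).
#' @param susp_oc Mass fraction organic carbon of suspended sediment.
#' @param area_ws Water-sediment interface area (m^2).
#' @param adv_flow Advective water through-flow G_W (m^3 day^-1).
#' @param dep_vel Particle deposition velocity U_DP (m day^-1).
#' @param resusp_vel Particle resuspension velocity U_RS (m day^-1).
#' @param mtc_ws Water-sediment diffusive mass-transfer coefficient
#'   (m day^-1).
#' @return An object of class `fug_water`.
#' @export
fug_water <- function(volume, temp, susp_frac = NULL, susp_density,
                      susp_oc, area_ws, adv_flow = 0, dep_vel = 0,
                      resusp_vel = 0, mtc_ws = 0) {
  .check(.num1(volume) && volume > 0, "volume", "must be > 0", "water")
  .check(.num1(temp) && temp > 0, "temp", "must be > 0 K", "water")
  .check(is.null(susp_frac) ||
           (.num1(susp_frac) && susp_frac >= 0 && susp_frac < 1),
         "susp_frac", "must be in [0, 1) or NULL (derived)", "water")
  .check(.num1(susp_density) && susp_density > 0, "susp_density",
         "must be > 0", "water")
  .check(.num1(susp_oc) && susp_oc >= 0 && susp_oc <= 1, "susp_oc",
         "must be in [0, 1]", "water")
  .check(.num1(area_ws) && area_ws > 0, "area_ws", "must be > 0", "water")
  for (f in c("adv_flow", "dep_vel", "resusp_vel", "mtc_ws")) {
    v <- get(f)
    .check(.num1(v) && v >= 0, f, "must be >= 0", "water")
  }
  structure(
    list(volume = volume, temp = temp, susp_frac = susp_frac,
         susp_density = susp_density, susp_oc = susp_oc, area_ws = area_ws,
         adv_flow = adv_flow, dep_vel = dep_vel, resusp_vel = resusp_vel,
         mtc_ws = mtc_ws),
    class = "fug_water"
  )
}

#' Sediment compartment geometry and composition
#'
#' Describes the bio-active top layer of the bed sediment (default 0.1 m), a
#' mixture of pore water and organic-carbon-bearing solids.
#'
#' @param volume Sediment volume V_S (m^3). Defaults to `area_ws * depth` when
#'   `area_ws` is given.
#' @param solid_frac Volume fraction of solid sediment (the rest is saturated
#'   pore water).
#' @param solid_density Sediment solid density (kg m^-3).
#' @param solid_oc Mass fraction organic carbon of sediment solids.
#' @param burial_flow Burial flow G_S to deep sediment (m^3 day^-1); 0 closes
#'   the sediment bottom.
#' @param depth Active-layer depth (m).
#' @param area_ws Water-sediment interface area (m^2), used only to default
#'   `volume`.
#' @return An object of class `fug_sediment`.
#' @export
fug_sediment <- function(volume = NULL, solid_frac, solid_density, solid_oc,
                         burial_flow = 0, depth = 0.1, area_ws = NULL) {
  if (is.null(volume)) {
    .check(!is.null(area_ws), "volume",
           "must be given (or supply `area_ws` with `depth`)", "sediment")
    volume <- area_ws * depth
  }
  .check(.num1(volume) && volume > 0, "volume", "must be > 0", "sediment")
  .check(.num1(solid_frac) && solid_frac >= 0 && solid_frac < 1,
         "solid_frac", "must be in [0, 1)", "sediment")
  .check(.num1(solid_density) && solid_density > 0, "solid_density",
         "must be > 0", "sediment")
  .check(.num1(solid_oc) && solid_oc >= 0 && solid_oc <= 1, "solid_oc",
         "must be in [0, 1]", "sediment")
  .check(.num1(burial_flow) && burial_flow >= 0, "burial_flow",
         "must be >= 0", "sediment")
  .check(.num1(depth) && depth > 0, "depth", "must be > 0", "sediment")
  structure(
    list(volume = volume, solid_frac = solid_frac,
         solid_density = solid_density, solid_oc = solid_oc,
         burial_flow = burial_flow, depth = depth),
    class = "fug_sediment"
  )
}

.species_cols <- c("name", "habitat", "lipid_frac", "body_mass", "density",
                   "gill_clearance", "metabolic_rate", "max_age",
                   "assimilation", "pop_volume", "lifetime")

#' Build a species table row
#'
#' Convenience constructor for one row of the species table used by
#' [fug_foodweb()].
#'
#' @param name Species label.
#' @param habitat One of `"pelagic"`, `"benthic"`, `"producer"`. Producers have
#'   an empty diet and exchange with the water column like pelagic species.
#' @param lipid_frac Lipid fraction L of the organism (0-1).
#' @param body_mass Individual body mass W_B (kg).
#' @param density Organism density (kg m^-3), usually close to water.
#' @param gill_clearance Gill (or surface) clearance k1, m^3 of water cleared
#'   per kg of biomass per day.
#' @param metabolic_rate First-order metabolic transformation rate k_M
#'   (day^-1).
#' @param max_age Maximum age t_max (years), driving natural mortality.
#' @param assimilation Dietary chemical absorption efficiency E_D (0-1).
#' @param pop_volume Population volume V_P (m^3); may be `NA` if later filled
#'   by [balance_populations()].
#' @param lifetime Average lifetime (days); used by the energy-mass biomass
#'   estimate for producers, `NA` otherwise.
#' @return A one-row tibble.
#' @export
fug_species <- function(name, habitat, lipid_frac, body_mass, density = 1000,
                        gill_clearance, metabolic_rate = 0, max_age,
                        assimilation = 0.8, pop_volume = NA_real_,
                        lifetime = NA_real_) {
  habitat <- match.arg(habitat, c("pelagic", "benthic", "producer"))
  .check(.num1(body_mass) && body_mass > 0, "body_mass", "must be > 0", name)
  .check(.num1(lipid_frac) && lipid_frac >= 0 && lipid_frac <= 1,
         "lipid_frac", "must be in [0, 1]", name)
  .check(.num1(assimilation) && assimilation >= 0 && assimilation <= 1,
         "assimilation", "must be in [0, 1]", name)
  .check(.num1(max_age) && max_age > 0, "max_age", "must be > 0", name)
  .check(.num1(density) && density > 0, "density", "must be > 0", name)
  .check(.num1(gill_clearance) && gill_clearance >= 0, "gill_clearance",
         "must be >= 0", name)
  .check(.num1(metabolic_rate) && metabolic_rate >= 0, "metabolic_rate",
         "must be >= 0", name)
  tibble(
    name = name, habitat = habitat, lipid_frac = lipid_frac,
    body_mass = body_mass, density = density,
    gill_clearance = gill_clearance, metabolic_rate = metabolic_rate,
    max_age = max_age, assimilation = assimilation,
    pop_volume = as.numeric(pop_volume), lifetime = as.numeric(lifetime)
  )
}

#' Food-web structure
#'
#' Couples a species table to a diet matrix `p[i, j]` = fraction of prey `j`
#' in the diet of consumer `i`. Consumer rows must sum to 1; producer rows must
#' be all zero; self-loops are rejected.
#'
#' @param species A species tibble with the columns produced by
#'   [fug_species()] (one row per species).
#' @param diet A square numeric matrix with dimnames equal to the species
#'   names, rows = consumers, columns = prey. `NULL` is allowed when all
#'   species are producers.
#' @return An object of class `fug_foodweb` with elements `species` and
#'   `diet`.
#' @export
fug_foodweb <- function(species, diet = NULL) {
  species <- as_tibble(species)
  missing_cols <- setdiff(.species_cols, names(species))
  .check(length(missing_cols) == 0, "species",
         paste("missing columns:", paste(missing_cols, collapse = ", ")),
         "foodweb")
  .check(!anyDuplicated(species$name), "species", "duplicate species names",
         "foodweb")
  n <- nrow(species)
  if (is.null(diet)) {
    diet <- matrix(0, n, n, dimnames = list(species$name, species$name))
  }
  .check(is.matrix(diet) && all(dim(diet) == n), "diet",
         "must be an n x n matrix", "foodweb")
  if (is.null(dimnames(diet))) {
    dimnames(diet) <- list(species$name, species$name)
  }
  .check(identical(rownames(diet), species$name) &&
           identical(colnames(diet), species$name), "diet",
         "dimnames must match species names (consumer rows, prey columns)",
         "foodweb")
  .check(all(diet >= 0), "diet", "fractions must be >= 0", "foodweb")
  .check(all(diag(diet) == 0), "diet", "self-loops p[i,i] > 0 not allowed",
         "foodweb")
  rs <- rowSums(diet)
  for (i in seq_len(n)) {
    if (species$habitat[i] == "producer") {
      .check(rs[i] == 0, "diet",
             paste0("producer `", species$name[i], "` must have an empty diet"),
             "foodweb")
    } else {
      .check(abs(rs[i] - 1) <= 1e-9, "diet",
             paste0("diet row of `", species$name[i], "` sums to ",
                    format(rs[i]), ", expected 1"),
             "foodweb")
    }
  }
  structure(list(species = species, diet = diet), class = "fug_foodweb")
}

#' Scenario option set
#'
#' @param population_dynamics Integrate population volumes alongside
#'   fugacities (default `FALSE`: constant populations).
#' @param mortality_to_water Fraction of the natural-mortality chemical flux of
#'   pelagic species routed to water instead of sediment (default 0, i.e. all
#'   decomposition products reach the sediment).
#' @param exclude Character vector of process groups to switch off; any of
#'   `"feeding"`, `"metabolism"`, `"mortality"`, `"reaction"`, `"advection"`,
#'   `"deposition"` (all one-way particle pathways: rain, dry and wet aerosol
#'   deposition, particle settling, resuspension) or `"burial"`. Useful for
#'   closed-system and equipartition studies.
#' @return An object of class `fug_options`.
#' @export
fug_options <- function(population_dynamics = FALSE, mortality_to_water = 0,
                        exclude = character()) {
  allowed <- c("feeding", "metabolism", "mortality", "reaction", "advection",
               "deposition", "burial")
  bad <- setdiff(exclude, allowed)
  .check(length(bad) == 0, "exclude",
         paste("unknown process:", paste(bad, collapse = ", ")), "options")
  .check(.num1(mortality_to_water) && mortality_to_water >= 0 &&
           mortality_to_water <= 1,
         "mortality_to_water", "must be in [0, 1]", "options")
  structure(
    list(population_dynamics = isTRUE(population_dynamics),
         mortality_to_water = mortality_to_water,
         exclude = exclude),
    class = "fug_options"
  )
}
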
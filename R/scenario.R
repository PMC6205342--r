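# Scenario assembly and cross-validation.

#' Assemble a model scenario
#'
#' Bundles one congener, the three environmental compartments, an optional
#' food web and the forcing into a validated scenario. Derivable fields are
#' filled here: the suspended-sediment volume fraction (from the 70/30
#' loading split) when not given, and the forcing defaults to constant
#' compartment temperatures.
#'
#' @param congener A [fug_congener()].
#' @param air,water,sediment Environmental compartments ([fug_air()],
#'   [fug_water()], [fug_sediment()]).
#' @param foodweb A [fug_foodweb()] with population volumes set, or `NULL`
#'   for an abiotic scenario.
#' @param forcing A [fug_forcing()]; defaults to constant temperatures taken
#'   from the compartments, no inflow fugacity and no emission.
#' @param options A [fug_options()].
#' @return An object of class `fug_scenario`.
#' @export
fug_scenario <- function(congener, air, water, sediment, foodweb = NULL,
                         forcing = NULL, options = fug_options()) {
  stopifnot(inherits(congener, "fug_congener"), inherits(air, "fug_air"),
            inherits(water, "fug_water"), inherits(sediment, "fug_sediment"))
  if (!is.null(foodweb)) stopifnot(inherits(foodweb, "fug_foodweb"))
  stopifnot(inherits(options, "fug_options"))
  if (is.null(water$susp_frac)) {
    water$susp_frac <- tau2_from_split(water$susp_density, water$susp_oc,
                                       koc_from_kow(congener$kow_ref))
  }
  if (is.null(forcing)) {
    forcing <- fug_forcing(air_temp = air$temp, water_temp = water$temp)
  }
  stopifnot(inherits(forcing, "fug_forcing"))
  known <- c("air", "water", "sediment",
             if (!is.null(foodweb)) foodweb$species$name)
  bad <- setdiff(names(forcing$emission), known)
  .check(length(bad) == 0, "emission",
         paste("unknown compartment:", paste(bad, collapse = ", ")),
         "forcing")
  if (!is.null(foodweb) && nrow(foodweb$species) > 0) {
    vp <- foodweb$species$pop_volume
    .check(all(!is.na(vp) & vp >= 0), "pop_volume",
           "all species need a nonnegative population volume (use balance_populations())",
           "foodweb")
  }
  structure(
    list(congener = congener, air = air, water = water, sediment = sediment,
         foodweb = foodweb, forcing = forcing, options = options),
    class = "fug_scenario"
  )
}

#' @export
print.fug_scenario <- function(x, ...) {
  n_sp <- if (is.null(x$foodweb)) 0 else nrow(x$foodweb$species)
  cat("<fug_scenario> congener", x$congener$name, "|",
      3 + n_sp, "compartments (air, water, sediment",
      if (n_sp) paste0("+ ", n_sp, " species"), ")\n")
  invisible(x)
}

# Apply the option switches by zeroing the corresponding scenario fields,
# so every downstream builder sees a consistent parameter set.
.apply_options <- function(scn) {
  ex <- scn$options$exclude
  if ("advection" %in% ex) {
    scn$air$adv_in <- scn$air$adv_out <- 0
    scn$water$adv_flow <- 0
  }
  if ("reaction" %in% ex) {
    scn$congener$lifetime_air <- Inf
    scn$congener$lifetime_water <- Inf
    scn$congener$lifetime_sediment <- Inf
  }
  if ("deposition" %in% ex) {
    scn$air$rain_rate <- scn$air$dry_dep_vel <- scn$air$scavenging <- 0
    scn$water$dep_vel <- scn$water$resusp_vel <- 0
  }
  if ("burial" %in% ex) {
    scn$sediment$burial_flow <- 0
  }
  scn
}

# Precompute everything the engine's right-hand side needs.
.compile <- function(scn) {
  stopifnot(inherits(scn, "fug_scenario"))
  scn <- .apply_options(scn)
  web <- scn$foodweb
  n_sp <- if (is.null(web)) 0L else nrow(web$species)
  comp <- c("air", "water", "sediment",
            if (n_sp) web$species$name)
  biotic_include <- setdiff(c("gill", "metabolism", "mortality", "feeding"),
                            scn$options$exclude)
  trophic <- if (n_sp && any(web$diet > 0)) trophic_levels(web) else
    if (n_sp) tibble(name = web$species$name,
                     trophic_level = rep(1, n_sp)) else NULL
  emission <- setNames(numeric(length(comp)), comp)
  emission[names(scn$forcing$emission)] <- scn$forcing$emission
  list(
    scn = scn, comp = comp, n = length(comp), n_sp = n_sp,
    web = web, trophic = trophic, biotic_include = biotic_include,
    emission = emission,
    vp0 = if (n_sp) web$species$pop_volume else numeric(),
    lipid = if (n_sp) web$species$lipid_frac else numeric(),
    volumes_env = c(scn$air$volume, scn$water$volume, scn$sediment$volume)
  )
}

# Ledger (columns of directed D-value records) at given temperatures and
# population volumes. Plain list on purpose: this is the integrator's hot
# path; build_ledger() wraps it as a tibble.
.build_ledger_at <- function(cc, temp_air, temp_water, vp) {
  scn <- cc$scn
  cap <- .capacities_core(scn$congener, scn$air, scn$water, scn$sediment,
                          temp_air, temp_water)
  parts <- list(
    .aw_chunk(cap, scn$air),
    .ws_chunk(cap, scn$water, scn$sediment),
    .ra_chunk(cap, scn$congener, scn$air, scn$water, scn$sediment)
  )
  if (cc$n_sp > 0 && length(cc$biotic_include) > 0) {
    parts <- c(parts, list(
      .biota_chunk(cc$web, scn$congener, cap, temp_water - 273.15,
                   trophic = cc$trophic,
                   mortality_to_water = scn$options$mortality_to_water,
                   pop_volume = vp, include = cc$biotic_include)
    ))
  }
  ledger <- .chunk_bind(parts)
  attr(ledger, "cap") <- cap
  ledger
}

# Per-compartment bulk capacities in compartment order (air, water, sediment,
# species...).
.z_vector <- function(cc, cap) {
  c(cap$z_air_bulk, cap$z_water_bulk, cap$z_sed_bulk,
    z_biota(cc$lipid, cap$z_water, cc$scn$congener$kow_ref))
}

#' Build the full flux ledger of a scenario
#'
#' Evaluates every D-value of the model (abiotic exchange, reaction,
#' advection, and the biotic gill/metabolism/mortality/dietary records) at
#' one time point, as a tidy table of directed flux records. The flux carried
#' by a record is `coeff * f(source)`; `kind` distinguishes internal
#' exchanges from boundary inputs and exits.
#'
#' @param scenario A [fug_scenario()].
#' @param t Time (days) at which forcing temperatures are taken.
#' @param pop_volume Optional replacement species population volumes.
#' @return A tibble with columns `name`, `source`, `sink`, `coeff`
#'   (mol Pa^-1 day^-1) and `kind`; the capacity bundle used is attached as
#'   attribute `"cap"`.
#' @export
build_ledger <- function(scenario, t = 0, pop_volume = NULL) {
  cc <- .compile(scenario)
  frc <- forcing_at(scenario$forcing, t)
  led <- .build_ledger_at(cc, frc$temp_air, frc$temp_water,
                          pop_volume %||% cc$vp0)
  cap <- attr(led, "cap")
  out <- .chunk_tbl(led[c("name", "source", "sink", "coeff", "kind")])
  attr(out, "cap") <- as_tibble(cap)
  out
}
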
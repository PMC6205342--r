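# D-value (mol Pa^-1 day^-1) transport coefficients, each an explicit
# directed (source, sink, coeff) flux record. Flux = coeff * f(source).
# `kind` is "exchange" (internal), "input" (EXTERNAL -> compartment, driven by
# an inflow fugacity) or "exit" (compartment -> EXTERNAL).
#
# The builders work on plain column lists ("chunks") because they sit on the
# integrator's hot path; the exported functions return the same records as a
# tibble.

.dchunk <- function(name, source, sink, coeff, kind) {
  n <- length(coeff)
  list(name = rep_len(name, n), source = rep_len(source, n),
       sink = rep_len(sink, n), coeff = as.numeric(coeff),
       kind = rep_len(kind, n))
}

.chunk_bind <- function(chunks) {
  chunks <- chunks[lengths(chunks) > 0]
  list(
    name = unlist(lapply(chunks, `[[`, "name"), use.names = FALSE),
    source = unlist(lapply(chunks, `[[`, "source"), use.names = FALSE),
    sink = unlist(lapply(chunks, `[[`, "sink"), use.names = FALSE),
    coeff = unlist(lapply(chunks, `[[`, "coeff"), use.names = FALSE),
    kind = unlist(lapply(chunks, `[[`, "kind"), use.names = FALSE)
  )
}

.chunk_tbl <- function(chunk) {
  structure(chunk, row.names = c(NA_integer_, -length(chunk$coeff)),
            class = c("tbl_df", "tbl", "data.frame"))
}

.aw_chunk <- function(cap, air) {
  if ((air$mtc_air == 0 || air$mtc_water == 0) && air$area_aw > 0) {
    abort("two-film resistance is degenerate: `mtc_air` and `mtc_water` must be > 0.",
          class = "fugapop_domain_error")
  }
  dv <- 1 / (1 / (air$mtc_air * air$area_aw * cap$z_gas) +
               1 / (air$mtc_water * air$area_aw * cap$z_water))
  drww <- air$area_aw * air$rain_rate * cap$z_water
  dqdw <- air$area_aw * air$dry_dep_vel * cap$z_aerosol
  dqww <- air$area_aw * air$scavenging * air$rain_rate * cap$z_aerosol
  .dchunk(c("DV", "DV", "DRWW", "DQDW", "DQWW"),
          c("air", "water", "air", "air", "air"),
          c("water", "air", "water", "water", "water"),
          c(dv, dv, drww, dqdw, dqww),
          "exchange")
}

.ws_chunk <- function(cap, water, sediment) {
  dy <- water$mtc_ws * water$area_ws * cap$z_water
  dds <- water$dep_vel * water$area_ws * cap$z_susp
  drs <- water$resusp_vel * water$area_ws * cap$z_sed_solid
  out <- .dchunk(c("DY", "DY", "DDS", "DRS"),
                 c("water", "sediment", "water", "sediment"),
                 c("sediment", "water", "sediment", "water"),
                 c(dy, dy, dds, drs),
                 "exchange")
  if (sediment$burial_flow > 0) {
    out <- .chunk_bind(list(out,
      .dchunk("DSO", "sediment", "EXTERNAL",
              sediment$burial_flow * cap$z_sed_bulk, "exit")))
  }
  out
}

.ra_chunk <- function(cap, congener, air, water, sediment) {
  nm <- c("RA", "RW", "RS", "DAI", "DAO", "DWI", "DWO")
  src <- c("air", "water", "sediment", "EXTERNAL", "air", "EXTERNAL",
           "water")
  snk <- c("EXTERNAL", "EXTERNAL", "EXTERNAL", "air", "EXTERNAL", "water",
           "EXTERNAL")
  kind <- c("exit", "exit", "exit", "input", "exit", "input", "exit")
  coeff <- c(air$volume * cap$z_air_bulk / congener$lifetime_air,
             water$volume * cap$z_water_bulk / congener$lifetime_water,
             sediment$volume * cap$z_sed_bulk / congener$lifetime_sediment,
             air$adv_in * cap$z_air_bulk,
             air$adv_out * cap$z_air_bulk,
             water$adv_flow * cap$z_water_bulk,
             water$adv_flow * cap$z_water_bulk)
  keep <- coeff > 0
  .dchunk(nm[keep], src[keep], snk[keep], coeff[keep], kind[keep])
}

.dietary_split_core <- function(ed, tmf, delta_tl) {
  if (any(delta_tl <= 0)) {
    warn("non-positive predator-prey trophic-level difference; clamped to 1e-6.")
    delta_tl <- pmax(delta_tl, 1e-6)
  }
  gut <- ed * tmf^(-delta_tl)
  list(retained = ed - gut, gut_feces = gut, undigested = 1 - ed)
}

.biota_chunk <- function(web, congener, cap, temp_c, trophic = NULL,
                         mortality_to_water = 0, pop_volume = NULL,
                         include = c("gill", "metabolism", "mortality",
                                     "feeding")) {
  sp <- web$species
  vp <- pop_volume %||% sp$pop_volume
  if (any(is.na(vp) | vp < 0)) {
    abort("population volumes must be set and >= 0 to build biotic D-values.",
          class = "fugapop_validation_error")
  }
  zb <- sp$lipid_frac * cap$z_water * congener$kow_ref
  chunks <- list()

  if ("gill" %in% include) {
    dgg <- sp$gill_clearance * vp * sp$density * cap$z_water
    env <- ifelse(sp$habitat == "benthic", "sediment", "water")
    chunks <- c(chunks, list(
      .dchunk(paste0("DGG:", sp$name), env, sp$name, dgg, "exchange"),
      .dchunk(paste0("DGL:", sp$name), sp$name, env, dgg, "exchange")
    ))
  }

  if ("metabolism" %in% include) {
    rb <- vp * zb * sp$metabolic_rate
    keep <- rb > 0
    if (any(keep)) {
      chunks <- c(chunks, list(
        .dchunk(paste0("RB:", sp$name[keep]), sp$name[keep], "EXTERNAL",
                rb[keep], "exit")
      ))
    }
  }

  if ("mortality" %in% include) {
    dmd <- natural_mortality_rate(sp$max_age) * .const$mortality_mass_scale *
      vp * zb
    to_water <- ifelse(sp$habitat == "benthic", 0, mortality_to_water)
    dmd_s <- dmd * (1 - to_water)
    dmd_w <- dmd * to_water
    keep <- dmd_s > 0
    if (any(keep)) {
      chunks <- c(chunks, list(
        .dchunk(paste0("DMD:", sp$name[keep]), sp$name[keep], "sediment",
                dmd_s[keep], "exchange")
      ))
    }
    keep <- dmd_w > 0
    if (any(keep)) {
      chunks <- c(chunks, list(
        .dchunk(paste0("DMDW:", sp$name[keep]), sp$name[keep], "water",
                dmd_w[keep], "exchange")
      ))
    }
  }

  if ("feeding" %in% include && any(web$diet > 0)) {
    tl <- (trophic %||% trophic_levels(web))$trophic_level
    feed <- feeding_rate(temp_c, sp$body_mass)
    pairs <- which(web$diet > 0, arr.ind = TRUE)
    pred <- pairs[, 1]
    prey <- pairs[, 2]
    base <- feed[pred] * sp$density[pred] * vp[pred] *
      web$diet[pairs] * zb[prey]
    ed <- sp$assimilation[pred]
    if (any(ed < 0 | ed > 1)) {
      abort("`assimilation` must be in [0, 1].",
            class = "fugapop_validation_error")
    }
    split <- .dietary_split_core(ed, congener$tmf, tl[pred] - tl[prey])
    lab <- paste0(sp$name[prey], "->", sp$name[pred])
    chunks <- c(chunks, list(
      .dchunk(paste0("DFI:", lab), sp$name[prey], sp$name[pred],
              base * split$retained, "exchange"),
      .dchunk(paste0("DEX:", lab), sp$name[prey], "sediment",
              base * split$gut_feces, "exchange"),
      .dchunk(paste0("DEG:", lab), sp$name[prey], "sediment",
              base * split$undigested, "exchange")
    ))
  }

  if (length(chunks) == 0) {
    return(.dchunk(character(), character(), character(), numeric(),
                   character()))
  }
  .chunk_bind(chunks)
}

#' Air-water exchange D-values
#'
#' * `DV` — two-film volatilisation/absorption, the series resistance
#'   `(1/(kVA AAW Z_gas) + 1/(kVW AAW Z_wat))^-1`, registered in both
#'   directions;
#' * `DRWW` — wet dissolution (rain), `AAW UQ Z_wat`, air to water;
#' * `DQDW` — dry aerosol deposition, `AAW vQ Z_aer`, air to water;
#' * `DQWW` — wet aerosol scavenging, `AAW UR UQ Z_aer`, air to water.
#'
#' The deposition velocity `vQ` and scavenging ratio `UR` act on the full
#' aerosol-phase capacity `Z_aer`, so they are aerosol-volumetric quantities
#' (particle velocity scaled by the aerosol volume fraction).
#'
#' @param cap Capacity bundle from [fug_capacities()].
#' @param air A [fug_air()].
#' @return A ledger tibble (`name`, `source`, `sink`, `coeff`, `kind`).
#' @export
air_water_dvalues <- function(cap, air) {
  .chunk_tbl(.aw_chunk(cap, air))
}

#' Water-sediment exchange D-values
#'
#' * `DY` — diffusive exchange `kSW ASW Z_wat`, both directions;
#' * `DDS` — particle deposition `UDP ASW Z_susp`, water to sediment;
#' * `DRS` — resuspension `URS ASW Z_sol`, sediment to water;
#' * `DSO` — burial `GS Z_S` out of the system (exit; off when the burial
#'   flow is zero).
#'
#' @param cap Capacity bundle from [fug_capacities()].
#' @param water A [fug_water()].
#' @param sediment A [fug_sediment()].
#' @return A ledger tibble.
#' @export
water_sediment_dvalues <- function(cap, water, sediment) {
  .chunk_tbl(.ws_chunk(cap, water, sediment))
}

#' Reaction and advection D-values of the abiotic compartments
#'
#' Reaction: `R_x = V_x Z_x / lifetime_x` (exit). Advection: `D = G Z_bulk`,
#' with inputs carrying the inflow fugacity from the forcing and outputs
#' leaving at the resident fugacity.
#'
#' @param cap Capacity bundle from [fug_capacities()].
#' @param congener A [fug_congener()] (reaction lifetimes).
#' @param air,water A [fug_air()] and [fug_water()] (advective flows,
#'   volumes).
#' @param sediment A [fug_sediment()].
#' @return A ledger tibble; rows with zero coefficient (e.g. infinite
#'   lifetime) are dropped.
#' @export
reaction_advection_dvalues <- function(cap, congener, air, water, sediment) {
  .chunk_tbl(.ra_chunk(cap, congener, air, water, sediment))
}

#' Three-way partition of ingested chemical
#'
#' Chemical ingested with food is split into a retained part that reaches the
#' predator, a gut-feces exchange part governed by the trophic magnification
#' factor, and an undigested part; the last two are egested to the sediment:
#' \deqn{retained = E_D (TMF^{\Delta TL} - 1)/TMF^{\Delta TL},}
#' \deqn{gut feces = E_D\, TMF^{-\Delta TL}, \quad undigested = 1 - E_D,}
#' with \eqn{\Delta TL} the predator-prey trophic-level difference. The three
#' fractions sum to one for any valid inputs, so ingestion conserves
#' chemical. TMF = 1 gives zero net magnification (all absorbed chemical is
#' re-exchanged to the feces). Non-positive \eqn{\Delta TL} (a loop or
#' cannibalistic pair) is clamped to 1e-6 with a warning.
#'
#' @param ed Dietary absorption efficiency E_D in `[0, 1]`.
#' @param tmf Trophic magnification factor (> 0).
#' @param delta_tl Trophic-level difference TL_predator - TL_prey.
#' @return A tibble with columns `retained`, `gut_feces`, `undigested`.
#' @examples
#' dietary_split(ed = 0.8, tmf = 2, delta_tl = 1)
#' @export
dietary_split <- function(ed, tmf, delta_tl) {
  if (any(ed < 0 | ed > 1)) {
    abort("`ed` must be in [0, 1].", class = "fugapop_validation_error")
  }
  if (any(tmf <= 0)) {
    abort("`tmf` must be > 0.", class = "fugapop_validation_error")
  }
  as_tibble(.dietary_split_core(ed, tmf, delta_tl))
}

#' Biotic D-values of the food web
#'
#' For every species: gill uptake/release `DGG = DGL = k1 VP rho Z_wat`
#' (pure-water capacity), exchanging with the water fugacity for pelagic
#' species and producers and with the sediment (pore-water) fugacity for
#' benthic species; metabolic loss `RB = VP Z_B kM` (exit); natural-mortality
#' chemical flux `DMD = M(tmax) * mass scale * VP Z_B` routed to the
#' sediment (optionally partly to water for pelagic species). For every
#' predator-prey pair, the dietary flux `feed(T, WB_i) rho_i VP_i p_ij Z_Bj`
#' acting on the prey fugacity is split by [dietary_split()] into a
#' prey-to-predator part and two prey-to-sediment egestion parts. The same
#' records read from the prey side are its predation losses.
#'
#' @param web A [fug_foodweb()] with population volumes set.
#' @param congener A [fug_congener()] (TMF).
#' @param cap Capacity bundle from [fug_capacities()].
#' @param temp_c Water temperature (degC) for the feeding kernel.
#' @param trophic Optional precomputed [trophic_levels()] result.
#' @param mortality_to_water Fraction of the pelagic mortality flux routed to
#'   water (default 0: all to sediment).
#' @param pop_volume Optional replacement population volumes (m^3).
#' @param include Character vector of biotic process groups to build; any of
#'   `"gill"`, `"metabolism"`, `"mortality"`, `"feeding"`.
#' @return A ledger tibble with one row per directed flux, named e.g.
#'   `"DGG:perch"`, `"DFI:zoo->perch"`, `"DEX:zoo->perch"`.
#' @export
biota_dvalues <- function(web, congener, cap, temp_c, trophic = NULL,
                          mortality_to_water = 0, pop_volume = NULL,
                          include = c("gill", "metabolism", "mortality",
                                      "feeding")) {
  stopifnot(inherits(web, "fug_foodweb"))
  .chunk_tbl(.biota_chunk(web, congener, cap, temp_c, trophic = trophic,
                          mortality_to_water = mortality_to_water,
                          pop_volume = pop_volume, include = include))
}
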
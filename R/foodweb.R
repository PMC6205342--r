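# Food-web structure: trophic levels, allometric population rates,
# steady-population closure and the energy-mass primary-producer estimator.

#' Trophic levels of a food web
#'
#' Solves the linear fixed point TL = 1 + P TL, where `P` is the diet matrix
#' (consumer rows, prey columns). Producers get exactly 1; cycles are
#' supported as long as the system is non-singular.
#'
#' @param web A [fug_foodweb()].
#' @return A tibble with columns `name` and `trophic_level` (>= 1).
#' @examples
#' sp <- rbind(
#'   fug_species("alga", "producer", 0.01, 1e-12, gill_clearance = 5,
#'               max_age = 0.1, pop_volume = 10),
#'   fug_species("grazer", "pelagic", 0.02, 1e-7, gill_clearance = 5,
#'               max_age = 2)
#' )
#' d <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE,
#'             dimnames = list(sp$name, sp$name))
#' trophic_levels(fug_foodweb(sp, d))
#' @export
trophic_levels <- function(web) {
  stopifnot(inherits(web, "fug_foodweb"))
  p <- web$diet
  n <- nrow(p)
  a <- diag(n) - p
  tl <- tryCatch(
    solve(a, rep(1, n)),
    error = function(e) {
      abort(paste0("trophic-level system is singular (pathological cycle ",
                   "among: ", paste(web$species$name, collapse = ", "), ")"),
            class = "fugapop_no_solution_error")
    }
  )
  tibble(name = web$species$name, trophic_level = as.numeric(tl))
}

#' Allometric specific growth rate
#'
#' kG = 0.00586 * 1.113^(T - 20) * (1000 WB)^-0.2 per day: warm water and
#' small body mass speed up specific growth.
#'
#' @param temp_c Temperature in degrees Celsius.
#' @param body_mass Body mass W_B in kg.
#' @return Specific growth rate (day^-1), vectorised.
#' @examples
#' growth_rate(20, 0.001)  # both factors unity
#' @export
growth_rate <- function(temp_c, body_mass) {
  if (any(body_mass <= 0)) {
    abort("`body_mass` must be > 0.", class = "fugapop_domain_error")
  }
  .const$growth_coef * .const$growth_temp_base^(temp_c - 20) *
    (1000 * body_mass)^(-0.2)
}

#' Mass-specific feeding rate
#'
#' feed(T, WB) = 0.022 e^(0.06 T) WB^-0.15, in kg of food per kg of predator
#' per day. The gross ingestion rate of a predator is `feed * WB`.
#'
#' @inheritParams growth_rate
#' @return Feeding rate (day^-1), vectorised.
#' @examples
#' feeding_rate(0, 1)  # both factors unity
#' @export
feeding_rate <- function(temp_c, body_mass) {
  if (any(body_mass <= 0)) {
    abort("`body_mass` must be > 0.", class = "fugapop_domain_error")
  }
  .const$feeding_coef * exp(.const$feeding_temp_slope * temp_c) *
    body_mass^(-0.15)
}

#' Longevity-based natural mortality rate
#'
#' The empirical longevity model M = 4.899 tmax^-0.916 per year, converted to
#' day^-1 by default. The chemical mortality D-value additionally carries the
#' per-mille bookkeeping factor `mortality_mass_scale` of [fug_constants()]
#' (see [biota_dvalues()]); the population balance does not.
#'
#' @param max_age Maximum age t_max in years.
#' @param annualized Return yr^-1 instead of day^-1? Default `FALSE`.
#' @return Natural mortality rate, vectorised.
#' @examples
#' natural_mortality_rate(1, annualized = TRUE)  # 4.899
#' natural_mortality_rate(10, annualized = TRUE)
#' @export
natural_mortality_rate <- function(max_age, annualized = FALSE) {
  if (any(max_age <= 0)) {
    abort("`max_age` must be > 0.", class = "fugapop_domain_error")
  }
  m <- .const$mortality_annual_coef * max_age^.const$mortality_exponent
  if (annualized) m else m / .const$days_per_year
}

#' Population volume lost to predation
#'
#' For each species, sums the ingestion of its predators:
#' sum_k feed(T, WB_k) rho_k VP_k p\[k, i\] / rho_i (m^3 of prey per day) —
#' predator biomass intake converted to prey volume via the prey density.
#'
#' @param web A [fug_foodweb()] with predator `pop_volume` set.
#' @param temp_c Water temperature (degC).
#' @param pop_volume Optional replacement vector of population volumes
#'   (m^3), in species order; defaults to the table's `pop_volume`.
#' @return A tibble with columns `name` and `predation_loss` (m^3 day^-1).
#' @export
predation_loss <- function(web, temp_c, pop_volume = NULL) {
  stopifnot(inherits(web, "fug_foodweb"))
  sp <- web$species
  vp <- pop_volume %||% sp$pop_volume
  feed <- feeding_rate(temp_c, sp$body_mass)
  # loss_i = sum_k feed_k rho_k vp_k p[k, i] / rho_i
  intake <- feed * sp$density * vp            # kg food per day per predator k
  loss <- as.numeric(crossprod(web$diet, intake)) / sp$density
  tibble(name = sp$name, predation_loss = loss)
}

#' Energy parameters for primary-producer biomass estimation
#'
#' @param solar_flux Mean solar energy flux at the surface (J s^-1 m^-2).
#' @param photosyn_eff Photosynthetic efficiency (fraction).
#' @param coverage Areal coverage of the producer (fraction).
#' @param transport_factor Fraction of fixed energy retained in the system.
#' @param carbon_prod Carbon production factor (g carbon per J).
#' @param carbon_frac Carbon mass fraction of the organism (> 0).
#' @param area Surface area (m^2).
#' @return An object of class `fug_energy`.
#' @export
fug_energy <- function(solar_flux, photosyn_eff, coverage = 1,
                       transport_factor = 1, carbon_prod, carbon_frac,
                       area) {
  for (f in c("photosyn_eff", "coverage", "transport_factor")) {
    v <- get(f)
    .check(.num1(v) && v >= 0 && v <= 1, f, "must be in [0, 1]", "energy")
  }
  for (f in c("solar_flux", "carbon_prod", "area")) {
    v <- get(f)
    .check(.num1(v) && v >= 0, f, "must be >= 0", "energy")
  }
  .check(.num1(carbon_frac) && carbon_frac > 0, "carbon_frac",
         "must be > 0", "energy")
  structure(list(solar_flux = solar_flux, photosyn_eff = photosyn_eff,
                 coverage = coverage, transport_factor = transport_factor,
                 carbon_prod = carbon_prod, carbon_frac = carbon_frac,
                 area = area),
            class = "fug_energy")
}

#' Energy-mass estimate of primary-producer standing stock
#'
#' Daily areal carbon fixation (solar flux x photosynthetic efficiency x
#' coverage x transport factor x carbon production factor x area, with the
#' seconds-to-day factor made explicit) times the average lifetime of the
#' producer, divided by its carbon mass fraction to convert carbon to
#' biomass:
#' \deqn{m = E_{solar} \cdot 86400 \cdot \varphi_{PE} \sigma_C \varphi_T
#'       \vartheta_C A \tau / \varphi_C.}
#'
#' @param energy A [fug_energy()].
#' @param lifetime Average lifetime of the producer (days).
#' @return Standing stock in grams.
#' @examples
#' ep <- fug_energy(solar_flux = 200, photosyn_eff = 1, coverage = 1,
#'                  carbon_prod = 1.5e-6, carbon_frac = 0.5, area = 1e6)
#' primary_producer_biomass(ep, lifetime = 5)
#' @export
primary_producer_biomass <- function(energy, lifetime) {
  stopifnot(inherits(energy, "fug_energy"))
  if (!.num1(lifetime) || lifetime <= 0) {
    abort("`lifetime` must be > 0 days.", class = "fugapop_domain_error")
  }
  energy$solar_flux * .const$seconds_per_day * energy$photosyn_eff *
    energy$coverage * energy$transport_factor * energy$carbon_prod *
    energy$area * lifetime / energy$carbon_frac
}

#' Steady-population closure of the food web
#'
#' Under constant population sizes, growth balances natural mortality plus
#' predation for every species. With producer populations fixed, this is a
#' linear system in the consumer population volumes: one balance equation per
#' preyed-upon species, one unknown per consumer. Apex species (never preyed
#' upon) contribute no equation; their own imbalance
#' (kG - M) VP is reported as a residual, not forced to zero.
#'
#' @param web A [fug_foodweb()] whose producers have `pop_volume` set.
#' @param temp_c Water temperature (degC) at which rates are evaluated.
#' @return A tibble with columns `name`, `habitat`, `trophic_level`,
#'   `pop_volume` (m^3, solved for consumers), `residual` (m^3 day^-1, the
#'   net dV/dt at the returned volumes) and `apex` (logical).
#' @export
balance_populations <- function(web, temp_c) {
  stopifnot(inherits(web, "fug_foodweb"))
  sp <- web$species
  n <- nrow(sp)
  p <- web$diet
  tl <- trophic_levels(web)$trophic_level

  is_consumer <- rowSums(p) > 0
  is_preyed <- colSums(p) > 0
  if (any(!is_consumer & (is.na(sp$pop_volume) | sp$pop_volume <= 0))) {
    bad <- sp$name[!is_consumer &
                     (is.na(sp$pop_volume) | sp$pop_volume <= 0)]
    abort(paste0("producer population volume must be fixed and positive: ",
                 paste(bad, collapse = ", ")),
          class = "fugapop_validation_error")
  }

  kg <- growth_rate(temp_c, sp$body_mass)
  m <- natural_mortality_rate(sp$max_age)
  surplus <- kg - m
  feed <- feeding_rate(temp_c, sp$body_mass)
  # c[i, k]: prey volume of i consumed per unit predator volume VP_k per day
  cik <- t(p) * rep(feed * sp$density, each = n) / sp$density

  unknown <- which(is_consumer)
  eqs <- which(is_preyed)
  if (length(unknown) > 0) {
    a <- matrix(0, length(eqs), length(unknown),
                dimnames = list(sp$name[eqs], sp$name[unknown]))
    b <- numeric(length(eqs))
    for (r in seq_along(eqs)) {
      i <- eqs[r]
      for (s in seq_along(unknown)) {
        k <- unknown[s]
        a[r, s] <- -cik[i, k] + if (i == k) surplus[i] else 0
      }
      b[r] <- if (is_consumer[i]) 0 else surplus[i] * sp$pop_volume[i]
      if (!is_consumer[i]) a[r, ] <- -a[r, ] else b[r] <- b[r]
    }
    # producer rows were negated so that predator coefficients are positive;
    # the solution is unchanged. Least squares when the web is branched.
    vp_new <- tryCatch(
      qr.solve(a, b),
      error = function(e) {
        abort("population balance system is singular.",
              class = "fugapop_no_solution_error")
      }
    )
    if (any(vp_new < 0)) {
      abad <- names(vp_new)[vp_new < 0]
      abort(paste0("infeasible web: negative population volume for ",
                   paste(abad, collapse = ", ")),
            class = "fugapop_infeasible_error")
    }
    sp$pop_volume[unknown] <- as.numeric(vp_new)
  }

  web2 <- fug_foodweb(sp, p)
  res <- dv_dt(web2, temp_c)
  tibble(
    name = sp$name, habitat = sp$habitat, trophic_level = tl,
    pop_volume = sp$pop_volume, residual = res$dv_dt,
    apex = !is_preyed
  )
}

#' Population volume rate of change
#'
#' dV/dt = growth - natural mortality - predation loss per species
#' (m^3 day^-1). Zero for every non-apex species at balanced populations.
#'
#' @inheritParams balance_populations
#' @param pop_volume Optional replacement vector of population volumes.
#' @return A tibble with columns `name`, `growth`, `mortality`, `predation`
#'   and `dv_dt` (all m^3 day^-1).
#' @export
dv_dt <- function(web, temp_c, pop_volume = NULL) {
  stopifnot(inherits(web, "fug_foodweb"))
  sp <- web$species
  vp <- pop_volume %||% sp$pop_volume
  g <- growth_rate(temp_c, sp$body_mass) * vp
  m <- natural_mortality_rate(sp$max_age) * vp
  pl <- predation_loss(web, temp_c, pop_volume = vp)$predation_loss
  tibble(name = sp$name, growth = g, mortality = m, predation = pl,
         dv_dt = g - m - pl)
}
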
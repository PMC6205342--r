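#' Model constants
#'
#' Named physical and empirical constants used throughout the model. They are
#' exposed in one place so that every hard-wired coefficient of the rate laws
#' is visible and auditable:
#'
#' * `R` — ideal gas constant, 8.314 J mol^-1 K^-1.
#' * `koc_kow_ratio` — organic-carbon/octanol partition ratio, K_OC = 0.41 K_OW
#'   (K_OC in L kg^-1). K_OC is always derived, never user-entered, so the
#'   dissolved/particulate loading split cancels exactly.
#' * `aerosol_z_factor` — the 0.1 factor in the aerosol capacity
#'   Z_aerosol = 0.1 Z_gas K_OA.
#' * `growth_coef` — allometric specific growth coefficient, 0.00586 day^-1 at
#'   20 degC for a 1 g organism.
#' * `growth_temp_base` — 1.113, the per-degC multiplier of the growth law.
#' * `feeding_coef` — 0.022 kg food (kg predator)^-1 day^-1 at 0 degC for a
#'   1 kg predator.
#' * `feeding_temp_slope` — 0.06 degC^-1 exponent slope of the feeding kernel.
#' * `mortality_annual_coef` — 4.899 yr^-1 at a maximum age of 1 year
#'   (empirical longevity-based natural-mortality model).
#' * `mortality_exponent` — -0.916, the longevity exponent of that model.
#' * `mortality_mass_scale` — 1e-3, the residual per-mille bookkeeping factor
#'   carried by the chemical mortality D-value (see [natural_mortality_rate()]).
#' * `seconds_per_day`, `days_per_year` — unit conversions.
#'
#' @return A named list of numeric constants.
#' @examples
#' fug_constants()$koc_kow_ratio
#' @export
fug_constants <- function() {
  list(
    R = 8.314,
    koc_kow_ratio = 0.41,
    aerosol_z_factor = 0.1,
    growth_coef = 0.00586,
    growth_temp_base = 1.113,
    feeding_coef = 0.022,
    feeding_temp_slope = 0.06,
    mortality_annual_coef = 4.899,
    mortality_exponent = -0.916,
    mortality_mass_scale = 1e-3,
    seconds_per_day = 86400,
    days_per_year = 365
  )
}

.const <- fug_constants()

#' Organic-carbon partition coefficient from K_OW
#'
#' K_OC (L kg^-1) is taken as a fixed fraction (0.41) of the octanol-water
#' partition coefficient.
#'
#' @param kow Octanol-water partition coefficient (dimensionless, > 0).
#' @return K_OC in L kg^-1.
#' @examples
#' koc_from_kow(1e6)
#' @export
koc_from_kow <- function(kow) {
  if (any(!is.finite(kow) | kow <= 0)) {
    abort("`kow` must be positive and finite.", class = "fugapop_domain_error")
  }
  .const$koc_kow_ratio * kow
}
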
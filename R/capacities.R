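# Fugacity capacities Z (mol Pa^-1 m^-3) for every phase, their temperature
# dependence, and their analytic time derivatives.

#' Temperature-dependent octanol-air partition coefficient
#'
#' log10 K_OA is linear in inverse temperature: K_OA(T) = 10^(a/T + b).
#'
#' @param congener A [fug_congener()].
#' @param temp Temperature (K).
#' @return K_OA (dimensionless), vectorised over `temp`.
#' @examples
#' c153 <- fug_congener("x", kow_ref = 1e6, koa_a = 3000, koa_b = -2,
#'                      henry_ref = 20)
#' koa_at(c153, 300)
#' @export
koa_at <- function(congener, temp) {
  stopifnot(inherits(congener, "fug_congener"))
  if (any(!is.finite(temp) | temp <= 0)) {
    abort("`temp` must be positive (kelvin).", class = "fugapop_domain_error")
  }
  10^(congener$koa_a / temp + congener$koa_b)
}

#' Temperature-corrected Henry's law constant
#'
#' van't Hoff correction:
#' H(T) = H_ref exp(-(dU_AW / R) (1/T - 1/T_ref)).
#'
#' @inheritParams koa_at
#' @return H (Pa m^3 mol^-1), vectorised over `temp`.
#' @export
henry_at <- function(congener, temp) {
  stopifnot(inherits(congener, "fug_congener"))
  if (any(!is.finite(temp) | temp <= 0)) {
    abort("`temp` must be positive (kelvin).", class = "fugapop_domain_error")
  }
  congener$henry_ref *
    exp(-(congener$du_aw / .const$R) * (1 / temp - 1 / congener$t_ref))
}

#' Octanol-water partition coefficient, optionally temperature-corrected
#'
#' K_OW is far less temperature-sensitive than H and is held constant by
#' default. Setting `temperature_correction = TRUE` applies the analogous
#' van't Hoff correction with `du_ow`.
#'
#' @inheritParams koa_at
#' @param temperature_correction Apply the van't Hoff correction with
#'   `congener$du_ow`? Default `FALSE` (constant K_OW).
#' @return K_OW (dimensionless).
#' @export
kow_at <- function(congener, temp, temperature_correction = FALSE) {
  stopifnot(inherits(congener, "fug_congener"))
  if (!temperature_correction) {
    return(rep_len(congener$kow_ref, length(temp)))
  }
  if (any(!is.finite(temp) | temp <= 0)) {
    abort("`temp` must be positive (kelvin).", class = "fugapop_domain_error")
  }
  congener$kow_ref *
    exp(-(congener$du_ow / .const$R) * (1 / temp - 1 / congener$t_ref))
}

#' Fugacity capacities of all abiotic phases
#'
#' Computes the phase capacities (gas, aerosol, dissolved water, suspended
#' sediment, sediment solid) and the bulk compartment capacities:
#' \deqn{Z_{gas} = 1/(R T_A), \quad Z_{aer} = 0.1 Z_{gas} K_{OA},}
#' \deqn{Z_{wat} = 1/H(T_W), \quad Z_{susp} = Z_{wat}\rho_5\delta_5 K_{OC}/1000,}
#' \deqn{Z_{sol} = Z_{wat}\rho_4\delta_4 K_{OC}/1000,}
#' with bulk values \eqn{Z_A = Z_{gas} + \tau_1 Z_{aer}},
#' \eqn{Z_W = Z_{wat} + \tau_2 Z_{susp}},
#' \eqn{Z_S = (1-\tau_3) Z_{wat} + \tau_3 Z_{sol}}. K_OC is always derived as
#' 0.41 K_OW. Densities are in kg m^-3 and K_OC in L kg^-1, hence the /1000.
#'
#' @param congener A [fug_congener()].
#' @param air A [fug_air()].
#' @param water A [fug_water()]. If `susp_frac` is `NULL` it is derived via
#'   [tau2_from_split()].
#' @param sediment A [fug_sediment()].
#' @param temp_air,temp_water Optional temperature overrides (K); default to
#'   the compartment temperatures.
#' @return A one-row tibble with columns `z_gas`, `z_aerosol`, `z_water`,
#'   `z_susp`, `z_sed_solid`, `z_air_bulk`, `z_water_bulk`, `z_sed_bulk`
#'   (all mol Pa^-1 m^-3), plus the `koc` and derived `susp_frac` used.
#' @examples
#' c153 <- fug_congener("x", kow_ref = 1e6, koa_a = 3000, koa_b = -2,
#'                      henry_ref = 20)
#' air <- fug_air(volume = 1e10, temp = 298.15, area_aw = 1e7,
#'                mtc_air = 70, mtc_water = 0.7)
#' wat <- fug_water(volume = 1e8, temp = 285, susp_density = 1500,
#'                  susp_oc = 0.1, area_ws = 1e7)
#' sed <- fug_sediment(volume = 1e6, solid_frac = 0.1, solid_density = 2400,
#'                     solid_oc = 0.03)
#' fug_capacities(c153, air, wat, sed)
#' @export
fug_capacities <- function(congener, air, water, sediment,
                           temp_air = NULL, temp_water = NULL) {
  stopifnot(inherits(congener, "fug_congener"), inherits(air, "fug_air"),
            inherits(water, "fug_water"), inherits(sediment, "fug_sediment"))
  as_tibble(.capacities_core(congener, air, water, sediment,
                             temp_air %||% air$temp,
                             temp_water %||% water$temp))
}

# plain-list twin of fug_capacities for the integrator's hot path
.capacities_core <- function(congener, air, water, sediment, ta, tw) {
  kow <- congener$kow_ref
  koc <- .const$koc_kow_ratio * kow
  if (ta <= 0 || tw <= 0) {
    abort("temperatures must be positive kelvin.",
          class = "fugapop_domain_error")
  }
  z_gas <- 1 / (.const$R * ta)
  z_aerosol <- .const$aerosol_z_factor * z_gas *
    10^(congener$koa_a / ta + congener$koa_b)
  z_water <- 1 / (congener$henry_ref *
                    exp(-(congener$du_aw / .const$R) *
                          (1 / tw - 1 / congener$t_ref)))
  z_susp <- z_water * water$susp_density * water$susp_oc * koc / 1000
  z_sed_solid <- z_water * sediment$solid_density * sediment$solid_oc *
    koc / 1000

  tau2 <- water$susp_frac %||%
    tau2_from_split(water$susp_density, water$susp_oc, koc)
  tau1 <- air$aerosol_frac
  tau3 <- sediment$solid_frac

  list(
    z_gas = z_gas, z_aerosol = z_aerosol, z_water = z_water, z_susp = z_susp,
    z_sed_solid = z_sed_solid,
    z_air_bulk = z_gas + tau1 * z_aerosol,
    z_water_bulk = z_water + tau2 * z_susp,
    z_sed_bulk = (1 - tau3) * z_water + tau3 * z_sed_solid,
    koc = koc, susp_frac = tau2
  )
}

#' Biota fugacity capacity
#'
#' Z_B = L Z_W K_OW: chemical storage in an organism is dominated by its lipid
#' pool, modelled as octanol.
#'
#' @param lipid_frac Lipid fraction L (0-1).
#' @param z_water_pure Pure-water capacity Z_W (mol Pa^-1 m^-3).
#' @param kow Octanol-water partition coefficient.
#' @return Z_B (mol Pa^-1 m^-3).
#' @examples
#' z_biota(0.05, 0.02, 1e6)
#' @export
z_biota <- function(lipid_frac, z_water_pure, kow) {
  if (any(lipid_frac < 0 | lipid_frac > 1 | !is.finite(lipid_frac))) {
    abort("`lipid_frac` must be in [0, 1].",
          class = "fugapop_validation_error")
  }
  lipid_frac * z_water_pure * kow
}

#' Suspended-sediment volume fraction from the loading split
#'
#' Derives the suspended-sediment volume fraction tau_2 that makes the
#' equal-fugacity dissolved/particulate partition of water-column chemical
#' match the observed 70 % / 30 % loading allocation:
#' \deqn{\tau_2 = 3000 / (7 \rho_5 \delta_5 K_{OC}).}
#' By construction the dissolved mass share
#' Z_wat / (Z_wat + tau_2 Z_susp) is exactly 0.70, independent of the
#' arguments.
#'
#' @param susp_density Suspended-sediment density rho_5 (kg m^-3).
#' @param susp_oc Organic-carbon mass fraction delta_5.
#' @param koc Organic-carbon partition coefficient (L kg^-1).
#' @return Volume fraction tau_2 (dimensionless).
#' @examples
#' tau2_from_split(1500, 0.1, 41000)
#' @export
tau2_from_split <- function(susp_density, susp_oc, koc) {
  if (any(c(susp_density, susp_oc, koc) <= 0) ||
      any(!is.finite(c(susp_density, susp_oc, koc)))) {
    abort("all arguments must be positive.", class = "fugapop_domain_error")
  }
  3000 / (7 * susp_density * susp_oc * koc)
}

#' Analytic time derivatives of the fugacity capacities
#'
#' Exact derivatives of the bulk capacities along a temperature trajectory,
#' given the current temperature rates of change. Sediment and biota share the
#' water temperature. With K_OW constant and lipid content constant,
#' \deqn{dZ_B/dt = -L K_{OW} \frac{\Delta U_{AW}}{H R T_W^2} \frac{dT_W}{dt}.}
#' The air derivative combines the 1/T_A^2 gas term with the chain-rule
#' derivative of K_OA(T_A); water and sediment scale the van't Hoff derivative
#' of 1/H by their particle content.
#'
#' @inheritParams fug_capacities
#' @param dtemp_air_dt,dtemp_water_dt Temperature rates of change
#'   (K day^-1).
#' @param lipid_frac Optional numeric vector of species lipid fractions; one
#'   `dz_biota` value is returned per element.
#' @return A list with `dz_air`, `dz_water`, `dz_sed` (scalars) and
#'   `dz_biota` (vector along `lipid_frac`), all in mol Pa^-1 m^-3 day^-1.
#' @export
dz_dt <- function(congener, air, water, sediment,
                  dtemp_air_dt = 0, dtemp_water_dt = 0,
                  lipid_frac = numeric(), temp_air = NULL, temp_water = NULL) {
  stopifnot(inherits(congener, "fug_congener"))
  ta <- temp_air %||% air$temp
  tw <- temp_water %||% water$temp
  if (any(c(ta, tw) <= 0)) {
    abort("temperatures must be positive.", class = "fugapop_domain_error")
  }
  R <- .const$R
  kow <- congener$kow_ref
  koc <- koc_from_kow(kow)
  tau1 <- air$aerosol_frac
  tau2 <- water$susp_frac %||%
    tau2_from_split(water$susp_density, water$susp_oc, koc)
  tau3 <- sediment$solid_frac

  # Air: Z_A = (1 + 0.1 tau1 K_OA) / (R T_A), K_OA = 10^(a/T + b).
  koa <- koa_at(congener, ta)
  af <- .const$aerosol_z_factor
  dza <- (-(1 + af * tau1 * koa) / (R * ta^2) -
            af * tau1 * congener$koa_a * log(10) * koa / (R * ta^3)) *
    dtemp_air_dt

  # Water: Z_W = (1 + tau2 rho5 d5 Koc/1000) / H; dH/dT = H dU_AW/(R T^2).
  h <- henry_at(congener, tw)
  dlnh_dt <- congener$du_aw / (R * tw^2) * dtemp_water_dt
  part_w <- 1 + tau2 * water$susp_density * water$susp_oc * koc / 1000
  dzw <- -part_w / h * dlnh_dt

  # Sediment: Z_S = (1 - tau3 + tau3 rho4 d4 Koc/1000) / H.
  part_s <- (1 - tau3) + tau3 * sediment$solid_density * sediment$solid_oc *
    koc / 1000
  dzs <- -part_s / h * dlnh_dt

  # Biota: Z_B = L Kow / H with dL/dt = 0 (constant lipid content).
  dzb <- -lipid_frac * kow / h * dlnh_dt

  list(dz_air = dza, dz_water = dzw, dz_sed = dzs, dz_biota = dzb)
}
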
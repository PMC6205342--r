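# Sediment composition closure: empirical relations linking organic-carbon
# content, dry bulk density, solid density and water content of the bio-active
# sediment layer.

#' Sediment solid density from organic-matter content
#'
#' Two-component mixture of organic matter (1.25 g cm^-3) and mineral
#' particles (conventionally 2.65 g cm^-3):
#' solid density = 1.25 OM + 2.65 (1 - OM).
#'
#' @param om_frac Organic-matter mass fraction (0-1).
#' @return Solid density in g cm^-3.
#' @examples
#' sediment_solid_density(0)     # pure mineral
#' sediment_solid_density(0.17)
#' @export
sediment_solid_density <- function(om_frac) {
  if (any(om_frac < 0 | om_frac > 1)) {
    abort("`om_frac` must be in [0, 1].", class = "fugapop_domain_error")
  }
  1.25 * om_frac + 2.65 * (1 - om_frac)
}

.dry_bulk_density <- function(oc) 1.776 - 0.363 * log(oc)

.oc_max <- exp(1.776 / 0.363) # dry bulk density reaches zero here

.sed_forward <- function(oc) {
  dbd <- .dry_bulk_density(oc)
  om <- 1.7 * oc / 1000
  sd <- sediment_solid_density(om)
  solid_frac <- dbd / sd
  list(oc = oc, om = om, dry_bulk_density = dbd, solid_density = sd,
       solid_frac = solid_frac, water_content = 1 - solid_frac)
}

#' Sediment composition from organic carbon or water content
#'
#' Forward mode (`oc` given): the dry bulk density follows the empirical
#' regression `1.776 - 0.363 ln(OC)` (g cm^-3, OC in mg per dry-weight g),
#' organic matter is `OM = 1.7 OC`, the solid density is the organic/mineral
#' mixture of [sediment_solid_density()], and the solid volume fraction is
#' dry bulk density / solid density (its complement is the water content).
#'
#' Inverse mode (`water_content` given): the organic-carbon content is
#' recovered by bisection on OC between 1e-3 mg/g and the OC at which the dry
#' bulk density vanishes, to a residual below 1e-10. Guaranteed bracketing,
#' no derivative needed.
#'
#' @param oc Organic-carbon concentration, mg per dry-weight gram (> 0).
#' @param water_content Volume fraction of pore water (0-1).
#' @return A one-row tibble with columns `oc`, `om` (mass fraction),
#'   `dry_bulk_density` and `solid_density` (g cm^-3), `solid_frac` and
#'   `water_content` (volume fractions).
#' @examples
#' sediment_composition(oc = 1)
#' sediment_composition(water_content = 0.9)
#' @export
sediment_composition <- function(oc = NULL, water_content = NULL) {
  if (is.null(oc) == is.null(water_content)) {
    abort("supply exactly one of `oc` or `water_content`.",
          class = "fugapop_validation_error")
  }
  if (!is.null(oc)) {
    if (!.num1(oc) || oc <= 0) {
      abort("`oc` must be a positive number (mg per dry-weight g).",
            class = "fugapop_domain_error")
    }
    if (.dry_bulk_density(oc) <= 0) {
      abort(paste0("`oc` = ", format(oc), " mg/g gives a non-positive dry ",
                   "bulk density (limit ", format(.oc_max, digits = 6),
                   " mg/g)."),
            class = "fugapop_domain_error")
    }
    out <- .sed_forward(oc)
  } else {
    if (!.num1(water_content) || water_content <= 0 || water_content >= 1) {
      abort("`water_content` must be in (0, 1).",
            class = "fugapop_domain_error")
    }
    resid <- function(x) .sed_forward(x)$water_content - water_content
    lo <- 1e-3
    hi <- .oc_max * (1 - 1e-12)
    if (resid(lo) > 0 || resid(hi) < 0) {
      abort("no organic-carbon content reproduces this water content.",
            class = "fugapop_no_solution_error")
    }
    # bisection; resid is monotone increasing in OC over the bracket
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      r <- resid(mid)
      if (abs(r) < 1e-10) break
      if (r > 0) hi <- mid else lo <- mid
    }
    out <- .sed_forward(mid)
  }
  as_tibble(out[c("oc", "om", "dry_bulk_density", "solid_density",
                  "solid_frac", "water_content")])
}
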
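# Scenario configuration reading/writing. The config is a single YAML
# document; every physical quantity is either a bare number (already in the
# internal SI-day unit system: kelvin, metres, days, kg, Pa, mol) or a string
# with an explicit unit tag such as "12 degC" or "30 yr", converted at load.

.unit_table <- list(
  "K" = identity,
  "degC" = function(x) x + 273.15,
  "d" = identity, "day" = identity, "days" = identity,
  "yr" = function(x) x * 365, "year" = function(x) x * 365,
  "h" = function(x) x / 24,
  "%" = function(x) x / 100, "percent" = function(x) x / 100,
  "m" = identity, "m2" = identity, "m3" = identity,
  "m/d" = identity, "m3/d" = identity, "m3/kg/d" = identity,
  "kg" = identity, "g" = function(x) x / 1000, "kg/m3" = identity,
  "Pa" = identity, "Pa*m3/mol" = identity,
  "J/mol" = identity, "kJ/mol" = function(x) x * 1000,
  "mol/d" = identity, "1/d" = identity, "frac" = identity
)

.parse_quantity <- function(x, path) {
  if (is.numeric(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+|\\.inf|Inf)\\s+(\\S+)\\s*$", x))[[1]]
    if (length(m) == 3) {
      val <- if (m[2] %in% c(".inf", "Inf")) Inf else as.numeric(m[2])
      conv <- .unit_table[[m[3]]]
      if (is.null(conv)) {
        abort(paste0("unknown unit `", m[3], "` at ", path),
              class = "fugapop_unit_error")
      }
      if (is.na(val)) {
        abort(paste0("unparseable quantity `", x, "` at ", path),
              class = "fugapop_unit_error")
      }
      return(conv(val))
    }
  }
  abort(paste0("expected a number or \"value unit\" string at ", path),
        class = "fugapop_validation_error")
}

.section_args <- function(cfg, section, allowed, required = character()) {
  x <- cfg[[section]]
  if (is.null(x)) {
    if (length(required) > 0) {
      abort(paste0("missing config section [", section, "]"),
            class = "fugapop_validation_error")
    }
    return(NULL)
  }
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown key(s) in [", section, "]: ",
                 paste(unknown, collapse = ", ")),
          class = "fugapop_validation_error")
  }
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) {
    abort(paste0("missing key(s) in [", section, "]: ",
                 paste(miss, collapse = ", ")),
          class = "fugapop_validation_error")
  }
  lapply(setNames(names(x), names(x)), function(k) {
    v <- x[[k]]
    if (k %in% c("name", "habitat", "exclude")) v
    else if (is.list(v) || is.logical(v)) v
    else .parse_quantity(v, paste0(section, "$", k))
  })
}

.series_from_cfg <- function(x, path) {
  if (is.list(x) && !is.null(x$time)) {
    data.frame(time = vapply(x$time, .parse_quantity, 0, path),
               value = vapply(x$value, .parse_quantity, 0, path))
  } else {
    .parse_quantity(x, path)
  }
}

#' Load a scenario from a YAML configuration file
#'
#' Parses, unit-converts and fully validates a scenario configuration.
#' Derivable fields are filled (suspended-sediment fraction from the loading
#' split when omitted) and echoed with `message()` so every derived
#' parameter is visible. Unknown keys and malformed diets are rejected with
#' the config path of the offending field.
#'
#' @param path Path to a YAML scenario file (see [save_scenario()] for the
#'   layout; [make_toy_lake()] plus [save_scenario()] writes an example).
#' @param quiet Suppress the derived-parameter messages.
#' @return A [fug_scenario()].
#' @export
load_scenario <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "fugapop_validation_error")
  }
  cfg <- yaml::read_yaml(path)
  top_allowed <- c("congener", "air", "water", "sediment", "species", "diet",
                   "forcing", "options")
  unknown <- setdiff(names(cfg), top_allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown top-level section(s): ",
                 paste(unknown, collapse = ", ")),
          class = "fugapop_validation_error")
  }

  cg <- .section_args(cfg, "congener",
    allowed = c("name", "kow_ref", "koa_a", "koa_b", "henry_ref", "t_ref",
                "du_aw", "du_ow", "tmf", "lifetime_air", "lifetime_water",
                "lifetime_sediment"),
    required = c("name", "kow_ref", "koa_a", "koa_b", "henry_ref"))
  congener <- do.call(fug_congener, cg)

  air <- do.call(fug_air, .section_args(cfg, "air",
    allowed = c("volume", "temp", "aerosol_frac", "area_aw", "mtc_air",
                "mtc_water", "rain_rate", "dry_dep_vel", "scavenging",
                "adv_in", "adv_out"),
    required = c("volume", "temp", "area_aw", "mtc_air", "mtc_water")))
  water <- do.call(fug_water, .section_args(cfg, "water",
    allowed = c("volume", "temp", "susp_frac", "susp_density", "susp_oc",
                "area_ws", "adv_flow", "dep_vel", "resusp_vel", "mtc_ws"),
    required = c("volume", "temp", "susp_density", "susp_oc", "area_ws")))
  sediment <- do.call(fug_sediment, .section_args(cfg, "sediment",
    allowed = c("volume", "solid_frac", "solid_density", "solid_oc",
                "burial_flow", "depth", "area_ws"),
    required = c("solid_frac", "solid_density", "solid_oc")))
  if (is.null(water$susp_frac) && !quiet) {
    message("water$susp_frac derived from the 70/30 loading split: ",
            signif(tau2_from_split(water$susp_density, water$susp_oc,
                                   koc_from_kow(congener$kow_ref)), 6))
  }

  web <- NULL
  if (!is.null(cfg$species)) {
    sp_rows <- lapply(seq_along(cfg$species), function(i) {
      s <- cfg$species[[i]]
      allowed <- .species_cols
      unknown <- setdiff(names(s), allowed)
      if (length(unknown) > 0) {
        abort(paste0("unknown key(s) in species[", i, "]: ",
                     paste(unknown, collapse = ", ")),
              class = "fugapop_validation_error")
      }
      s[setdiff(names(s), c("name", "habitat"))] <-
        lapply(setdiff(names(s), c("name", "habitat")), function(k) {
          .parse_quantity(s[[k]], paste0("species[", i, "]$", k))
        })
      do.call(fug_species, s)
    })
    sp <- dplyr::bind_rows(sp_rows)
    diet <- matrix(0, nrow(sp), nrow(sp),
                   dimnames = list(sp$name, sp$name))
    for (consumer in names(cfg$diet)) {
      if (!consumer %in% sp$name) {
        abort(paste0("diet lists unknown consumer `", consumer, "`"),
              class = "fugapop_validation_error")
      }
      for (prey in names(cfg$diet[[consumer]])) {
        if (!prey %in% sp$name) {
          abort(paste0("diet of `", consumer, "` lists unknown prey `",
                       prey, "`"),
                class = "fugapop_validation_error")
        }
        diet[consumer, prey] <-
          .parse_quantity(cfg$diet[[consumer]][[prey]],
                          paste0("diet$", consumer, "$", prey))
      }
    }
    web <- fug_foodweb(sp, diet)
  }

  forcing <- NULL
  if (!is.null(cfg$forcing)) {
    fc <- cfg$forcing
    allowed <- c("air_temp", "water_temp", "inflow_fug_air",
                 "inflow_fug_water", "emission")
    unknown <- setdiff(names(fc), allowed)
    if (length(unknown) > 0) {
      abort(paste0("unknown key(s) in [forcing]: ",
                   paste(unknown, collapse = ", ")),
            class = "fugapop_validation_error")
    }
    em <- c(water = 0)
    if (!is.null(fc$emission)) {
      em <- vapply(fc$emission, .parse_quantity, 0, "forcing$emission")
    }
    forcing <- fug_forcing(
      air_temp = .series_from_cfg(fc$air_temp %||% air$temp,
                                  "forcing$air_temp"),
      water_temp = .series_from_cfg(fc$water_temp %||% water$temp,
                                    "forcing$water_temp"),
      inflow_fug_air = .series_from_cfg(fc$inflow_fug_air %||% 0,
                                        "forcing$inflow_fug_air"),
      inflow_fug_water = .series_from_cfg(fc$inflow_fug_water %||% 0,
                                          "forcing$inflow_fug_water"),
      emission = em
    )
  }

  opts <- fug_options()
  if (!is.null(cfg$options)) {
    oa <- .section_args(cfg, "options",
      allowed = c("population_dynamics", "mortality_to_water", "exclude"))
    oa$exclude <- as.character(unlist(oa$exclude %||% character()))
    oa$population_dynamics <- isTRUE(oa$population_dynamics) ||
      identical(oa$population_dynamics, 1)
    opts <- do.call(fug_options, oa)
  }

  fug_scenario(congener, air, water, sediment, foodweb = web,
               forcing = forcing, options = opts)
}

.series_to_cfg <- function(s) {
  if (length(s$value) == 2 && s$value[1] == s$value[2]) {
    s$value[1]
  } else {
    list(time = as.list(s$time), value = as.list(s$value))
  }
}

#' Save a scenario to a YAML configuration file
#'
#' Writes all scenario fields in the internal SI-day unit system (kelvin,
#' metres, days). A file written here loads back to an equivalent scenario
#' with [load_scenario()].
#'
#' @param scenario A [fug_scenario()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "fug_scenario"))
  drop_class <- function(x) { x <- unclass(x); x[!vapply(x, is.null, TRUE)] }
  cfg <- list(
    congener = drop_class(scenario$congener),
    air = drop_class(scenario$air),
    water = drop_class(scenario$water),
    sediment = drop_class(scenario$sediment)
  )
  if (!is.null(scenario$foodweb)) {
    sp <- scenario$foodweb$species
    cfg$species <- lapply(seq_len(nrow(sp)), function(i) {
      row <- as.list(sp[i, ])
      row[!vapply(row, function(v) is.na(v) %in% TRUE, TRUE)]
    })
    d <- scenario$foodweb$diet
    diet <- list()
    for (i in seq_len(nrow(d))) {
      nz <- which(d[i, ] > 0)
      if (length(nz) > 0) {
        row <- as.list(d[i, nz])
        names(row) <- colnames(d)[nz]
        diet[[rownames(d)[i]]] <- row
      }
    }
    if (length(diet) > 0) cfg$diet <- diet
  }
  frc <- scenario$forcing
  cfg$forcing <- list(
    air_temp = .series_to_cfg(frc$air_temp),
    water_temp = .series_to_cfg(frc$water_temp),
    inflow_fug_air = .series_to_cfg(frc$inflow_fug_air),
    inflow_fug_water = .series_to_cfg(frc$inflow_fug_water),
    emission = as.list(frc$emission)
  )
  cfg$options <- drop_class(scenario$options)
  if (length(cfg$options$exclude) == 0) cfg$options$exclude <- NULL
  # %.17g guarantees exact double round-trip through the text file
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}
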
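# broom-style tidiers and ggplot2 visualisations for fitted/solved objects.

#' @export
print.fug_steady <- function(x, ...) {
  cat("<fug_steady> steady-state fugacities (Pa), residual",
      format(x$residual, digits = 3), "\n")
  print(signif(x$fugacity, 4))
  invisible(x)
}

#' Tidy a steady-state solution
#'
#' @param x A `fug_steady` from [steady_state()].
#' @param ... Unused.
#' @return A tibble with one row per compartment: `compartment`, `fugacity`
#'   (Pa), `z` (mol Pa^-1 m^-3), `volume` (m^3), `concentration`
#'   (mol m^-3) and `mass` (mol).
#' @method tidy fug_steady
#' @export
tidy.fug_steady <- function(x, ...) {
  tibble(
    compartment = names(x$fugacity),
    fugacity = unname(x$fugacity),
    z = unname(x$z),
    volume = unname(x$volume),
    concentration = unname(x$z * x$fugacity),
    mass = unname(x$mass)
  )
}

#' Glance at a steady-state solution
#'
#' @inheritParams tidy.fug_steady
#' @return A one-row tibble: `n_compartments`, `total_mass` (mol),
#'   `max_fugacity` (Pa), `residual`.
#' @method glance fug_steady
#' @export
glance.fug_steady <- function(x, ...) {
  tibble(n_compartments = length(x$fugacity),
         total_mass = sum(x$mass),
         max_fugacity = max(x$fugacity),
         residual = x$residual)
}

#' @export
print.fug_simulation <- function(x, ...) {
  cat("<fug_simulation>", length(x$times), "output times over",
      format(max(x$times)), "days,", ncol(x$fugacity), "compartments\n")
  invisible(x)
}

#' Tidy a simulation result
#'
#' @param x A `fug_simulation` from [fug_simulate()].
#' @param ... Unused.
#' @return A long tibble: `time` (days), `compartment`, `fugacity` (Pa),
#'   `mass` (mol) and `pop_volume` (m^3, `NA` for abiotic compartments).
#' @method tidy fug_simulation
#' @export
tidy.fug_simulation <- function(x, ...) {
  comp <- colnames(x$fugacity)
  dplyr::bind_rows(lapply(comp, function(cp) {
    tibble(time = x$times, compartment = cp,
           fugacity = x$fugacity[, cp],
           mass = x$mass[, cp],
           pop_volume = if (!is.null(x$pop_volume) &&
                              cp %in% colnames(x$pop_volume))
             x$pop_volume[, cp] else NA_real_)
  }))
}

#' Glance at a simulation result
#'
#' @inheritParams tidy.fug_simulation
#' @return A one-row tibble: `t_end` (days), `n_times`, `n_compartments`,
#'   `total_mass_start` / `total_mass_end` (mol) and `mass_change` (their
#'   relative difference).
#' @method glance fug_simulation
#' @export
glance.fug_simulation <- function(x, ...) {
  m0 <- sum(x$mass[1, ])
  m1 <- sum(x$mass[nrow(x$mass), ])
  tibble(t_end = max(x$times), n_times = length(x$times),
         n_compartments = ncol(x$fugacity),
         total_mass_start = m0, total_mass_end = m1,
         mass_change = (m1 - m0) / max(m0, .Machine$double.eps))
}

#' Plot fugacity or mass trajectories
#'
#' @param object A `fug_simulation`.
#' @param what `"fugacity"` (Pa) or `"mass"` (mol).
#' @param log10 Log-scale the y axis (fugacities span many orders of
#'   magnitude).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fug_simulation
#' @export
autoplot.fug_simulation <- function(object, what = c("fugacity", "mass"),
                                    log10 = TRUE, ...) {
  what <- match.arg(what)
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data[[what]],
                                       colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)",
                  y = if (what == "fugacity") "fugacity (Pa)" else
                    "mass (mol)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (log10) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot steady-state fugacities per compartment
#'
#' @param object A `fug_steady`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fug_steady
#' @export
autoplot.fug_steady <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$compartment,
                                                     .data$fugacity),
                                  y = .data$fugacity)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "steady-state fugacity (Pa)") +
    ggplot2::theme_minimal()
}
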
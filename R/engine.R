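# The engine: assemble the flux ledger into the simultaneous fugacity
# equations, solve the steady state as a linear system, integrate the
# dynamics, and audit mass balance.
#
# Compartment/state ordering is fixed and documented:
# [air, water, sediment, species in declaration order].

.ledger_index <- function(ledger, comp) {
  list(
    src = match(ledger$source, comp),   # NA for EXTERNAL (input rows)
    snk = match(ledger$sink, comp),     # NA for EXTERNAL (exit rows)
    coeff = ledger$coeff,
    input = ledger$kind == "input"
  )
}

# dM/dt accumulation: E_i + sum gains * f(source) - sum losses * f_i
.dmdt_core <- function(idx, f, fin, emission) {
  dm <- emission
  coeff <- idx$coeff
  src <- idx$src
  snk <- idx$snk
  inp <- idx$input
  for (r in seq_along(coeff)) {
    if (inp[r]) {
      dm[snk[r]] <- dm[snk[r]] + coeff[r] * fin[snk[r]]
    } else {
      fl <- coeff[r] * f[src[r]]
      dm[src[r]] <- dm[src[r]] - fl
      if (!is.na(snk[r])) dm[snk[r]] <- dm[snk[r]] + fl
    }
  }
  dm
}

.fin_vector <- function(cc, frc) {
  fin <- numeric(cc$n)
  fin[1] <- frc$inflow_fug_air
  fin[2] <- frc$inflow_fug_water
  fin
}

#' Mass rate of change from a flux ledger
#'
#' Evaluates dM/dt = E_i + sum_j D_ji f_j - D_Ti f_i per compartment from a
#' ledger of directed flux records.
#'
#' @param ledger A ledger tibble from [build_ledger()].
#' @param fugacity Named fugacity vector (Pa) over the compartments appearing
#'   in the ledger.
#' @param inflow_fugacity Named vector of inflow fugacities (Pa) applied to
#'   `kind = "input"` records, by sink compartment (e.g.
#'   `c(air = 1e-9, water = 0)`).
#' @param emission Named vector of direct emissions (mol day^-1).
#' @return A tibble with columns `compartment` and `dm_dt` (mol day^-1).
#' @export
dmdt <- function(ledger, fugacity, inflow_fugacity = NULL, emission = NULL) {
  comp <- names(fugacity)
  if (is.null(comp)) {
    abort("`fugacity` must be a named vector.",
          class = "fugapop_validation_error")
  }
  idx <- .ledger_index(ledger, comp)
  if (any(is.na(idx$src) & !idx$input)) {
    abort("ledger references compartments absent from `fugacity`.",
          class = "fugapop_validation_error")
  }
  fin <- setNames(numeric(length(comp)), comp)
  if (!is.null(inflow_fugacity)) {
    fin[names(inflow_fugacity)] <- inflow_fugacity
  }
  em <- setNames(numeric(length(comp)), comp)
  if (!is.null(emission)) em[names(emission)] <- emission
  tibble(compartment = comp,
         dm_dt = .dmdt_core(idx, unname(fugacity), unname(fin), unname(em)))
}

# Full right-hand side at (t, f, vp); returns the pieces so that dfdt(),
# the integrator and the flux reporters share one code path.
.rhs_pieces <- function(cc, t, f, vp) {
  scn <- cc$scn
  frc <- forcing_at(scn$forcing, t)
  ledger <- .build_ledger_at(cc, frc$temp_air, frc$temp_water, vp)
  cap <- attr(ledger, "cap")
  idx <- .ledger_index(ledger, cc$comp)
  fin <- .fin_vector(cc, frc)
  dm <- .dmdt_core(idx, f, fin, cc$emission)

  z <- .z_vector(cc, cap)
  v <- c(cc$volumes_env, vp)
  dz <- dz_dt(scn$congener, scn$air, scn$water, scn$sediment,
              dtemp_air_dt = frc$dtemp_air_dt,
              dtemp_water_dt = frc$dtemp_water_dt,
              lipid_frac = cc$lipid,
              temp_air = frc$temp_air, temp_water = frc$temp_water)
  dzv <- c(dz$dz_air, dz$dz_water, dz$dz_sed, dz$dz_biota)

  dvv <- numeric(cc$n)
  dvp <- NULL
  if (scn$options$population_dynamics && cc$n_sp > 0) {
    dvp <- dv_dt(cc$web, frc$temp_water - 273.15, pop_volume = vp)$dv_dt
    dvv[3 + seq_len(cc$n_sp)] <- dvp
  }

  df <- dm / (z * v) - (f / z) * dzv - (f / v) * dvv
  list(df = df, dvp = dvp, dm = dm, z = z, v = v, ledger = ledger,
       idx = idx, fin = fin, frc = frc)
}

#' Fugacity rate of change
#'
#' df_i/dt = (1/(Z_i V_i)) dM_i/dt - (f_i/Z_i) dZ_i/dt - (f_i/V_i) dV_i/dt,
#' combining the ledger mass balance, the analytic capacity derivatives
#' driven by the forcing temperature slopes, and the population dynamics
#' (zero when population dynamics are off).
#'
#' @param scenario A [fug_scenario()].
#' @param fugacity Fugacity vector (Pa) in compartment order
#'   (air, water, sediment, species...).
#' @param t Time (days).
#' @param pop_volume Optional species population volumes (m^3).
#' @return A tibble with columns `compartment`, `fugacity`, `df_dt`
#'   (Pa day^-1) and `dm_dt` (mol day^-1).
#' @export
dfdt <- function(scenario, fugacity, t = 0, pop_volume = NULL) {
  cc <- .compile(scenario)
  vp <- pop_volume %||% cc$vp0
  if (length(fugacity) != cc$n) {
    abort(paste0("`fugacity` must have length ", cc$n, "."),
          class = "fugapop_validation_error")
  }
  p <- .rhs_pieces(cc, t, unname(fugacity), vp)
  if (any(p$z * p$v == 0)) {
    abort("degenerate compartment: Z * V is zero.",
          class = "fugapop_domain_error")
  }
  tibble(compartment = cc$comp, fugacity = unname(fugacity),
         df_dt = p$df, dm_dt = p$dm)
}

#' Steady-state solution of the fugacity equations
#'
#' With temperatures and populations frozen at their values at time `t`, the
#' mass balance dM/dt = 0 is linear in the fugacities: A f + b = 0, where A
#' collects the ledger gains and losses and b the boundary inputs (emissions
#' and advective inflow). Solved directly; the relative residual is checked
#' against `tol`.
#'
#' @param scenario A [fug_scenario()].
#' @param t Time (days) at which forcing values are frozen.
#' @param tol Maximum acceptable relative residual of the linear solve.
#' @return An object of class `fug_steady`: list with `fugacity` (named Pa
#'   vector), `mass` (mol), `z`, `volume`, `flux` (ledger with a `flux`
#'   column, mol day^-1), `residual`, and matrices `A`, `b` as attributes.
#' @export
steady_state <- function(scenario, t = 0, tol = 1e-10) {
  cc <- .compile(scenario)
  frc <- forcing_at(scenario$forcing, t)
  ledger <- .build_ledger_at(cc, frc$temp_air, frc$temp_water, cc$vp0)
  cap <- attr(ledger, "cap")
  idx <- .ledger_index(ledger, cc$comp)
  fin <- .fin_vector(cc, frc)

  n <- cc$n
  a <- matrix(0, n, n, dimnames = list(cc$comp, cc$comp))
  b <- unname(cc$emission)
  for (r in seq_along(idx$coeff)) {
    if (idx$input[r]) {
      b[idx$snk[r]] <- b[idx$snk[r]] + idx$coeff[r] * fin[idx$snk[r]]
    } else {
      s <- idx$src[r]
      a[s, s] <- a[s, s] - idx$coeff[r]
      if (!is.na(idx$snk[r])) {
        a[idx$snk[r], s] <- a[idx$snk[r], s] + idx$coeff[r]
      }
    }
  }
  no_loss <- which(diag(a) == 0)
  if (length(no_loss) > 0) {
    abort(paste0("no loss pathway from compartment(s): ",
                 paste(cc$comp[no_loss], collapse = ", "),
                 "; the steady-state system is structurally singular."),
          class = "fugapop_structural_error")
  }
  f <- tryCatch(
    solve(a, -b),
    error = function(e) {
      abort("steady-state system is singular.",
            class = "fugapop_structural_error")
    }
  )
  resid <- if (all(b == 0)) 0 else
    sqrt(sum((a %*% f + b)^2)) / sqrt(sum(b^2))
  if (resid > tol) {
    abort(paste0("steady-state residual ", format(resid),
                 " exceeds tolerance."),
          class = "fugapop_structural_error")
  }
  if (any(f < 0)) {
    warn(paste0("negative steady-state fugacity for: ",
                paste(cc$comp[f < 0], collapse = ", "),
                " - nonphysical parameter set."))
  }
  z <- .z_vector(cc, cap)
  v <- c(cc$volumes_env, cc$vp0)
  flux <- .chunk_tbl(ledger[c("name", "source", "sink", "coeff", "kind")])
  flux$flux <- idx$coeff * ifelse(idx$input, fin[idx$snk], f[idx$src])

  structure(
    list(fugacity = setNames(as.numeric(f), cc$comp),
         mass = setNames(as.numeric(z * v * f), cc$comp),
         z = setNames(z, cc$comp), volume = setNames(v, cc$comp),
         flux = flux, residual = resid,
         A = a, b = b, scenario = scenario),
    class = "fug_steady"
  )
}

#' Integrate the dynamic fugacity equations
#'
#' Integrates df/dt (and dV/dt when population dynamics are on) with a
#' stiffness-capable adaptive method (deSolve's `lsoda` by default), with
#' dense output on a regular (or user-supplied) grid.
#'
#' @param scenario A [fug_scenario()].
#' @param t_end End time (days).
#' @param init Initial fugacities: `"steady"` (default; start from the
#'   steady state at t = 0), `"zero"`, or a numeric vector in compartment
#'   order.
#' @param times Optional output time grid (days); defaults to `n_out`
#'   regularly spaced points on `[0, t_end]`.
#' @param n_out Number of output points when `times` is not given.
#' @param rtol,atol Relative / absolute integration tolerances. Fugacities
#'   span many orders of magnitude, hence the small absolute tolerance
#'   (in Pa).
#' @param method Integration method passed to [deSolve::ode()].
#' @return An object of class `fug_simulation`: list with `times`,
#'   `fugacity` (time x compartment matrix, Pa), `mass` (mol),
#'   `pop_volume` (m^3; constant columns when population dynamics are off),
#'   `flux` (per-time per-compartment gain/loss and boundary rates) and the
#'   `scenario`.
#' @export
fug_simulate <- function(scenario, t_end, init = "steady", times = NULL,
                         n_out = 201, rtol = 1e-8, atol = 1e-12,
                         method = "lsoda") {
  cc <- .compile(scenario)
  if (is.character(init)) {
    init <- match.arg(init, c("steady", "zero"))
    f0 <- switch(init,
                 steady = unname(steady_state(scenario)$fugacity),
                 zero = numeric(cc$n))
  } else {
    if (length(init) != cc$n) {
      abort(paste0("`init` must have length ", cc$n, "."),
            class = "fugapop_validation_error")
    }
    f0 <- unname(as.numeric(init))
  }
  if (is.null(times)) times <- seq(0, t_end, length.out = n_out)
  popdyn <- scenario$options$population_dynamics && cc$n_sp > 0
  y0 <- if (popdyn) c(f0, cc$vp0) else f0

  rhs <- function(t, y, parms) {
    f <- y[seq_len(cc$n)]
    vp <- if (popdyn) y[cc$n + seq_len(cc$n_sp)] else cc$vp0
    p <- .rhs_pieces(cc, t, f, vp)
    list(c(p$df, if (popdyn) p$dvp))
  }

  # integrate segment-by-segment between forcing slope breakpoints, so the
  # right-hand side is smooth in t within every integrator call
  frc <- scenario$forcing
  brk <- sort(unique(c(frc$air_temp$time, frc$water_temp$time,
                       frc$inflow_fug_air$time, frc$inflow_fug_water$time)))
  t0 <- times[1]
  t1 <- times[length(times)]
  seg <- sort(unique(c(t0, t1, brk[brk > t0 & brk < t1])))
  sol <- matrix(NA_real_, length(times), length(y0))
  sol[1, ] <- y0
  y <- y0
  for (s in seq_len(length(seg) - 1)) {
    a <- seg[s]; b <- seg[s + 1]
    inner <- times[times > a & times < b]
    seg_times <- c(a, inner, b)
    res <- deSolve::ode(y = y, times = seg_times, func = rhs, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
    if (nrow(res) < length(seg_times)) {
      abort(paste0("integration failed at t = ", max(res[, 1]),
                   "; last state: ",
                   paste(signif(res[nrow(res), -1], 4), collapse = ", "),
                   ". The system may be stiffer than the method allows; ",
                   "try method = 'bdf' or looser tolerances."),
            class = "fugapop_integration_error")
    }
    keep <- seg_times %in% times & seg_times > a
    sol[match(seg_times[keep], times), ] <- res[keep, -1, drop = FALSE]
    y <- unname(res[nrow(res), -1])
  }
  sol <- cbind(times, sol)
  fug <- sol[, 1 + seq_len(cc$n), drop = FALSE]
  colnames(fug) <- cc$comp
  vp_m <- if (popdyn) {
    m <- sol[, 1 + cc$n + seq_len(cc$n_sp), drop = FALSE]
    colnames(m) <- cc$comp[-(1:3)]
    m
  } else if (cc$n_sp > 0) {
    matrix(rep(cc$vp0, each = length(times)), ncol = cc$n_sp,
           dimnames = list(NULL, cc$comp[-(1:3)]))
  } else NULL

  # post-hoc mass and flux series on the output grid
  mass <- matrix(NA_real_, length(times), cc$n,
                 dimnames = list(NULL, cc$comp))
  gain <- loss <- bnd_in <- bnd_out <- mass
  for (k in seq_along(times)) {
    vp_k <- if (is.null(vp_m)) numeric() else vp_m[k, ]
    frc <- forcing_at(scenario$forcing, times[k])
    ledger <- .build_ledger_at(cc, frc$temp_air, frc$temp_water, vp_k)
    cap <- attr(ledger, "cap")
    idx <- .ledger_index(ledger, cc$comp)
    fin <- .fin_vector(cc, frc)
    f <- fug[k, ]
    z <- .z_vector(cc, cap)
    v <- c(cc$volumes_env, vp_k)
    mass[k, ] <- z * v * f
    g <- l <- bi <- bo <- numeric(cc$n)
    bi <- bi + unname(cc$emission)
    g <- g + unname(cc$emission)
    for (r in seq_along(idx$coeff)) {
      if (idx$input[r]) {
        fl <- idx$coeff[r] * fin[idx$snk[r]]
        g[idx$snk[r]] <- g[idx$snk[r]] + fl
        bi[idx$snk[r]] <- bi[idx$snk[r]] + fl
      } else {
        fl <- idx$coeff[r] * f[idx$src[r]]
        l[idx$src[r]] <- l[idx$src[r]] + fl
        if (is.na(idx$snk[r])) {
          bo[idx$src[r]] <- bo[idx$src[r]] + fl
        } else {
          g[idx$snk[r]] <- g[idx$snk[r]] + fl
        }
      }
    }
    gain[k, ] <- g; loss[k, ] <- l; bnd_in[k, ] <- bi; bnd_out[k, ] <- bo
  }
  flux <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(time = times),
                     as_tibble(gain) |> setNames(paste0("gain.", cc$comp)),
                     as_tibble(loss) |> setNames(paste0("loss.", cc$comp)),
                     as_tibble(bnd_in) |> setNames(paste0("in.", cc$comp)),
                     as_tibble(bnd_out) |> setNames(paste0("out.", cc$comp))),
    cols = -"time", names_to = c("what", "compartment"), names_sep = "\\.",
    values_to = "rate") |>
    tidyr::pivot_wider(names_from = "what", values_from = "rate") |>
    dplyr::rename(boundary_in = "in", boundary_out = "out")

  structure(
    list(times = times, fugacity = fug, mass = mass, pop_volume = vp_m,
         flux = flux, scenario = scenario,
         rtol = rtol, atol = atol, method = method),
    class = "fug_simulation"
  )
}

#' Mass-balance audit of a simulation
#'
#' Integrates (trapezoidal rule on the output grid) the per-compartment gains
#' and losses of a [fug_simulate()] result and compares them with the storage
#' change: closure = integrated inputs - integrated outputs - (M_end -
#' M_start). A `TOTAL` row audits the whole system against its boundary
#' flows only. Closed systems must close to numerical precision.
#'
#' @param sim A `fug_simulation`.
#' @return A tibble with columns `compartment`, `mass_start`, `mass_end`,
#'   `inputs`, `outputs`, `storage_change`, `closure_error` and
#'   `relative_error`.
#' @export
mass_balance_audit <- function(sim) {
  stopifnot(inherits(sim, "fug_simulation"))
  tt <- sim$times
  trap <- function(y) sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  comp <- colnames(sim$mass)
  rows <- lapply(comp, function(cp) {
    fx <- sim$flux[sim$flux$compartment == cp, ]
    fx <- fx[order(fx$time), ]
    ins <- trap(fx$gain)
    outs <- trap(fx$loss)
    dm <- sim$mass[nrow(sim$mass), cp] - sim$mass[1, cp]
    err <- ins - outs - dm
    tibble(compartment = cp, mass_start = sim$mass[1, cp],
           mass_end = sim$mass[nrow(sim$mass), cp],
           inputs = ins, outputs = outs, storage_change = dm,
           closure_error = err,
           relative_error = abs(err) / max(abs(ins), abs(outs), abs(dm),
                                           .Machine$double.eps))
  })
  per_comp <- dplyr::bind_rows(rows)
  fx <- sim$flux |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(bin = sum(.data$boundary_in),
                     bout = sum(.data$boundary_out), .groups = "drop") |>
    dplyr::arrange(.data$time)
  ins <- trap(fx$bin)
  outs <- trap(fx$bout)
  dm <- sum(sim$mass[nrow(sim$mass), ]) - sum(sim$mass[1, ])
  err <- ins - outs - dm
  dplyr::bind_rows(
    per_comp,
    tibble(compartment = "TOTAL", mass_start = sum(sim$mass[1, ]),
           mass_end = sum(sim$mass[nrow(sim$mass), ]),
           inputs = ins, outputs = outs, storage_change = dm,
           closure_error = err,
           relative_error = abs(err) / max(abs(ins), abs(outs), abs(dm),
                                           .Machine$double.eps))
  )
}
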
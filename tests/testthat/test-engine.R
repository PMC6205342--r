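# The ledger-assembled mass balance is checked term-by-term against the
# model's printed composite right-hand sides, hand-coded here as independent
# oracles, then the steady-state and dynamic solvers against linear-algebra
# and conservation properties.

# Composite right-hand sides for the air, water, sediment and per-species
# balances, written directly from the closed-form equations (two-film
# diffusion, deposition, advection, reaction, gill exchange, TMF dietary
# partition, mortality), independent of the ledger plumbing.
h_oracle_dm <- function(scn, f) {
  cg <- scn$congener; air <- scn$air; wat <- scn$water; sed <- scn$sediment
  web <- scn$foodweb; sp <- web$species
  frc <- forcing_at(scn$forcing, 0)
  cap <- fug_capacities(cg, air, wat, sed)
  tw_c <- frc$temp_water - 273.15
  koc <- 0.41 * cg$kow_ref
  z1 <- cap$z_gas; z7 <- cap$z_aerosol; z2 <- cap$z_water
  z5 <- cap$z_susp; z4 <- cap$z_sed_solid
  za <- cap$z_air_bulk; zw <- cap$z_water_bulk; zs <- cap$z_sed_bulk
  zb <- sp$lipid_frac * z2 * cg$kow_ref
  tl <- trophic_levels(web)$trophic_level
  feed <- feeding_rate(tw_c, sp$body_mass)
  nsp <- nrow(sp)
  fa <- f[["air"]]; fw <- f[["water"]]; fs <- f[["sediment"]]
  fb <- f[sp$name]

  dv <- 1 / (1 / (air$mtc_air * air$area_aw * z1) +
               1 / (air$mtc_water * air$area_aw * z2))
  drww <- air$area_aw * air$rain_rate * z2
  dqdw <- air$area_aw * air$dry_dep_vel * z7
  dqww <- air$area_aw * air$scavenging * air$rain_rate * z7
  ra <- air$volume * za / cg$lifetime_air
  rw <- wat$volume * zw / cg$lifetime_water
  rs <- sed$volume * zs / cg$lifetime_sediment
  dy <- wat$mtc_ws * wat$area_ws * z2
  dds <- wat$dep_vel * wat$area_ws * z5
  drs <- wat$resusp_vel * wat$area_ws * z4
  gill <- sp$gill_clearance * sp$pop_volume * sp$density * z2
  dmd <- 4.899 * sp$max_age^-0.916 * sp$pop_volume / 365000 * zb
  pel <- sp$habitat != "benthic"

  dm_air <- frc$inflow_fug_air * air$adv_in * za - fa * air$adv_out * za +
    dv * (fw - fa) - (drww + dqdw + dqww + ra) * fa

  dm_water <- wat$adv_flow * zw * (frc$inflow_fug_water - fw) +
    dv * (fa - fw) + (drww + dqdw + dqww) * fa +
    dy * (fs - fw) + drs * fs - dds * fw - rw * fw +
    sum((fb[pel] - fw) * gill[pel]) + frc$emission[["water"]]

  # dietary egestion sums (gut-feces TMF part and undigested part)
  eg_gut <- 0; eg_und <- 0
  for (i in seq_len(nsp)) for (j in seq_len(nsp)) {
    p <- web$diet[i, j]
    if (p > 0) {
      ing <- sp$assimilation[i] * sp$density[i] * sp$pop_volume[i] *
        feed[i] * p * zb[j] * fb[j]
      eg_gut <- eg_gut + ing * cg$tmf^-(tl[i] - tl[j])
      eg_und <- eg_und + (1 - sp$assimilation[i]) * sp$density[i] *
        sp$pop_volume[i] * feed[i] * p * zb[j] * fb[j]
    }
  }
  dm_sed <- eg_gut + eg_und +
    sum((fb[!pel] - fs) * gill[!pel]) +
    dds * fw - rs * fs - dy * (fs - fw) - drs * fs +
    sum(dmd * fb)

  dm_sp <- numeric(nsp)
  for (i in seq_len(nsp)) {
    fenv <- if (pel[i]) fw else fs
    uptake <- gill[i] * fenv
    dietary <- 0
    for (j in seq_len(nsp)) {
      p <- web$diet[i, j]
      if (p > 0) {
        dtl <- tl[i] - tl[j]
        dietary <- dietary + sp$assimilation[i] * sp$density[i] *
          sp$pop_volume[i] * feed[i] * (cg$tmf^dtl - 1) / cg$tmf^dtl *
          p * zb[j] * fb[j]
      }
    }
    pred <- 0
    for (k in seq_len(nsp)) {
      p <- web$diet[k, i]
      if (p > 0) {
        pred <- pred + feed[k] * sp$density[k] * sp$pop_volume[k] * p * zb[i]
      }
    }
    dm_sp[i] <- uptake + dietary -
      fb[i] * (gill[i] + sp$pop_volume[i] * zb[i] * sp$metabolic_rate[i] +
                 dmd[i] + pred)
  }
  c(air = unname(dm_air), water = unname(dm_water),
    sediment = unname(dm_sed), setNames(dm_sp, sp$name))
}

test_that("ledger mass balance reproduces the printed composite equations", {
  scn <- h_scenario3()
  led <- build_ledger(scn)
  comp <- c("air", "water", "sediment", scn$foodweb$species$name)
  withr::with_seed(21, {
    for (rep in 1:5) {
      f <- setNames(10^runif(6, -9, -5), comp)
      got <- dmdt(led, f,
                  inflow_fugacity = c(air = 2e-9, water = 5e-8),
                  emission = c(water = 0.1))
      want <- h_oracle_dm(scn, f)
      expect_equal(setNames(got$dm_dt, got$compartment), want,
                   tolerance = 1e-12)
    }
  })
})

test_that("dmdt obeys its degenerate and closure cases", {
  scn <- h_scenario3()
  led <- build_ledger(scn)
  comp <- c("air", "water", "sediment", scn$foodweb$species$name)
  # no fugacity anywhere, no inputs: nothing moves
  z <- dmdt(led, setNames(numeric(6), comp))
  expect_equal(z$dm_dt, numeric(6))

  # closed system at uniform fugacity: compartment gains/losses cancel in sum
  scn_cl <- h_scenario3(options = fug_options(
    exclude = c("advection", "reaction", "burial", "metabolism")))
  led_cl <- build_ledger(scn_cl)
  u <- dmdt(led_cl, setNames(rep(1e-6, 6), comp))
  expect_lt(abs(sum(u$dm_dt)), 1e-12 * max(abs(u$dm_dt)))

  # a single exit record drains its source at D * f
  one <- tibble::tibble(name = "RX", source = "box", sink = "EXTERNAL",
                        coeff = 3.5, kind = "exit")
  expect_equal(dmdt(one, c(box = 2))$dm_dt, -7)
})

test_that("dfdt reduces to dM/dt / (Z V) at constant temperature", {
  scn <- h_scenario3()
  comp <- c("air", "water", "sediment", scn$foodweb$species$name)
  f <- setNames(10^seq(-9, -4, length.out = 6), comp)
  out <- dfdt(scn, f)
  led <- build_ledger(scn)
  cap <- attr(led, "cap")
  z <- c(cap$z_air_bulk, cap$z_water_bulk, cap$z_sed_bulk,
         z_biota(scn$foodweb$species$lipid_frac, cap$z_water,
                 scn$congener$kow_ref))
  v <- c(1e9, 1e7, 1e5, scn$foodweb$species$pop_volume)
  expect_equal(out$df_dt, out$dm_dt / (z * v), tolerance = 1e-12)
})

test_that("steady state solves the linear balance and is a fixed point", {
  scn <- make_toy_lake(seed = 1)
  st <- steady_state(scn)
  expect_lt(st$residual, 1e-10)
  expect_true(all(st$fugacity >= 0))
  expect_equal(st$mass, st$z * st$volume * st$fugacity)

  # dM/dt vanishes at the steady fugacities
  led <- build_ledger(scn)
  frc <- forcing_at(scn$forcing, 0)
  dm <- dmdt(led, st$fugacity,
             inflow_fugacity = c(air = frc$inflow_fug_air,
                                 water = frc$inflow_fug_water),
             emission = frc$emission)
  scale <- max(abs(st$flux$flux))
  expect_equal(dm$dm_dt / scale, rep(0, 8), tolerance = 1e-12)

  # homogeneous system: no inputs means zero fugacity everywhere
  scn0 <- h_scenario3(forcing = fug_forcing(air_temp = 280,
                                            water_temp = 285))
  st0 <- steady_state(scn0)
  expect_equal(unname(st0$fugacity), numeric(6))

  # a closed exchange-only system has no unique steady state
  expect_error(steady_state(make_toy_lake(seed = 1, exchange_only = TRUE)),
               class = "fugapop_structural_error")
})

test_that("dynamics match the matrix-exponential solution of the linear system", {
  # abiotic scenario: 3 x 3 linear system solved independently by eigen
  # decomposition of the Jacobian
  scn <- fug_scenario(h_congener(), h_air(), h_water(), h_sediment(),
                      forcing = fug_forcing(air_temp = 280, water_temp = 285,
                                            inflow_fug_air = 2e-9,
                                            inflow_fug_water = 5e-8,
                                            emission = c(water = 0.1)))
  st <- steady_state(scn)
  jac <- st$A / (st$z * st$volume)
  f_star <- unname(st$fugacity)
  eg <- eigen(jac)
  f0 <- c(1e-7, 1e-7, 1e-7)
  co <- solve(eg$vectors, f0 - f_star)
  times <- c(0, 5, 50, 500, 5000)
  sim <- fug_simulate(scn, t_end = max(times), init = f0, times = times)
  for (k in seq_along(times)) {
    want <- f_star + Re(eg$vectors %*% (co * exp(eg$values * times[k])))
    expect_equal(unname(sim$fugacity[k, ]), as.numeric(want),
                 tolerance = 1e-6)
  }
})

test_that("simulation started at steady state stays flat", {
  scn <- make_toy_lake(seed = 6)
  st <- steady_state(scn)
  sim <- fug_simulate(scn, t_end = 2000, n_out = 21)
  dev <- sweep(sim$fugacity, 2, st$fugacity, "/") - 1
  expect_lt(max(abs(dev)), 10 * sim$rtol)
  expect_true(all(sim$fugacity >= -10 * sim$rtol * max(sim$fugacity)))
})

test_that("population dynamics hold balanced webs steady", {
  scn <- make_toy_lake(seed = 8)
  scn$options <- fug_options(population_dynamics = TRUE)
  sim <- fug_simulate(scn, t_end = 200, n_out = 11)
  vp0 <- sim$pop_volume[1, ]
  vp1 <- sim$pop_volume[11, ]
  bal <- balance_populations(scn$foodweb,
                             forcing_at(scn$forcing, 0)$temp_water - 273.15)
  drift <- abs(vp1 / vp0 - 1)
  # non-apex species are exactly balanced; the apex is tuned below 1 % of
  # growth, so over 200 days it moves well under a percent
  expect_lt(max(drift[!bal$apex]), 1e-6)
  expect_lt(drift[bal$apex], 0.01)
})

test_that("mass-balance audit closes for steady and closed systems", {
  scn <- make_toy_lake(seed = 9)
  sim <- fug_simulate(scn, t_end = 500, n_out = 26)
  aud <- mass_balance_audit(sim)
  expect_true(all(aud$relative_error < 1e-6))
  tot <- aud[aud$compartment == "TOTAL", ]
  expect_equal(tot$inputs, tot$outputs, tolerance = 1e-6)

  scn_cl <- make_toy_lake(seed = 9, closed = TRUE)
  sim_cl <- fug_simulate(scn_cl, t_end = 500, init = rep(1e-6, 8),
                         n_out = 26)
  aud_cl <- mass_balance_audit(sim_cl)
  tot_cl <- aud_cl[aud_cl$compartment == "TOTAL", ]
  expect_equal(tot_cl$inputs, 0)
  expect_equal(tot_cl$outputs, 0)
  expect_lt(abs(tot_cl$storage_change) / tot_cl$mass_start, 1e-6)
})

test_that("tidiers and plots expose the result tables", {
  scn <- make_toy_lake(seed = 1)
  st <- steady_state(scn)
  td <- tidy(st)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("compartment", "fugacity", "z", "volume",
                     "concentration", "mass"))
  expect_equal(nrow(td), 8)
  gl <- glance(st)
  expect_equal(gl$total_mass, sum(st$mass))

  sim <- fug_simulate(scn, t_end = 10, n_out = 5)
  tds <- tidy(sim)
  expect_equal(nrow(tds), 5 * 8)
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(autoplot(st), "ggplot")
})
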
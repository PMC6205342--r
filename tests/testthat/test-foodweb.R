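test_that("trophic levels solve the diet-weighted fixed point", {
  web <- h_web3()
  tl <- trophic_levels(web)
  expect_equal(tl$trophic_level, c(1, 2, 2))

  # omnivore: half producer, half herbivore
  sp <- dplyr::bind_rows(
    fug_species("alga", "producer", 0.01, 1e-12, gill_clearance = 8,
                max_age = 0.2, pop_volume = 10),
    fug_species("grazer", "pelagic", 0.02, 1e-7, gill_clearance = 4,
                max_age = 2),
    fug_species("omni", "pelagic", 0.05, 1e-3, gill_clearance = 2,
                max_age = 5)
  )
  diet <- matrix(0, 3, 3, dimnames = list(sp$name, sp$name))
  diet["grazer", "alga"] <- 1
  diet["omni", c("alga", "grazer")] <- 0.5
  tl <- trophic_levels(fug_foodweb(sp, diet))
  expect_equal(tl$trophic_level, c(1, 2, 2.5))

  # random acyclic webs against the fixed-point oracle
  withr::with_seed(5, {
    for (rep in 1:20) {
      n <- sample(3:7, 1)
      nm <- paste0("s", seq_len(n))
      d <- matrix(0, n, n, dimnames = list(nm, nm))
      for (i in 2:n) {
        prey <- sample(seq_len(i - 1), min(i - 1, sample(1:2, 1)))
        w <- runif(length(prey)); d[i, prey] <- w / sum(w)
      }
      spn <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
        fug_species(nm[i], if (i == 1) "producer" else "pelagic",
                    0.02, 1e-6 * i, gill_clearance = 1, max_age = 2,
                    pop_volume = 1)
      }))
      tl <- trophic_levels(fug_foodweb(spn, d))$trophic_level
      expect_equal(tl, h_tl_fixed_point(d), tolerance = 1e-9)
      expect_true(all(tl >= 1))
    }
  })
})

test_that("allometric growth rate matches its printed coefficients", {
  expect_equal(growth_rate(20, 0.001), 0.00586)
  expect_equal(growth_rate(25, 0.001), 0.010009, tolerance = 1e-4)
  expect_equal(growth_rate(20, 1), 1.4720e-3, tolerance = 1e-4)
  # warmer is faster, bigger is slower
  expect_gt(growth_rate(25, 0.1), growth_rate(15, 0.1))
  expect_lt(growth_rate(20, 1), growth_rate(20, 0.01))
})

test_that("longevity-based mortality matches its printed coefficients", {
  expect_equal(natural_mortality_rate(1, annualized = TRUE), 4.899)
  expect_equal(natural_mortality_rate(10, annualized = TRUE), 0.59446,
               tolerance = 1e-4)
  expect_equal(natural_mortality_rate(1), 4.899 / 365)
  ages <- c(0.5, 1, 2, 5, 10, 30)
  expect_true(all(diff(natural_mortality_rate(ages)) < 0))
})

test_that("feeding kernel and predation loss follow the allometric law", {
  expect_equal(feeding_rate(0, 1), 0.022)
  # one predator at the kernel's unity point
  sp <- dplyr::bind_rows(
    fug_species("prey", "producer", 0.02, 1e-3, density = 1000,
                gill_clearance = 1, max_age = 2, pop_volume = 5),
    fug_species("pred", "pelagic", 0.05, 1, density = 1000,
                gill_clearance = 1, max_age = 10, pop_volume = 1)
  )
  diet <- matrix(0, 2, 2, dimnames = list(sp$name, sp$name))
  diet["pred", "prey"] <- 1
  web <- fug_foodweb(sp, diet)
  pl <- predation_loss(web, temp_c = 0)
  expect_equal(pl$predation_loss[pl$name == "prey"], 0.022)
  expect_equal(pl$predation_loss[pl$name == "pred"], 0)

  # linear in predator population volume
  pl2 <- predation_loss(web, temp_c = 0, pop_volume = c(5, 2))
  expect_equal(pl2$predation_loss[1], 0.044)
})

test_that("energy-mass estimate of producer biomass is a unit-checked product", {
  ep <- fug_energy(solar_flux = 200, photosyn_eff = 1, coverage = 1,
                   transport_factor = 1, carbon_prod = 1.5e-6,
                   carbon_frac = 0.5, area = 1e6)
  expect_equal(primary_producer_biomass(ep, lifetime = 5), 2.592e8)
  ep0 <- fug_energy(solar_flux = 200, photosyn_eff = 1, coverage = 0,
                    carbon_prod = 1.5e-6, carbon_frac = 0.5, area = 1e6)
  expect_equal(primary_producer_biomass(ep0, 5), 0)
  expect_error(fug_energy(solar_flux = 200, photosyn_eff = 1,
                          carbon_prod = 1.5e-6, carbon_frac = 0,
                          area = 1e6),
               class = "fugapop_validation_error")
})

test_that("population balance closes growth against mortality plus predation", {
  # two-species chain: the predator volume follows by hand algebra
  sp <- dplyr::bind_rows(
    fug_species("alga", "producer", 0.01, 1e-12, density = 1000,
                gill_clearance = 8, max_age = 0.2, pop_volume = 50),
    fug_species("grazer", "pelagic", 0.02, 1e-7, density = 1000,
                gill_clearance = 4, max_age = 2)
  )
  diet <- matrix(0, 2, 2, dimnames = list(sp$name, sp$name))
  diet["grazer", "alga"] <- 1
  web <- fug_foodweb(sp, diet)
  temp <- 12
  bal <- balance_populations(web, temp)
  surplus <- growth_rate(temp, 1e-12) - natural_mortality_rate(0.2)
  kernel <- feeding_rate(temp, 1e-7) * 1000 / 1000 # per unit grazer volume
  expect_equal(bal$pop_volume[2], surplus * 50 / kernel, tolerance = 1e-12)

  # balanced volumes satisfy dV/dt = 0 for all non-apex species
  res <- dv_dt(fug_foodweb(
    dplyr::mutate(sp, pop_volume = bal$pop_volume), diet), temp)
  expect_equal(res$dv_dt[1], 0, tolerance = 1e-9 * res$growth[1])
  expect_true(bal$apex[2])

  # branched web: every preyed species balances simultaneously
  scn <- make_toy_lake(seed = 4)
  web5 <- scn$foodweb
  temp5 <- forcing_at(scn$forcing, 0)$temp_water - 273.15
  bal5 <- balance_populations(web5, temp5)
  non_apex <- !bal5$apex
  expect_true(all(abs(bal5$residual[non_apex]) <=
                    1e-9 * growth_rate(temp5, web5$species$body_mass[non_apex]) *
                    bal5$pop_volume[non_apex] + 1e-12))
  expect_true(all(bal5$pop_volume >= 0))

  # infeasible web (mortality exceeds growth at the base) is reported
  sp_bad <- sp
  sp_bad$max_age[1] <- 0.02
  expect_error(balance_populations(fug_foodweb(sp_bad, diet), temp),
               class = "fugapop_infeasible_error")
})

test_that("dV/dt composes growth, mortality and predation", {
  web <- h_web3()
  temp <- 15
  withr::with_seed(3, {
    for (i in 1:10) {
      vp <- runif(3, 0.1, 30)
      out <- dv_dt(web, temp, pop_volume = vp)
      kg <- growth_rate(temp, web$species$body_mass)
      m <- natural_mortality_rate(web$species$max_age)
      pl <- predation_loss(web, temp, pop_volume = vp)$predation_loss
      expect_equal(out$dv_dt, kg * vp - m * vp - pl, tolerance = 1e-12)
    }
  })
  # no predators and positive surplus: population grows
  lone <- fug_foodweb(dplyr::slice(web$species, 1),
                      matrix(0, 1, 1, dimnames = list("alga", "alga")))
  expect_gt(dv_dt(lone, 15)$dv_dt, 0)
})
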
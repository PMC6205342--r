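test_that("two-film volatilisation D-value behaves as a series resistance", {
  cg <- h_congener()
  cap <- fug_capacities(cg, h_air(), h_water(), h_sediment())

  # single-film limit: air-side resistance vanishes as kVA grows
  fast_air <- air_water_dvalues(cap, h_air(mtc_air = 1e12))
  dv <- fast_air$coeff[fast_air$name == "DV"][1]
  expect_equal(dv, 0.5 * 1e6 * cap$z_water, tolerance = 1e-6)

  # harmonic-mean bound for random film coefficients
  withr::with_seed(7, {
    for (i in 1:50) {
      kva <- 10^runif(1, -2, 3)
      kvw <- 10^runif(1, -3, 1)
      led <- air_water_dvalues(cap, h_air(mtc_air = kva, mtc_water = kvw))
      dv <- led$coeff[led$name == "DV"][1]
      expect_lt(dv, min(kva * 1e6 * cap$z_gas, kvw * 1e6 * cap$z_water))
      expect_true(all(led$coeff >= 0))
    }
  })

  # no rain: wet pathways off
  dry <- air_water_dvalues(cap, h_air(rain_rate = 0))
  expect_equal(dry$coeff[dry$name %in% c("DRWW", "DQWW")], c(0, 0))
  expect_error(air_water_dvalues(cap, h_air(mtc_air = 0)),
               class = "fugapop_domain_error")

  # volatilisation is registered in both directions
  dvs <- air_water_dvalues(cap, h_air())
  dvs <- dvs[dvs$name == "DV", ]
  expect_setequal(paste(dvs$source, dvs$sink),
                  c("air water", "water air"))
})

test_that("water-sediment D-values are direct products of their factors", {
  cap <- list(z_water = 0.1, z_susp = 0.5, z_sed_solid = 40, z_sed_bulk = 4)
  led <- water_sediment_dvalues(
    cap, h_water(dep_vel = 1e-4, area_ws = 1e6), h_sediment())
  expect_equal(led$coeff[led$name == "DDS"], 50)

  led0 <- water_sediment_dvalues(cap, h_water(resusp_vel = 0), h_sediment())
  expect_equal(led0$coeff[led0$name == "DRS"], 0)

  # burial off keeps the sediment bottom closed; on adds an exit
  expect_false("DSO" %in% led$name)
  ledb <- water_sediment_dvalues(cap, h_water(),
                                 h_sediment(burial_flow = 100))
  expect_equal(ledb$coeff[ledb$name == "DSO"], 100 * 4)
  expect_equal(ledb$kind[ledb$name == "DSO"], "exit")
})

test_that("reaction and advection D-values scale with V Z / lifetime and G Z", {
  cap <- list(z_air_bulk = 4e-4, z_water_bulk = 0.1, z_sed_bulk = 4)
  led <- reaction_advection_dvalues(
    cap, h_congener(lifetime_air = 100),
    h_air(volume = 1e9), h_water(), h_sediment())
  expect_equal(led$coeff[led$name == "RA"], 1e9 * 4e-4 / 100)

  # inert chemical: reaction rows are dropped entirely
  inert <- reaction_advection_dvalues(
    cap, h_congener(lifetime_air = Inf, lifetime_water = Inf,
                    lifetime_sediment = Inf),
    h_air(), h_water(), h_sediment())
  expect_false(any(inert$name %in% c("RA", "RW", "RS")))

  # equal in/out flows with the same bulk Z give equal advective D
  expect_equal(led$coeff[led$name == "DAI"], led$coeff[led$name == "DAO"])
})

test_that("dietary three-way split conserves ingested chemical", {
  s <- dietary_split(ed = 1, tmf = 1e12, delta_tl = 1)
  expect_equal(s$retained, 1, tolerance = 1e-10)
  expect_equal(s$gut_feces, 0, tolerance = 1e-10)

  # TMF = 1: all absorbed chemical re-exchanged to feces
  s1 <- dietary_split(ed = 0.8, tmf = 1, delta_tl = 1)
  expect_equal(s1$retained, 0)
  expect_equal(s1$gut_feces, 0.8)

  withr::with_seed(11, {
    ed <- runif(1000)
    tmf <- 10^runif(1000, -0.5, 1) # includes trophic dilution (TMF < 1)
    dtl <- runif(1000, 0.05, 2.5)
    s <- dietary_split(ed, tmf, dtl)
    expect_equal(s$retained + s$gut_feces + s$undigested, rep(1, 1000),
                 tolerance = 1e-12)
    expect_true(all(s$gut_feces >= 0 & s$undigested >= 0))
    # magnifying chemicals (TMF >= 1) always retain a nonnegative share
    mag <- tmf >= 1
    expect_true(all(s$retained[mag] >= 0))
  })

  expect_warning(dietary_split(0.5, 2, -0.5), regexp = "clamped")
  sneg <- suppressWarnings(dietary_split(0.5, 2, -0.5))
  expect_equal(sneg$retained + sneg$gut_feces + sneg$undigested, 1)
  expect_error(dietary_split(1.5, 2, 1), class = "fugapop_validation_error")
})

test_that("biotic D-values couple to the right environmental fugacity", {
  cg <- h_congener()
  cap <- fug_capacities(cg, h_air(), h_water(), h_sediment())
  web <- h_web3()
  led <- biota_dvalues(web, cg, cap, temp_c = 12)

  expect_true(all(led$coeff >= 0))

  # pelagic and producer gills exchange with water, benthic with sediment
  gg <- led[startsWith(led$name, "DGG"), ]
  expect_equal(gg$source[gg$sink == "alga"], "water")
  expect_equal(gg$source[gg$sink == "daphnia"], "water")
  expect_equal(gg$source[gg$sink == "worm"], "sediment")

  # gill uptake coefficient k1 VP rho Z_wat, and release mirrors uptake
  sp <- web$species
  expect_equal(gg$coeff,
               sp$gill_clearance * sp$pop_volume * sp$density * cap$z_water)
  gl <- led[startsWith(led$name, "DGL"), ]
  expect_equal(gl$coeff, gg$coeff)

  # mortality routed to sediment by default, split when requested
  md <- led[startsWith(led$name, "DMD"), ]
  expect_true(all(md$sink == "sediment"))
  led2 <- biota_dvalues(web, cg, cap, temp_c = 12, mortality_to_water = 0.4)
  mdw <- led2[startsWith(led2$name, "DMDW"), ]
  expect_setequal(mdw$source, c("alga", "daphnia")) # benthic never to water
  md2 <- led2[led2$name %in% paste0("DMD:", sp$name), ]
  tot1 <- sum(md$coeff)
  expect_equal(sum(mdw$coeff) + sum(md2$coeff), tot1, tolerance = 1e-12)

  # each dietary record appears once per predator-prey pair and class
  dfi <- led[startsWith(led$name, "DFI"), ]
  expect_equal(nrow(dfi), 2)
  expect_setequal(dfi$sink, c("daphnia", "worm"))
  expect_true(all(dfi$source == "alga"))
})

test_that("mutual predation clamps the trophic-level difference with a warning", {
  sp <- dplyr::bind_rows(
    fug_species("alga", "producer", 0.01, 1e-12, gill_clearance = 8,
                max_age = 0.2, pop_volume = 20),
    fug_species("a", "pelagic", 0.02, 1e-7, gill_clearance = 4,
                max_age = 2, pop_volume = 3),
    fug_species("b", "pelagic", 0.02, 1e-7, gill_clearance = 4,
                max_age = 2, pop_volume = 3)
  )
  diet <- matrix(0, 3, 3, dimnames = list(sp$name, sp$name))
  diet["a", c("alga", "b")] <- 0.5
  diet["b", c("alga", "a")] <- 0.5
  web <- fug_foodweb(sp, diet)
  cg <- h_congener()
  cap <- fug_capacities(cg, h_air(), h_water(), h_sediment())
  expect_warning(biota_dvalues(web, cg, cap, temp_c = 12),
                 regexp = "clamped")
  led <- suppressWarnings(biota_dvalues(web, cg, cap, temp_c = 12))
  expect_true(all(led$coeff >= 0))
})
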
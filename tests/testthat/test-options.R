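world <- small_world(n = 3, seed = 14)
rotations <- simulate_all_rotations(world)

test_that("the catalog carries five variants with the stated caps and combinability", {
  cat <- build_catalog(world, world$regions$id[1], rotations)
  expect_equal(nrow(cat), 5)
  expect_setequal(cat$option, c("soc_crop", "soc_pasture", "silvo_bioenergy",
                                "silvo_carbon", "biochar"))
  expect_equal(cat$max_share[cat$option == "soc_crop"], 0.90)
  expect_equal(cat$max_share[cat$option == "soc_pasture"], 0.60)
  expect_equal(cat$max_share[cat$option == "silvo_bioenergy"], 0.50)
  expect_equal(cat$max_share[cat$option == "silvo_carbon"], 0.50)
  # biochar is feedstock-limited, not area-capped
  expect_equal(cat$max_share[cat$option == "biochar"], 1)
  expect_equal(cat$saturation_years,
               c(20L, 20L, 10L, 30L, 30L)[match(cat$option, c("soc_crop",
                 "soc_pasture", "silvo_bioenergy", "silvo_carbon", "biochar"))])
  # cropland SOC and biochar sit in different combine groups (co-adoptable),
  # the two silvo variants share one group (mutually exclusive hectares)
  expect_equal(sum(cat$combine_group == "silvo"), 2)
  expect_error(build_catalog(world, world$regions$id[1], list()), "missing silvo")
})

test_that("maximum adoptable areas follow the caps", {
  rid <- world$regions$id[2]
  reg <- world$regions[world$regions$id == rid, ]
  cat <- build_catalog(world, rid, rotations)
  expect_equal(cat$max_share[cat$option == "soc_crop"] * reg$cropland_area,
               0.9 * reg$cropland_area)
})

test_that("co-adopted options are additive in the ledger flux", {
  led <- new_ledger()
  led <- add_vintage(led, "R1", "soc_crop", 2030, 10, 0.5, 20L)
  led <- add_vintage(led, "R1", "biochar", 2030, 10, 2.0, 30L)
  expect_equal(annual_flux(led, 2035),
               annual_flux(led, 2035, option = "soc_crop") +
                 annual_flux(led, 2035, option = "biochar"))
  expect_equal(annual_flux(led, 2035), 10 * 0.5 + 10 * 2.0)
})

test_that("a vintage's flux is constant until saturation and zero exactly at the horizon", {
  for (case in list(list(op = "soc_crop", sat = 20L),
                    list(op = "biochar", sat = 30L),
                    list(op = "silvo_bioenergy", sat = 10L))) {
    led <- add_vintage(new_ledger(), "R1", case$op, 2025, 1, 0.7, case$sat)
    offsets <- 0:(case$sat + 5)
    flux <- vapply(offsets, function(d) annual_flux(led, 2025 + d), numeric(1))
    expect_true(all(flux[offsets < case$sat] == 0.7))
    expect_true(all(flux[offsets >= case$sat] == 0))
    first_zero <- offsets[which(flux == 0)[1]]
    expect_identical(first_zero, case$sat)
  }
})

test_that("multi-vintage flux equals the brute-force cohort enumeration", {
  led <- new_ledger()
  led <- add_vintage(led, "R1", "soc_crop", 2020, 3, 0.6, 20L)
  led <- add_vintage(led, "R1", "soc_crop", 2030, 2, 0.6, 20L)
  for (y in 2018:2060)
    expect_equal(annual_flux(led, y), brute_force_flux(led, y))
  # cumulative stock telescopes the annual fluxes exactly
  for (y in c(2025, 2040, 2055))
    expect_equal(cumulative_stock(led, y),
                 sum(vapply(2020:y, function(t) annual_flux(led, t), numeric(1))))
})

test_that("flux is invariant to splitting a vintage and dies once all cohorts saturate", {
  one <- add_vintage(new_ledger(), "R1", "soc_pasture", 2030, 8, 0.45, 20L)
  split <- add_vintage(new_ledger(), "R1", "soc_pasture", 2030, 5, 0.45, 20L)
  split <- add_vintage(split, "R1", "soc_pasture", 2030, 3, 0.45, 20L)
  for (y in seq(2030, 2055, by = 5))
    expect_equal(annual_flux(split, y), annual_flux(one, y))
  led <- add_vintage(one, "R2", "biochar", 2035, 2, 2.1, 30L)
  expect_gt(annual_flux(led, 2050), 0)
  expect_equal(annual_flux(led, 2066), 0)  # all cohorts past their horizons
})

test_that("yield co-benefits are linear with the stated regional rates", {
  expect_equal(yield_co_benefit("AFR", 1), 1.5)
  expect_equal(yield_co_benefit("LAM", 1), 1.2)
  expect_equal(yield_co_benefit("ASIA", 2), 1.4)
  expect_equal(yield_co_benefit("NORTH", 3), 0)
  expect_equal(yield_co_benefit("OTHER_SOUTH", 1), 0)
  expect_equal(yield_co_benefit("AFR", 0), 0)
})

test_that("the grazing penalty is 25% of yield on the converted area, linearly", {
  expect_equal(grazing_penalty(100, 2), 50)
  expect_equal(grazing_penalty(0, 2), 0)
  expect_equal(grazing_penalty(7, 1.8), 7 * grazing_penalty(1, 1.8))
})
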
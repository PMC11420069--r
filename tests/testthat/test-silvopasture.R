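params_euc <- species_params("eucalypt")

test_that("environmental modifiers respect their boundary behaviour", {
  soil <- make_soil()
  # optimum temperature gives a modifier of exactly 1
  m <- env_modifiers(make_month(t_mean = params_euc$t_opt), soil, age = 1,
                     params = params_euc)
  expect_equal(m[["temperature"]], 1)
  # at or outside the cardinal range the modifier is 0
  for (t in c(params_euc$t_min, params_euc$t_max, params_euc$t_min - 3,
              params_euc$t_max + 3)) {
    m <- env_modifiers(make_month(t_mean = t, t_min = t - 5, t_max = t + 5),
                       soil, age = 1, params = params_euc)
    expect_equal(m[["temperature"]], 0)
  }
  # a fully frosted month shuts growth down
  m <- env_modifiers(make_month(month = 1, frost_days = 31), soil, age = 1,
                     params = params_euc)
  expect_equal(m[["frost"]], 0)
  # no vapour pressure deficit, no VPD limitation
  m <- env_modifiers(make_month(vpd = 0), soil, age = 1, params = params_euc)
  expect_equal(m[["vpd"]], 1)
  # all modifiers bounded in [0, 1] across a sweep of conditions
  for (t in seq(-10, 45, by = 5)) for (v in c(0, 1, 3)) {
    m <- env_modifiers(make_month(t_mean = t, t_min = t - 6, t_max = t + 6,
                                  vpd = v), soil, age = 40, params = params_euc,
                       asw = 50)
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("a zero-radiation month produces no GPP and only turnover", {
  st <- new_stand(1400)
  st$w_foliage <- 1; st$w_root <- 1; st$w_stem <- 2
  out <- step_month(st, make_month(solar_radiation = 0), make_soil(), params_euc)
  expect_equal(out$gpp, 0)
  expect_equal(out$state$w_stem, 2)
  expect_equal(out$state$w_foliage, 1 * (1 - params_euc$turnover_foliage))
  expect_equal(out$state$w_root, 1 * (1 - params_euc$turnover_root))
  expect_error(step_month(st, make_month(solar_radiation = -1), make_soil(),
                          params_euc), "negative solar radiation")
})

test_that("with all modifiers at 1 NPP equals the closed form y * alpha * APAR", {
  st <- new_stand(1400)
  mo <- make_month(t_mean = params_euc$t_opt, vpd = 0, frost_days = 0)
  out <- step_month(st, mo, make_soil(), params_euc, lai_override = 3,
                    age_feedback = FALSE)
  apar <- mo$solar_radiation * 30 * 1e4 * 0.5 * (1 - exp(-params_euc$k * 3))
  expect_equal(out$npp, params_euc$y * params_euc$alpha * apar, tolerance = 1e-12)
})

test_that("harsher growing conditions shift allocation towards roots", {
  st <- new_stand(1400); st$w_foliage <- 1
  benign <- step_month(st, make_month(t_mean = params_euc$t_opt, vpd = 0),
                       make_soil(), params_euc)
  harsh <- step_month(st, make_month(t_mean = params_euc$t_opt, vpd = 2.2),
                      make_soil(), params_euc)
  expect_lt(prod(harsh$modifiers), prod(benign$modifiers))
  expect_gt(harsh$fractions[["root"]], benign$fractions[["root"]])
})

test_that("allocation fractions sum to one and the carbon balance closes to 1e-9", {
  st <- new_stand(1800); st$w_foliage <- 0.8; st$w_root <- 0.6; st$w_stem <- 1.5
  set.seed(1)
  for (i in 1:25) {
    mo <- make_month(month = sample(12, 1), t_mean = runif(1, 5, 35),
                     solar_radiation = runif(1, 2, 25), vpd = runif(1, 0, 2),
                     frost_days = sample(0:10, 1))
    out <- step_month(st, mo, make_soil(), params_euc, asw = runif(1, 20, 200))
    expect_equal(sum(out$fractions), 1, tolerance = 1e-12)
    pools_before <- st$w_foliage + st$w_root + st$w_stem
    pools_after <- out$state$w_foliage + out$state$w_root + out$state$w_stem
    expect_equal(pools_after - pools_before + out$turnover, out$npp,
                 tolerance = 1e-9 * max(1, out$npp))
    st <- out$state
  }
})

test_that("GPP is monotone non-decreasing in each modifier", {
  st <- new_stand(1400); st$w_foliage <- 1
  gpp_at <- function(...) step_month(st, make_month(...), make_soil(), params_euc)$gpp
  # towards the temperature optimum
  expect_lte(gpp_at(t_mean = 15), gpp_at(t_mean = 20))
  # lower VPD
  expect_lte(gpp_at(vpd = 1.5), gpp_at(vpd = 0.5))
  # fewer frost days
  expect_lte(gpp_at(frost_days = 10), gpp_at(frost_days = 2))
  # wetter soil
  g_dry <- step_month(st, make_month(), make_soil(), params_euc, asw = 40)$gpp
  g_wet <- step_month(st, make_month(), make_soil(), params_euc, asw = 180)$gpp
  expect_lte(g_dry, g_wet)
})

test_that("constant-climate cumulative NPP matches the closed form without feedbacks", {
  st <- new_stand(1400)
  mo <- make_month(month = 4, t_mean = 22, vpd = 0.6)
  mods <- env_modifiers(mo, make_soil(), age = 0, params = params_euc)
  mods[["age"]] <- 1
  apar <- mo$solar_radiation * 30 * 1e4 * 0.5 * (1 - exp(-params_euc$k * 2))
  n <- 24
  for (i in seq_len(n))
    st <- step_month(st, mo, make_soil(), params_euc, lai_override = 2,
                     age_feedback = FALSE)$state
  closed <- n * params_euc$y * params_euc$alpha * apar * prod(mods)
  expect_equal(params_euc$y * st$cumulative_gpp, closed, tolerance = 1e-6)
})

test_that("stand attributes are consistent with the allometry", {
  st <- new_stand(1000)
  expect_equal(stand_attributes(st, params_euc)$dbh > 0, TRUE)
  st$w_stem <- 0
  att0 <- stand_attributes(st, params_euc)
  expect_equal(att0$volume, 0); expect_equal(att0$dbh, 0)
  # allometry is monotone: doubling stem carbon at fixed stocking raises DBH
  st$w_stem <- 10; d1 <- stand_attributes(st, params_euc)$dbh
  st$w_stem <- 20; d2 <- stand_attributes(st, params_euc)$dbh
  expect_gt(d2, d1)
  # volume x wood density recovers stem dry mass within 1% on synthetic states
  for (ws in c(5, 20, 60)) {
    st$w_stem <- ws
    att <- stand_attributes(st, params_euc)
    expect_equal(att$volume * params_euc$wood_density, ws / 0.5,
                 tolerance = 0.01)
  }
  st$stems_per_ha <- 0
  expect_error(stand_attributes(st, params_euc), "no stems")
})

test_that("nutrient demand nets out soil supply and keeps the P:N ratio", {
  inc <- c(foliage = 1, root = 0.5, stem = 2)
  expect_equal(nutrient_demand(c(foliage = 0, root = 0, stem = 0), params_euc)$n, 0)
  nd <- nutrient_demand(inc, params_euc, soil_n_supply = 0)
  gross <- 1 * params_euc$n_conc_foliage + 0.5 * params_euc$n_conc_root +
    2 * params_euc$n_conc_stem
  expect_equal(nd$n, gross)
  expect_equal(nd$p / nd$n, params_euc$p_to_n_ratio)
  # supply above gross demand clamps to zero
  expect_equal(nutrient_demand(inc, params_euc, soil_n_supply = gross + 10)$n, 0)
})

test_that("rotations select species by climate and respect stated densities", {
  w <- small_world(n = 4, seed = 21)
  # force one region to a cool temperate climatology (MAT 8 degC)
  rid <- w$regions$id[1]
  i <- w$climate$region == rid
  mths <- w$climate$month[i]
  w$climate$t_mean[i] <- 8 + 9 * sin(2 * pi * (mths - 4) / 12)
  w$climate$t_min[i] <- w$climate$t_mean[i] - 5
  w$climate$t_max[i] <- w$climate$t_mean[i] + 5
  w$climate$frost_days[i] <- pmax(0, pmin(28, round((2 - w$climate$t_min[i]) * 3)))
  cool <- simulate_rotation(w, rid, "bioenergy_10yr")
  expect_equal(cool$species, "poplar")
  # and a hot one picks the eucalypt
  rid2 <- w$regions$id[2]
  i2 <- w$climate$region == rid2
  w$climate$t_mean[i2] <- 25; w$climate$t_min[i2] <- 20; w$climate$t_max[i2] <- 30
  w$climate$frost_days[i2] <- 0
  hot <- simulate_rotation(w, rid2, "carbon_30yr")
  expect_equal(hot$species, "eucalypt")
  # stated density windows per system
  expect_true(cool$stems_per_ha >= 1250 && cool$stems_per_ha <= 2500)
  expect_true(hot$stems_per_ha >= 400 && hot$stems_per_ha <= 600)
})

test_that("rotation trajectories accumulate carbon and annualize as 0.25 dC 44/12 / T", {
  w <- small_world(n = 2, seed = 33)
  for (sys in c("bioenergy_10yr", "carbon_30yr")) {
    r <- simulate_rotation(w, w$regions$id[1], sys)
    tr <- r$carbon_trajectory
    expect_true(all(diff(tr$total_c) >= 0))
    init <- r$stems_per_ha * 5e-4
    years <- r$rotation_years
    expect_equal(r$annualized_seq,
                 max(0, 0.25 * (tr$total_c[years] - init) * 44 / 12 / years),
                 tolerance = 1e-12)
    expect_gte(r$annualized_seq, 0)
  }
  r10 <- simulate_rotation(w, w$regions$id[2], "bioenergy_10yr")
  expect_true(is.finite(r10$harvested_biomass) && r10$harvested_biomass > 0)
})
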
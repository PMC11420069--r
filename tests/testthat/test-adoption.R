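test_that("the GHG price ramps linearly from zero in 2030 to the endpoint in 2050", {
  p <- price_trajectory(160)
  expect_equal(p(2020), 0)
  expect_equal(p(2029), 0)
  expect_equal(p(2030), 0)
  expect_equal(p(2040), 80)
  expect_equal(p(2050), 160)
  expect_equal(p(2070), 320)  # linear continuation on the extended horizon
})

test_that("the quadratic cost function and its marginal cost are consistent", {
  o <- make_option(c1 = 5, slope = 80)
  expect_equal(adoption_cost(o, 0), 0)
  # marginal cost matches the finite difference of C within 1e-6
  h <- 1e-7
  for (a in c(0.1, 0.5, 0.85)) {
    mc <- o$c1 + o$slope * a
    fd <- (adoption_cost(o, a + h) - adoption_cost(o, a - h)) / (2 * h)
    expect_equal(fd, mc, tolerance = 1e-6)
  }
  # doubling the slope doubles the curvature part C(a) - c1 a
  o2 <- make_option(c1 = 5, slope = 160)
  a <- 0.4
  expect_equal(adoption_cost(o2, a) - o2$c1 * a,
               2 * (adoption_cost(o, a) - o$c1 * a))
  expect_error(adoption_cost(o, 1.2), "outside")
})

test_that("optimal adoption solves the first-order condition and its corners", {
  expect_equal(optimal_adoption(make_option(c1 = 10), ghg_price = 0), 0)
  # zero slope with positive net marginal revenue hits the cap, no division error
  expect_equal(optimal_adoption(make_option(c1 = 0, slope = 0, max_share = 0.9),
                                ghg_price = 50), 0.9)
  expect_equal(optimal_adoption(make_option(c1 = 999, slope = 0), 1), 0)
  # comparative statics: non-decreasing in price
  o <- make_option(seq_coeff = 0.6, slope = 120)
  a <- vapply(seq(0, 300, by = 25), function(p) optimal_adoption(o, p), numeric(1))
  expect_true(all(diff(a) >= 0))
})

test_that("optimal adoption matches the brute-force grid oracle on 100 random draws", {
  set.seed(7)
  for (i in 1:100) {
    o <- make_option(seq_coeff = runif(1, 0.2, 2.5), c1 = runif(1, 0, 40),
                     slope = runif(1, 20, 400), max_share = runif(1, 0.3, 1))
    p <- runif(1, 0, 250)
    v <- runif(1, 0, 30)
    a_star <- optimal_adoption(o, p, v)
    a_grid <- grid_adoption_oracle(o, p, v)
    expect_lt(abs(a_star - a_grid), 1.1e-4)
  }
})

test_that("slope calibration round-trips the stated adoption shares at 100 USD", {
  w <- small_world(n = 3, seed = 5)
  rot <- simulate_all_rotations(w)
  cats <- lapply(w$regions$id, function(r) build_catalog(w, r, rot))
  names(cats) <- w$regions$id
  cats <- calibrate_catalogs(w, cats, calib_price = 100)
  for (rid in names(cats)) {
    cat <- cats[[rid]]
    crop <- cat[cat$option == "soc_crop", ]
    past <- cat[cat$option == "soc_pasture", ]
    expect_equal(optimal_adoption(crop, 100, crop$co_benefit), 0.90,
                 tolerance = 1e-6)
    expect_equal(optimal_adoption(past, 100, past$co_benefit), 0.60,
                 tolerance = 1e-6)
  }
})

test_that("the closed-form slope agrees with a bisection oracle to 1e-8", {
  o <- make_option(seq_coeff = 0.55, c1 = 3)
  target <- 0.62
  s_closed <- calibrate_slope(o, target, calib_price = 100)
  # bisection on s: adoption is decreasing in the slope
  lo <- 1e-6; hi <- 1e6
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    om <- o; om$slope <- mid
    if (optimal_adoption(om, 100) > target) lo <- mid else hi <- mid
  }
  expect_equal(s_closed, (lo + hi) / 2, tolerance = 1e-8)
  expect_error(calibrate_slope(make_option(seq_coeff = 0.01, c1 = 50), 0.5),
               "infeasible")
  expect_error(calibrate_slope(o, 0), "target share")
})

test_that("known slopes are recovered from synthetic observed adoptions to 1e-6", {
  set.seed(11)
  for (i in 1:25) {
    s_true <- runif(1, 30, 500)
    o <- make_option(seq_coeff = runif(1, 0.3, 2), c1 = runif(1, 0, 20),
                     slope = s_true, max_share = 1)
    p <- runif(1, 50, 200)
    a_obs <- optimal_adoption(o, p)
    if (a_obs <= 0 || a_obs >= 1) next   # only interior observations identify s
    expect_equal(calibrate_slope(o, a_obs, calib_price = p), s_true,
                 tolerance = 1e-6)
  }
})

test_that("a baseline run adopts nothing and a priced run hits the SOC calibration", {
  w1 <- generate_world(world_config(n_regions = 1, seed = 1))
  base <- run_horizon(new_model(w1, scenario_config("baseline")))
  expect_equal(nrow(as.data.frame(base$ledger)), 0)
  expect_true(all(base$reports$share == 0))
  # single region, agCO2 at 100 USD2000: cropland SOC reaches its 90% cap in 2050
  run <- run_horizon(new_model(w1, scenario_config("agCO2", endpoint = 100)))
  r50 <- run$reports[run$reports$year == 2050, ]
  expect_equal(r50$share[r50$option == "soc_crop"], 0.90, tolerance = 1e-6)
  expect_equal(r50$share[r50$option == "soc_pasture"], 0.60, tolerance = 1e-6)
})

test_that("a higher endpoint brings adoption forward", {
  w <- small_world(n = 2, seed = 4)
  run100 <- run_horizon(new_model(w, scenario_config("agCO2", endpoint = 100)))
  run200 <- run_horizon(new_model(w, scenario_config("agCO2", endpoint = 200)))
  s35 <- function(run) sum(run$reports$share[run$reports$year == 2035])
  expect_gt(s35(run200), s35(run100))
})

test_that("adoption is irreversible and respects the caps every period", {
  w <- small_world(n = 3, seed = 6)
  run <- run_horizon(new_model(w, scenario_config("agCO2_bio", endpoint = 200)))
  rep <- run$reports
  for (rid in w$regions$id) for (op in unique(rep$option)) {
    sh <- rep$share[rep$region == rid & rep$option == op]
    expect_true(all(diff(sh) >= -1e-12))   # vintage areas never shrink
  }
  # per land type the mutually exclusive silvo shares stay within the 50% cap
  for (rid in w$regions$id) for (y in unique(rep$year)) {
    i <- rep$region == rid & rep$year == y
    silvo <- sum(rep$share[i & rep$option %in% c("silvo_bioenergy", "silvo_carbon")])
    expect_lte(silvo, 0.50 + 1e-9)
    expect_lte(rep$share[i & rep$option == "soc_crop"], 0.90 + 1e-9)
    expect_lte(rep$share[i & rep$option == "soc_pasture"], 0.60 + 1e-9)
  }
  expect_true(all(vapply(run$markets, function(m)
    m$total_allocated <= sum(m$served) + 1e-9, logical(1))))
})

test_that("MACC points are deterministic and cumulative mitigation is monotone", {
  w <- small_world(n = 2, seed = 8)
  m <- build_macc(w, endpoints = c(50, 50, 150))
  expect_equal(m$cumulative[1], m$cumulative[2])   # duplicate endpoints agree
  expect_gte(m$cumulative[3], m$cumulative[1])
})
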
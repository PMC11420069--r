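# shared fixtures: tiny worlds and hand-built catalog rows

small_world <- function(n = 3, seed = 42, ...) {
  generate_world(world_config(n_regions = n, seed = seed, ...))
}

# a standalone catalog-row-like option for unit tests of the adoption math
make_option <- function(seq_coeff = 0.6, c1 = 0, slope = 100, max_share = 0.9,
                        saturation_years = 20L, yield_k = 0,
                        land_type = "cropland", option = "soc_crop") {
  data.frame(region = "T1", option = option, land_type = land_type,
             seq_coeff = seq_coeff, saturation_years = saturation_years,
             max_share = max_share, c1 = c1, slope = slope,
             yield_k = yield_k, combine_group = "test",
             stringsAsFactors = FALSE)
}

# a one-row climate slice with full control over the drivers
make_month <- function(month = 6, t_mean = 25, t_min = t_mean - 5,
                       t_max = t_mean + 5, precipitation = 150,
                       solar_radiation = 15, frost_days = 0, vpd = 0.8) {
  data.frame(region = "T1", month = month, t_min = t_min, t_max = t_max,
             t_mean = t_mean, precipitation = precipitation,
             solar_radiation = solar_radiation, frost_days = frost_days,
               vpd = vpd, stringsAsFactors = FALSE)
}

make_soil <- function(max_asw = 200, fertility_rating = 0.7, soc_stock = 50,
                      n_stock = 5) {
  list(max_asw = max_asw, fertility_rating = fertility_rating,
       soc_stock = soc_stock, n_stock = n_stock)
}

# grid-search oracle for the adoption problem: maximise
# p q a + v a - (c1 a + s/2 a^2) over a in [0, max_share]
grid_adoption_oracle <- function(option, price, v = 0, resolution = 1e-4) {
  a <- seq(0, option$max_share, by = resolution)
  profit <- price * option$seq_coeff * a + v * a -
    (option$c1 * a + option$slope / 2 * a^2)
  a[which.max(profit)]
}

# brute-force cohort enumeration of the ledger flux at one year
brute_force_flux <- function(ledger, year) {
  df <- as.data.frame(ledger)
  tot <- 0
  for (i in seq_len(nrow(df))) {
    age <- year - df$adoption_year[i]
    if (age >= 0 && age < df$saturation_years[i])
      tot <- tot + df$area[i] * df$seq_coeff[i]
  }
  tot
}
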
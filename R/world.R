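# Synthetic world generation: regions with land areas, monthly climate, soils,
# per-region sequestration coefficients and economic attributes. Stands in for
# the gridded land-use, soil and climate databases a global assessment would
# ingest, while preserving the statistical structure the downstream modules
# assume (area shares, coefficient magnitudes, plausible seasonal climate).

REGION_GROUPS <- c("AFR", "LAM", "ASIA", "NORTH", "OTHER_SOUTH")
COEF_OPTIONS <- c("soc_crop", "soc_pasture", "biochar")

#' World generator configuration
#'
#' Assembles and validates the configuration consumed by [generate_world()].
#' Default global land totals are illustrative values back-derived from
#' published adoption shares (900 Mha being 53% of cropland and 1,100 Mha
#' being 60% of managed grassland); coefficient ranges are in the magnitude
#' band reported for per-hectare mitigation efficiency of the options
#' (roughly 0.5--2.1 tCO2e ha-1 yr-1).
#'
#' @param n_regions number of synthetic world regions (>= 1).
#' @param seed integer root seed; reproducibly determines every draw.
#' @param global_cropland,global_pasture global land totals, Mha.
#' @param coefficient_ranges named list of length-2 numeric ranges
#'   (tCO2e ha-1 yr-1) for options `soc_crop`, `soc_pasture`, `biochar`.
#' @param bioenergy_demand_level `"baseline"` or `"1p5C"` exogenous bioenergy
#'   biomass demand trajectory.
#' @param bioenergy_demand named list with elements `baseline` and `p15`,
#'   world exogenous solid-biomass demand for energy in Mtdm yr-1 (defaults
#'   correspond to 8,300 and 15,900 Mm3 at 0.5 tdm m-3).
#' @param residue_bioenergy_committed Mtdm yr-1 of crop residues committed to
#'   existing bioenergy uses (about 16 EJ yr-1 at 18 GJ tdm-1).
#' @param dirichlet_concentration concentration of the Dirichlet split of land
#'   areas across regions; larger values give more even areas.
#' @return an object of class `world_config` (a validated list).
#' @export
world_config <- function(n_regions = 10L,
                         seed = 1L,
                         global_cropland = 900 / 0.53,
                         global_pasture = 1100 / 0.60,
                         coefficient_ranges = list(
                           soc_crop    = c(0.4, 0.8),
                           soc_pasture = c(0.4, 0.8),
                           biochar     = c(1.7, 2.5)
                         ),
                         bioenergy_demand_level = c("baseline", "1p5C"),
                         bioenergy_demand = list(baseline = 4150, p15 = 7950),
                         residue_bioenergy_committed = 890,
                         dirichlet_concentration = 3) {
  bioenergy_demand_level <- match.arg(bioenergy_demand_level)
  if (!is.numeric(n_regions) || length(n_regions) != 1 || n_regions < 1)
    stop("configuration error: n_regions must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(global_cropland) || global_cropland <= 0 ||
      !is.numeric(global_pasture) || global_pasture <= 0)
    stop("configuration error: global land areas must be positive", call. = FALSE)
  for (op in COEF_OPTIONS) {
    r <- coefficient_ranges[[op]]
    if (is.null(r) || length(r) != 2 || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2])
      stop(sprintf("configuration error: coefficient range for '%s' must be positive, finite, ordered", op),
           call. = FALSE)
  }
  if (dirichlet_concentration <= 0)
    stop("configuration error: dirichlet_concentration must be positive", call. = FALSE)
  structure(list(
    n_regions = as.integer(n_regions),
    seed = as.integer(seed),
    global_cropland = as.numeric(global_cropland),
    global_pasture = as.numeric(global_pasture),
    coefficient_ranges = lapply(coefficient_ranges[COEF_OPTIONS], as.numeric),
    bioenergy_demand_level = bioenergy_demand_level,
    bioenergy_demand = lapply(bioenergy_demand, as.numeric),
    residue_bioenergy_committed = as.numeric(residue_bioenergy_committed),
    dirichlet_concentration = as.numeric(dirichlet_concentration)
  ), class = "world_config")
}

# latitude-band archetype per region group; ASIA mixes tropical and temperate
band_for_group <- function(group) {
  switch(group,
    AFR = "tropical", LAM = "tropical", OTHER_SOUTH = "tropical",
    ASIA = sample(c("tropical", "temperate"), 1),
    NORTH = sample(c("temperate", "boreal"), 1, prob = c(0.7, 0.3))
  )
}

# one region-year of monthly climate for a latitude-band archetype with
# additive noise; ordering t_min <= t_mean <= t_max holds by construction
gen_climate <- function(region_id, band) {
  m <- 1:12
  phase <- 2 * pi * (m - 4) / 12
  base <- switch(band,
    tropical  = list(mat = stats::runif(1, 22, 27), amp = stats::runif(1, 1, 3),
                     prec = 140, prec_amp = 90, rad = 16, rad_amp = 3, diurnal = 9),
    temperate = list(mat = stats::runif(1, 6, 12), amp = stats::runif(1, 8, 11),
                     prec = 70, prec_amp = 25, rad = 12, rad_amp = 7, diurnal = 10),
    boreal    = list(mat = stats::runif(1, -2, 4), amp = stats::runif(1, 12, 16),
                     prec = 50, prec_amp = 20, rad = 10, rad_amp = 8, diurnal = 9)
  )
  t_mean <- base$mat + base$amp * sin(phase) + stats::rnorm(12, 0, 0.4)
  spread_lo <- base$diurnal / 2 + abs(stats::rnorm(12, 0, 0.5))
  spread_hi <- base$diurnal / 2 + abs(stats::rnorm(12, 0, 0.5))
  t_min <- t_mean - spread_lo
  t_max <- t_mean + spread_hi
  precipitation <- pmax(5, base$prec + base$prec_amp * sin(phase) + stats::rnorm(12, 0, 15))
  solar_radiation <- pmax(1, base$rad + base$rad_amp * sin(phase) + stats::rnorm(12, 0, 0.8))
  frost_days <- clamp(round((2 - t_min) * 3), 0, DAYS_IN_MONTH)
  vpd <- pmax(0.05, 0.12 * pmax(t_max, 1) * stats::runif(12, 0.5, 0.9))
  data.frame(region = region_id, month = m,
             t_min = t_min, t_max = t_max, t_mean = t_mean,
             precipitation = precipitation, solar_radiation = solar_radiation,
             frost_days = as.numeric(frost_days), vpd = vpd,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic world
#'
#' Draws a reproducible set of world regions: land areas split by a Dirichlet
#' allocation, production and emission intensities, a monthly climatology per
#' latitude-band archetype, soil attributes, and per-region sequestration
#' coefficients uniform within the configured ranges.
#'
#' @param config a [world_config()] object.
#' @return an object of class `agri_world`: a list of data.frames `regions`,
#'   `climate`, `soil`, `coefficients`, plus the `config`.
#' @export
generate_world <- function(config) {
  if (!inherits(config, "world_config")) config <- do.call(world_config, config)
  n <- config$n_regions
  with_seed(config$seed, {
    ids <- sprintf("R%02d", seq_len(n))
    groups <- rep_len(REGION_GROUPS, n)

    # Dirichlet area shares via normalized gamma draws; sums are exact up to
    # floating summation, which satisfies the 1e-6 relative conservation bound
    share_crop <- stats::rgamma(n, shape = config$dirichlet_concentration)
    share_crop <- share_crop / sum(share_crop)
    share_past <- stats::rgamma(n, shape = config$dirichlet_concentration)
    share_past <- share_past / sum(share_past)
    cropland_area <- share_crop * config$global_cropland
    pasture_area <- share_past * config$global_pasture

    crop_yield <- stats::runif(n, 2, 4)                  # t dm ha-1 yr-1
    crop_production <- cropland_area * crop_yield        # Mt dm yr-1
    grazing_yield <- stats::runif(n, 1, 3)               # t dm ha-1 yr-1
    livestock_output <- pasture_area * stats::runif(n, 0.2, 0.5) # index units

    n2o_intensity <- stats::runif(n, 3e-4, 7e-4)         # tN2O per t crop
    ch4_intensity <- stats::runif(n, 0.03, 0.06)         # tCH4 per livestock unit
    gdp_mean <- c(AFR = 1500, LAM = 5000, ASIA = 3500, NORTH = 28000,
                  OTHER_SOUTH = 4000)[groups]
    gdp_per_capita <- gdp_mean * exp(stats::rnorm(n, 0, 0.25))
    rpr <- stats::runif(n, 1.0, 1.8)                     # residue-product ratio
    crop_price <- stats::runif(n, 120, 200)              # USD2000 per t dm
    livestock_price <- stats::runif(n, 1200, 2000)       # USD2000 per index unit
    residue_base_cost <- 45                              # USD2000 per tdm, reference

    regions <- data.frame(
      id = ids, group = groups,
      cropland_area = cropland_area, pasture_area = pasture_area,
      crop_production = crop_production, livestock_output = livestock_output,
      crop_yield = crop_yield, grazing_yield = grazing_yield,
      n2o_intensity = n2o_intensity, ch4_intensity = ch4_intensity,
      gdp_per_capita = gdp_per_capita, rpr = rpr,
      crop_price = crop_price, livestock_price = livestock_price,
      residue_base_cost = residue_base_cost,
      stringsAsFactors = FALSE)
    rownames(regions) <- NULL

    climate <- do.call(rbind, lapply(seq_len(n), function(i)
      gen_climate(ids[i], band_for_group(groups[i]))))

    soil <- data.frame(
      region = ids,
      max_asw = stats::runif(n, 100, 300),
      fertility_rating = stats::runif(n, 0.3, 0.9),
      soc_stock = stats::runif(n, 30, 80),
      n_stock = stats::runif(n, 2, 8),
      stringsAsFactors = FALSE)

    coefficients <- do.call(rbind, lapply(COEF_OPTIONS, function(op) {
      r <- config$coefficient_ranges[[op]]
      data.frame(region = ids, option = op,
                 seq_coeff = stats::runif(n, r[1], r[2]),
                 stringsAsFactors = FALSE)
    }))
    rownames(coefficients) <- NULL

    world <- structure(list(regions = regions, climate = climate, soil = soil,
                            coefficients = coefficients, config = config),
                       class = "agri_world")
    validate_world(world)
    world
  })
}

#' @export
print.agri_world <- function(x, ...) {
  cat(sprintf("<agri_world> %d regions | cropland %.0f Mha | pasture %.0f Mha | seed %d\n",
              nrow(x$regions), sum(x$regions$cropland_area),
              sum(x$regions$pasture_area), x$config$seed))
  invisible(x)
}

# invariant checks shared by the generator and the reader
validate_world <- function(world, files = NULL) {
  f <- function(tab) files[[tab]] %||% paste0(tab, ".csv")
  r <- world$regions
  if (nrow(r) == 0) stop("world has no regions", call. = FALSE)
  check_nonneg(r, c("cropland_area", "pasture_area", "crop_production",
                    "livestock_output", "n2o_intensity", "ch4_intensity",
                    "gdp_per_capita"), f("regions"))
  bad <- which(!r$group %in% REGION_GROUPS)
  if (length(bad)) stop_parse(f("regions"), bad[1], "group", "unknown region group")
  cl <- world$climate
  check_nonneg(cl, c("precipitation", "solar_radiation", "frost_days", "vpd"),
               f("climate"))
  bad <- which(cl$t_min > cl$t_mean | cl$t_mean > cl$t_max)
  if (length(bad)) stop_parse(f("climate"), bad[1], "t_mean",
                              "temperature ordering t_min <= t_mean <= t_max violated")
  bad <- which(cl$frost_days > DAYS_IN_MONTH[cl$month])
  if (length(bad)) stop_parse(f("climate"), bad[1], "frost_days",
                              "more frost days than days in month")
  so <- world$soil
  check_nonneg(so, c("max_asw", "fertility_rating", "soc_stock", "n_stock"), f("soil"))
  bad <- which(so$fertility_rating > 1)
  if (length(bad)) stop_parse(f("soil"), bad[1], "fertility_rating", "must lie in [0, 1]")
  co <- world$coefficients
  check_nonneg(co, "seq_coeff", f("coefficients"))
  invisible(world)
}

#' Serialize / read a synthetic world
#'
#' `write_world()` writes the four world tables as CSV plus the configuration
#' as YAML into a directory; floats carry 17 significant digits so that
#' `read_world(write_world(w)) == w` bit-for-bit. `read_world()` validates all
#' invariants and raises a parse error naming file, row and column on
#' malformed input.
#'
#' @param world an `agri_world` object.
#' @param path directory to write into (created if missing).
#' @return `write_world()` returns `path` invisibly; `read_world()` returns
#'   the reconstructed `agri_world`.
#' @export
write_world <- function(world, path) {
  stopifnot(inherits(world, "agri_world"))
  if (nrow(world$regions) == 0) stop("refusing to write an empty world", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_table_full(world$regions, file.path(path, "regions.csv"))
  write_table_full(world$climate, file.path(path, "climate.csv"))
  write_table_full(world$soil, file.path(path, "soil.csv"))
  write_table_full(world$coefficients, file.path(path, "coefficients.csv"))
  cfg <- unclass(world$config)
  writeLines(yaml::as.yaml(cfg, precision = 17L), file.path(path, "config.yml"))
  invisible(path)
}

read_world_table <- function(path, name, cols) {
  file <- file.path(path, paste0(name, ".csv"))
  if (!file.exists(file)) stop(sprintf("%s: file not found", file), call. = FALSE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", file, paste(missing, collapse = ", ")),
         call. = FALSE)
  df
}

#' @rdname write_world
#' @export
read_world <- function(path) {
  regions <- read_world_table(path, "regions",
    c("id", "group", "cropland_area", "pasture_area", "crop_production",
      "livestock_output", "crop_yield", "grazing_yield", "n2o_intensity",
      "ch4_intensity", "gdp_per_capita", "rpr", "crop_price",
      "livestock_price", "residue_base_cost"))
  if (nrow(regions) == 0)
    stop(sprintf("%s: empty region list", file.path(path, "regions.csv")), call. = FALSE)
  climate <- read_world_table(path, "climate",
    c("region", "month", "t_min", "t_max", "t_mean", "precipitation",
      "solar_radiation", "frost_days", "vpd"))
  soil <- read_world_table(path, "soil",
    c("region", "max_asw", "fertility_rating", "soc_stock", "n_stock"))
  coefficients <- read_world_table(path, "coefficients",
    c("region", "option", "seq_coeff"))
  cfg <- yaml::read_yaml(file.path(path, "config.yml"))
  config <- world_config(
    n_regions = cfg$n_regions, seed = cfg$seed,
    global_cropland = cfg$global_cropland, global_pasture = cfg$global_pasture,
    coefficient_ranges = cfg$coefficient_ranges,
    bioenergy_demand_level = cfg$bioenergy_demand_level,
    bioenergy_demand = cfg$bioenergy_demand,
    residue_bioenergy_committed = cfg$residue_bioenergy_committed,
    dirichlet_concentration = cfg$dirichlet_concentration)
  world <- structure(list(regions = regions, climate = climate, soil = soil,
                          coefficients = coefficients, config = config),
                     class = "agri_world")
  files <- list(regions = file.path(path, "regions.csv"),
                climate = file.path(path, "climate.csv"),
                soil = file.path(path, "soil.csv"),
                coefficients = file.path(path, "coefficients.csv"))
  validate_world(world, files = files)
  world
}

# convenience accessors used throughout the downstream modules
region_climate <- function(world, region_id) {
  cl <- world$climate[world$climate$region == region_id, ]
  cl[order(cl$month), ]
}

region_soil <- function(world, region_id) {
  as.list(world$soil[world$soil$region == region_id, ])
}

region_coeff <- function(world, region_id, option) {
  co <- world$coefficients
  co$seq_coeff[co$region == region_id & co$option == option]
}
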
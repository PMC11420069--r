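# Profit-maximising, myopic (recursive-dynamic) adoption of sequestration
# options under a linearly increasing GHG price. Adoption of a technology
# moves a share `a` of the land type into the practice at quadratic cost
# C(a) = c1 a + (s/2) a^2 per hectare, so the interior optimum satisfies
# MC(a*) = c1 + s a* = marginal revenue (GHG price x sequestration rate +
# valued co-benefits). The cost-curve slope is calibrated so a stated price
# yields a stated adoption share. Adoption is irreversible and enters the
# vintage ledger; biochar adoption is additionally bounded by the feedstock
# market.

#' GHG price trajectory
#'
#' Zero before the start year, rising linearly to the endpoint at the end
#' year, and continuing on the same linear path afterwards when an extended
#' horizon is evaluated.
#'
#' @param endpoint price reached at `end_year`, USD2000 tCO2e-1.
#' @param start_year,end_year ramp years (defaults 2030 and 2050).
#' @return function of `year` returning the price, USD2000 tCO2e-1.
#' @export
price_trajectory <- function(endpoint, start_year = 2030, end_year = 2050) {
  stopifnot(endpoint >= 0, end_year > start_year)
  function(year) {
    ifelse(year < start_year, 0,
           endpoint * (year - start_year) / (end_year - start_year))
  }
}

#' Quadratic adoption cost
#'
#' `C(a) = c1 a + (s/2) a^2` USD2000 per land-type hectare at adoption share
#' `a`; marginal cost `c1 + s a`.
#'
#' @param option one-row slice of an option catalog (fields `c1`, `slope`).
#' @param a adoption share in \[0, 1\].
#' @return cost, USD2000 per hectare of the land type.
#' @export
adoption_cost <- function(option, a) {
  if (any(a < 0 | a > 1)) stop("adoption share outside [0, 1]", call. = FALSE)
  option$c1 * a + option$slope / 2 * a^2
}

#' Optimal adoption share at a GHG price
#'
#' Maximises `price * seq_coeff * a + v * a - C(a)` over `a` in
#' `[0, max_share]`: the interior solution is
#' `a* = (price * seq_coeff + v - c1) / s`, clipped to the feasible range.
#' A zero slope with positive net marginal revenue yields the corner
#' `max_share`.
#'
#' @param option one-row catalog slice (`seq_coeff`, `c1`, `slope`,
#'   `max_share`).
#' @param ghg_price GHG price, USD2000 tCO2e-1 (>= 0).
#' @param co_benefit_value valued co-benefits, USD2000 ha-1 yr-1.
#' @return optimal adoption share `a*`.
#' @export
optimal_adoption <- function(option, ghg_price, co_benefit_value = 0) {
  stopifnot(ghg_price >= 0)
  net <- ghg_price * option$seq_coeff + co_benefit_value - option$c1
  if (option$slope <= 0) {
    return(if (net > 0) option$max_share else 0)
  }
  clamp(net / option$slope, 0, option$max_share)
}

#' Calibrate the adoption cost-curve slope
#'
#' Chooses the slope `s` so that [optimal_adoption()] at the calibration
#' price returns the target share: `s = (price * seq_coeff + v - c1) /
#' target_share` when the solution is interior. Errors if net marginal
#' revenue at the calibration price is non-positive (no slope can attain the
#' target).
#'
#' @param option one-row catalog slice.
#' @param target_share adoption share to attain, in `(0, max_share]`.
#' @param calib_price calibration GHG price, USD2000 tCO2-1 (default 100).
#' @param co_benefit_value valued co-benefits used both here and at re-solve.
#' @return slope `s`, USD2000 per hectare per unit share.
#' @export
calibrate_slope <- function(option, target_share, calib_price = 100,
                            co_benefit_value = 0) {
  if (target_share <= 0 || target_share > option$max_share)
    stop("target share must lie in (0, max_share]", call. = FALSE)
  if (calib_price <= 0) stop("calibration price must be positive", call. = FALSE)
  net <- calib_price * option$seq_coeff + co_benefit_value - option$c1
  if (net <= 0)
    stop("calibration infeasible: net marginal revenue <= 0 at the calibration price",
         call. = FALSE)
  net / target_share
}

# value of the yield co-benefit, USD2000 per hectare per year: annual percent
# yield gain (k x seq rate) on the region's crop revenue, accumulated over the
# saturation horizon and annualized (mean cumulated gain = (T + 1) / 2 years)
co_benefit_value <- function(region_row, option_row) {
  if (option_row$yield_k <= 0) return(0)
  gain_pct <- option_row$yield_k * option_row$seq_coeff
  region_row$crop_price * region_row$crop_yield * gain_pct / 100 *
    (option_row$saturation_years + 1) / 2
}

#' Calibrate every region's SOC cost curves
#'
#' Fits the cropland SOC slope to 90% and the pasture SOC slope to 60%
#' adoption at 100 USD2000 tCO2-1, holding each region's valued yield
#' co-benefit fixed, and stores the implied co-benefit value on the catalog.
#'
#' @param world an `agri_world`.
#' @param catalogs named list of [build_catalog()] outputs per region.
#' @param calib_price calibration price, USD2000 tCO2-1.
#' @return the catalogs with `slope` and `co_benefit` columns filled.
#' @export
calibrate_catalogs <- function(world, catalogs, calib_price = 100) {
  targets <- c(soc_crop = MAX_SHARE_SOC_CROP, soc_pasture = MAX_SHARE_SOC_PASTURE)
  for (rid in names(catalogs)) {
    cat <- catalogs[[rid]]
    reg <- world$regions[world$regions$id == rid, ]
    cat$co_benefit <- vapply(seq_len(nrow(cat)), function(i)
      co_benefit_value(reg, cat[i, ]), numeric(1))
    for (op in names(targets)) {
      i <- which(cat$option == op)
      cat$slope[i] <- calibrate_slope(cat[i, ], targets[[op]], calib_price,
                                      cat$co_benefit[i])
    }
    catalogs[[rid]] <- cat
  }
  catalogs
}

# ---- model state and the recursive-dynamic period step ----------------------

#' Assemble a runnable model
#'
#' Builds rotations, catalogs (calibrated) and an empty vintage ledger for a
#' world under one scenario configuration.
#'
#' @param world an `agri_world`.
#' @param scenario a [scenario_config()].
#' @param bc_params a [biochar_params()] object.
#' @return list of class `agri_model`.
#' @export
new_model <- function(world, scenario, bc_params = biochar_params()) {
  rotations <- simulate_all_rotations(world)
  catalogs <- lapply(world$regions$id, function(rid)
    build_catalog(world, rid, rotations))
  names(catalogs) <- world$regions$id
  catalogs <- calibrate_catalogs(world, catalogs)
  structure(list(world = world, scenario = scenario, rotations = rotations,
                 catalogs = catalogs, ledger = new_ledger(),
                 bc_params = bc_params,
                 price = price_trajectory(scenario$endpoint)),
            class = "agri_model")
}

# feedstock needed per hectare of biochar adoption, tdm ha-1 yr-1
biochar_feedstock_per_ha <- function(seq_coeff, bc_params) {
  seq_coeff / (conversion_efficiency(bc_params) * CO2_PER_C)
}

# assemble the world feedstock pool table for one period
build_pools <- function(model) {
  world <- model$world
  regs <- world$regions
  sus <- sum(regs$crop_production * regs$rpr) * model$bc_params$residue_removable
  ref_gdp <- mean(regs$gdp_per_capita)
  res_cost <- sum(residue_cost(regs$residue_base_cost, regs$gdp_per_capita,
                               ref_gdp) * regs$crop_production * regs$rpr) /
    sum(regs$crop_production * regs$rpr)
  # annualized harvest from standing 10-yr silvo systems (tree strip share)
  df <- as.data.frame(model$ledger)
  silvo_area <- sum(df$area[df$option == "silvo_bioenergy"])  # Mha
  silvo_supply <- 0
  if (silvo_area > 0) {
    harv <- vapply(model$rotations, function(r)
      r$bioenergy_10yr$harvested_biomass, numeric(1))
    silvo_supply <- silvo_area * TREE_STRIP_SHARE * mean(harv) / 10
  }
  scale <- sum(regs$cropland_area) / (900 / 0.53)  # forestry pools scale with world size
  feedstock_pools(
    source = c("crop_residues", "silvo_biomass", "logging_residues",
               "other_wood", "srp"),
    available = c(sus, silvo_supply, 300 * scale, 200 * scale, 100 * scale),
    unit_cost = c(res_cost, 30, 40, 55, 60))
}

# exogenous non-biochar demands on the feedstock market, Mtdm yr-1
exo_demands <- function(model) {
  cfg <- model$world$config
  regs <- model$world$regions
  scale <- sum(regs$cropland_area) / (900 / 0.53)
  livestock <- 0.20 * sum(regs$crop_production * regs$rpr) *
    model$bc_params$residue_removable
  bio_level <- if (model$scenario$bioenergy_level == "1p5C")
    cfg$bioenergy_demand$p15 / cfg$bioenergy_demand$baseline else 1
  bioenergy <- cfg$residue_bioenergy_committed * bio_level * scale
  list(livestock = livestock, bioenergy = bioenergy)
}

#' Advance the model by one period
#'
#' Evaluates the GHG price at `year` and, region by region, solves the
#' optimal adoption share of each option, honouring maximum shares, the
#' combined 50% silvo-pasture cap (the two silvo variants exclude each other
#' on the same hectare) and irreversibility: only increases over the current
#' adopted share enter the ledger as a new vintage. Biochar adoption is
#' additionally bounded by the feedstock the merit-order market can supply
#' after livestock and exogenous bioenergy demands, with the pyrolysis
#' byproduct credited against bioenergy demand (solved by a short fixed-point
#' loop).
#'
#' @param model an `agri_model`.
#' @param year period year.
#' @return the model with updated ledger, plus `report` (per region x option
#'   adoption and flux) and `market` (feedstock market summary) attached for
#'   the period.
#' @export
run_period <- function(model, year) {
  scen <- model$scenario
  p <- model$price(year)
  world <- model$world
  rows <- list()

  # land-based options (not feedstock limited)
  for (rid in world$regions$id) {
    cat <- model$catalogs[[rid]]
    reg <- world$regions[world$regions$id == rid, ]
    land_options <- c("soc_crop", "soc_pasture", "silvo_bioenergy", "silvo_carbon")
    for (op in land_options) {  # lexicographic id order within groups below
      o <- cat[cat$option == op, ]
      land_area <- if (o$land_type == "cropland") reg$cropland_area else reg$pasture_area
      cur_share <- if (land_area > 0)
        adopted_area(model$ledger, rid, op) / land_area else 0
      a_star <- if (scen$agco2_priced && p > 0)
        optimal_adoption(o, p, o$co_benefit) else 0
      # combined cap for the mutually exclusive silvo variants
      if (o$combine_group == "silvo") {
        group_share <- if (land_area > 0)
          adopted_area(model$ledger, rid,
                       c("silvo_bioenergy", "silvo_carbon")) / land_area else 0
        headroom <- max(0, MAX_SHARE_SILVO - group_share)
        target <- min(a_star, cur_share + headroom)
      } else target <- a_star
      new_share <- max(0, target - cur_share)
      if (new_share > 0)
        model$ledger <- add_vintage(model$ledger, rid, op, year,
                                    new_share * land_area, o$seq_coeff,
                                    o$saturation_years)
      rows[[length(rows) + 1]] <- data.frame(
        year = year, region = rid, option = op,
        share = cur_share + new_share, new_area = new_share * land_area,
        stringsAsFactors = FALSE)
    }
  }

  # biochar: desired adoption given the feedstock shadow price, then a
  # market-clearing fixed point with the bioenergy byproduct credit
  pools <- build_pools(model)
  exo <- exo_demands(model)
  df <- as.data.frame(model$ledger)
  act <- df$option == "biochar" & (year - df$adoption_year < df$saturation_years)
  existing_demand <- if (any(act))
    sum(biochar_feedstock_per_ha(df$seq_coeff[act], model$bc_params) *
          df$area[act]) else 0

  shadow <- pools$unit_cost[1]
  market <- NULL
  desired_new <- stats::setNames(numeric(nrow(world$regions)), world$regions$id)
  for (iter in 1:6) {
    for (rid in world$regions$id) {
      cat <- model$catalogs[[rid]]
      reg <- world$regions[world$regions$id == rid, ]
      o <- cat[cat$option == "biochar", ]
      cur_share <- if (reg$cropland_area > 0)
        adopted_area(model$ledger, rid, "biochar") / reg$cropland_area else 0
      a_star <- 0
      if (scen$agco2_priced && p > 0) {
        fph <- biochar_feedstock_per_ha(o$seq_coeff, model$bc_params)
        net_price <- max(0, p - model$bc_params$pyrolysis_cost)
        v <- o$co_benefit - fph * shadow  # co-benefit net of feedstock cost
        a_star <- optimal_adoption(transform(o, c1 = o$c1), net_price, v)
      }
      desired_new[rid] <- max(0, a_star - cur_share) * reg$cropland_area
    }
    fph_bar <- vapply(world$regions$id, function(rid)
      biochar_feedstock_per_ha(
        model$catalogs[[rid]]$seq_coeff[model$catalogs[[rid]]$option == "biochar"],
        model$bc_params), numeric(1))
    new_demand <- sum(desired_new * fph_bar)
    total_bc <- existing_demand + new_demand
    bio_net <- max(0, exo$bioenergy -
                     model$bc_params$energy_byproduct * total_bc)
    market <- allocate_feedstock(pools, list(livestock = exo$livestock,
                                             bioenergy = bio_net,
                                             biochar = total_bc))
    shadow <- market$shadow_price
  }
  # scale back new adoption if the market cannot serve the full demand
  avail_new <- max(0, market$served[["biochar"]] - existing_demand)
  scale_back <- if (sum(desired_new * fph_bar) > 0)
    min(1, avail_new / sum(desired_new * fph_bar)) else 0
  for (rid in world$regions$id) {
    o <- model$catalogs[[rid]]
    o <- o[o$option == "biochar", ]
    reg <- world$regions[world$regions$id == rid, ]
    new_area <- desired_new[[rid]] * scale_back
    if (new_area > 0)
      model$ledger <- add_vintage(model$ledger, rid, "biochar", year, new_area,
                                  o$seq_coeff, o$saturation_years)
    cur_share <- if (reg$cropland_area > 0)
      adopted_area(model$ledger, rid, "biochar") / reg$cropland_area else 0
    rows[[length(rows) + 1]] <- data.frame(
      year = year, region = rid, option = "biochar",
      share = cur_share, new_area = new_area, stringsAsFactors = FALSE)
  }

  report <- do.call(rbind, rows)
  report$flux <- vapply(seq_len(nrow(report)), function(i)
    annual_flux(model$ledger, year, option = report$option[i],
                region = report$region[i]), numeric(1))
  model$report <- report
  model$market <- c(market, list(year = year,
                                 biochar_feedstock = market$served[["biochar"]]))
  model
}

#' Run the full horizon
#'
#' Steps the model over the period grid, accumulating per-period reports.
#'
#' @param model an `agri_model`.
#' @param years period grid (default five-year steps 2020--2050).
#' @return the model with `reports` (all periods row-bound) and `markets`.
#' @export
run_horizon <- function(model, years = seq(2020, 2050, by = 5)) {
  reports <- list(); markets <- list()
  for (y in years) {
    model <- run_period(model, y)
    reports[[as.character(y)]] <- model$report
    markets[[as.character(y)]] <- model$market
  }
  model$reports <- do.call(rbind, reports)
  model$markets <- markets
  model$years <- years
  model
}

#' Build a marginal abatement cost curve
#'
#' Runs one full horizon per GHG price endpoint and records, per endpoint,
#' the cumulative 2020--2050 mitigation (MtCO2e) in total and per option, and
#' the annual 2050 flux. The cumulative curve is non-decreasing in the
#' endpoint; the annual 2050 curve may be non-monotone because higher prices
#' pull adoption (and hence saturation) forward.
#'
#' @param world an `agri_world`.
#' @param endpoints GHG price endpoints, USD2000 tCO2e-1 (>= 2 values).
#' @param scenario_template a [scenario_config()] whose endpoint is replaced.
#' @param years period grid.
#' @return data.frame of class `macc`: one row per endpoint with columns
#'   `endpoint`, `price_2022`, `cumulative`, `annual_2050` and
#'   `cum_<option>` decompositions.
#' @export
build_macc <- function(world, endpoints,
                       scenario_template = scenario_config("agCO2"),
                       years = seq(2020, 2050, by = 5)) {
  if (length(endpoints) < 2) stop("need at least two endpoints", call. = FALSE)
  base <- new_model(world, scenario_template)
  rows <- lapply(endpoints, function(ep) {
    model <- base
    model$scenario$endpoint <- ep
    model$price <- price_trajectory(ep)
    model$ledger <- new_ledger()
    model <- run_horizon(model, years)
    end_year <- max(years)
    by_opt <- vapply(OPTION_IDS, function(op)
      cumulative_stock(model$ledger, end_year, option = op), numeric(1))
    out <- data.frame(endpoint = ep, price_2022 = to_usd2022(ep),
                      cumulative = sum(by_opt),
                      annual_2050 = annual_flux(model$ledger, end_year))
    for (op in OPTION_IDS) out[[paste0("cum_", op)]] <- by_opt[[op]]
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("macc", "data.frame")
  out
}
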
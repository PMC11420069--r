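# Orchestration of the scenario matrix: world -> growth -> catalog ->
# adoption -> economics, with manifests and a sensitivity suite. Five
# scenario rows are runnable: 'baseline' (no prices), 'default' /
# 'default_bio' (GHG price on agricultural non-CO2 only), 'agCO2' /
# 'agCO2_bio' (price additionally subsidises CO2 removals on agricultural
# land); '_bio' variants load the 1.5 degC-compatible bioenergy demand.

SCENARIO_IDS <- c("baseline", "default", "agCO2", "default_bio", "agCO2_bio")

#' Scenario configuration
#'
#' One row of the scenario matrix: which GHG sources are priced and which
#' exogenous bioenergy demand level applies. A FOLU pricing flag is accepted
#' for interface completeness but inert (forestry responses are outside this
#' package).
#'
#' @param id scenario identifier, one of `baseline`, `default`, `agCO2`,
#'   `default_bio`, `agCO2_bio`.
#' @param endpoint GHG price endpoint in 2050, USD2000 tCO2e-1.
#' @param supply_elasticity reduced-form constant elasticity of the supply
#'   contraction under the non-CO2 tax.
#' @param folu_priced inert flag, accepted for matrix completeness.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(id = SCENARIO_IDS, endpoint = 100,
                            supply_elasticity = 0.5, folu_priced = NULL) {
  id <- match.arg(id)
  flags <- switch(id,
    baseline    = list(nonco2 = FALSE, agco2 = FALSE, bio = "baseline"),
    default     = list(nonco2 = TRUE,  agco2 = FALSE, bio = "baseline"),
    agCO2       = list(nonco2 = TRUE,  agco2 = TRUE,  bio = "baseline"),
    default_bio = list(nonco2 = TRUE,  agco2 = FALSE, bio = "1p5C"),
    agCO2_bio   = list(nonco2 = TRUE,  agco2 = TRUE,  bio = "1p5C"))
  structure(list(id = id, endpoint = endpoint,
                 nonco2_priced = flags$nonco2, agco2_priced = flags$agco2,
                 bioenergy_level = flags$bio,
                 supply_elasticity = supply_elasticity,
                 folu_priced = isTRUE(folu_priced)),
            class = "scenario_config")
}

#' The quantified scenario matrix
#'
#' @return data.frame listing the five runnable scenario rows and their
#'   pricing flags.
#' @export
scenario_matrix <- function() {
  do.call(rbind, lapply(SCENARIO_IDS, function(id) {
    s <- scenario_config(id)
    data.frame(id = id, nonco2_priced = s$nonco2_priced,
               agco2_priced = s$agco2_priced,
               bioenergy_level = s$bioenergy_level, stringsAsFactors = FALSE)
  }))
}

# order-insensitive structural hash of a config list (FNV-style on the
# canonical YAML of recursively name-sorted content)
config_hash <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v))) v <- v[order(names(v))]
      lapply(v, canon)
    } else v
  }
  s <- yaml::as.yaml(canon(unclass(x)), precision = 17L)
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- ((h * 16777619) + b) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

# reduced-form 2050 economics of a completed run versus the baseline world
scenario_economics <- function(model, year = 2050) {
  scen <- model$scenario
  world <- model$world
  kk <- conversion_constants()
  p2000 <- model$price(year)
  p2022 <- to_usd2022(p2000)
  rows <- list()
  for (rid in world$regions$id) {
    reg <- world$regions[world$regions$id == rid, ]
    cat <- model$catalogs[[rid]]
    share <- function(op) {
      la <- if (op %in% c("soc_crop", "biochar")) reg$cropland_area else reg$pasture_area
      if (la > 0) adopted_area(model$ledger, rid, op) / la else 0
    }
    # crops: tax-driven supply contraction plus cumulated SOC yield co-benefit
    tax_unit_crp <- p2000 * reg$n2o_intensity * kk$gwp_n2o
    contract_crp <- if (scen$nonco2_priced && p2000 > 0)
      (1 + tax_unit_crp / reg$crop_price)^(-scen$supply_elasticity) else 1
    soc <- cat[cat$option == "soc_crop", ]
    yield_gain <- share("soc_crop") *
      yield_co_benefit(reg$group, soc$seq_coeff) / 100 *
      min(10, soc$saturation_years)   # mean cumulated years of gain
    q_crp <- reg$crop_production * contract_crp * (1 + yield_gain)
    # livestock: contraction plus the grazing penalty of tree strips
    tax_unit_lsp <- p2000 * reg$ch4_intensity * kk$gwp_ch4
    contract_lsp <- if (scen$nonco2_priced && p2000 > 0)
      (1 + tax_unit_lsp / reg$livestock_price)^(-scen$supply_elasticity) else 1
    silvo_share <- share("silvo_bioenergy") + share("silvo_carbon")
    q_lsp <- reg$livestock_output * contract_lsp *
      (1 - TREE_STRIP_SHARE * silvo_share)

    emis_crp <- q_crp * reg$n2o_intensity * kk$gwp_n2o / 1000     # GtCO2e
    emis_lsp <- q_lsp * reg$ch4_intensity * kk$gwp_ch4 / 1000
    tax_crp <- if (scen$nonco2_priced) emis_crp * p2022 else 0
    tax_lsp <- if (scen$nonco2_priced) emis_lsp * p2022 else 0
    rem_crp <- annual_flux(model$ledger, year, region = rid,
                           option = c("soc_crop", "biochar")) / 1000
    rem_lsp <- annual_flux(model$ledger, year, region = rid,
                           option = c("soc_pasture", "silvo_bioenergy",
                                      "silvo_carbon")) / 1000
    sub_crp <- if (scen$agco2_priced) rem_crp * p2022 else 0
    sub_lsp <- if (scen$agco2_priced) rem_lsp * p2022 else 0
    to_bil <- kk$usd2000_to_usd2022 / 1000   # million USD2000 -> billion USD2022
    rows[[rid]] <- data.frame(
      scenario = scen$id, region = rid, sector = c("crop", "livestock"),
      turnover = c(reg$crop_price * (q_crp - reg$crop_production) * to_bil,
                   reg$livestock_price * (q_lsp - reg$livestock_output) * to_bil),
      tax = c(tax_crp, tax_lsp), subsidy = c(sub_crp, sub_lsp),
      stringsAsFactors = FALSE)
  }
  net_positions(do.call(rbind, rows))
}

# area-under-MACC resource cost of realized adoption, billion USD2022
scenario_macc_cost <- function(model) {
  world <- model$world
  total <- 0
  for (rid in world$regions$id) {
    cat <- model$catalogs[[rid]]
    reg <- world$regions[world$regions$id == rid, ]
    for (i in seq_len(nrow(cat))) {
      o <- cat[i, ]
      la <- if (o$land_type == "cropland") reg$cropland_area else reg$pasture_area
      if (la <= 0) next
      share <- adopted_area(model$ledger, rid, o$option) / la
      total <- total + macc_area_cost(o, min(share, 1), la)
    }
  }
  total * conversion_constants()$usd2000_to_usd2022 / 1000
}

#' Run one scenario end to end
#'
#' Generates (or accepts) a world, simulates rotations, builds and calibrates
#' the option catalogs, steps the adoption market over the horizon, computes
#' the 2050 economics ledger, and optionally serializes period reports and a
#' run manifest.
#'
#' @param config a [world_config()] or an already generated `agri_world`.
#' @param scenario_id scenario identifier (see [scenario_matrix()]).
#' @param endpoint GHG price endpoint, USD2000 tCO2e-1.
#' @param years period grid.
#' @param out_dir optional output directory for CSV reports and the JSON
#'   manifest.
#' @return list of class `scenario_run`: `model` (with ledger and reports),
#'   `economics` (2050 ledger), `macc_cost`, `net_option_revenue`,
#'   `manifest`.
#' @export
run_scenario <- function(config, scenario_id, endpoint = 100,
                         years = seq(2020, 2050, by = 5), out_dir = NULL) {
  if (!scenario_id %in% SCENARIO_IDS)
    stop("unknown scenario id '", scenario_id, "'; valid: ",
         paste(SCENARIO_IDS, collapse = ", "), call. = FALSE)
  world <- if (inherits(config, "agri_world")) config else generate_world(config)
  scen <- scenario_config(scenario_id, endpoint = endpoint)
  model <- run_horizon(new_model(world, scen), years)
  economics <- scenario_economics(model, max(years))
  cost <- scenario_macc_cost(model)
  nor <- net_option_revenue(max(0, sum(economics$subsidy)), cost)
  manifest <- list(scenario = scenario_id, endpoint = endpoint,
                   seed = world$config$seed,
                   config_hash = config_hash(world$config),
                   years = years, outputs = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, c("periods.csv", "ledger.csv", "economics.csv"))
    write_table_full(model$reports, paths[1])
    write_table_full(as.data.frame(model$ledger), paths[2])
    write_table_full(as.data.frame(economics), paths[3])
    manifest$outputs <- paths
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(model = model, economics = economics, macc_cost = cost,
                 net_option_revenue = nor, manifest = manifest),
            class = "scenario_run")
}

# pure transforms of a built model implementing the sensitivity cases
apply_perturbation <- function(model, which) {
  w <- model$world
  adj_sat <- function(cat, d) {
    i <- cat$option %in% c("soc_crop", "soc_pasture", "silvo_bioenergy",
                           "silvo_carbon")
    cat$saturation_years[i] <- pmax(1L, cat$saturation_years[i] + d)
    cat
  }
  switch(which,
    "C-SEQ+" = { model$catalogs <- lapply(model$catalogs, adj_sat, d = 10L); model },
    "C-SEQ-" = { model$catalogs <- lapply(model$catalogs, adj_sat, d = -10L); model },
    "COST+"  = {
      model$catalogs <- lapply(model$catalogs, function(cat) {
        cat$c1 <- 2 * cat$c1; cat$slope <- 2 * cat$slope; cat })
      model
    },
    "DIET"   = {
      i <- w$regions$group == "NORTH"
      w$regions$livestock_output[i] <- 0.7 * w$regions$livestock_output[i]
      w$regions$pasture_area[i] <- 0.7 * w$regions$pasture_area[i]
      model$world <- w; model
    },
    "BIO+"   = { model$scenario$bioenergy_level <- "1p5C"; model },
    "TREE 20%" = ,
    "TREE 15%" = {
      frac <- if (which == "TREE 20%") 0.20 else 0.15
      model$catalogs <- lapply(model$catalogs, function(cat) {
        i <- cat$option %in% c("silvo_bioenergy", "silvo_carbon")
        cat$seq_coeff[i] <- cat$seq_coeff[i] * frac / TREE_STRIP_SHARE
        cat })
      model
    },
    "MAX 75%" = ,
    "MAX 50%" = {
      f <- if (which == "MAX 75%") 0.75 else 0.50
      model$catalogs <- lapply(model$catalogs, function(cat) {
        cat$max_share <- f * cat$max_share; cat })
      model
    },
    stop("unknown perturbation id '", which, "'", call. = FALSE))
}

#' Sensitivity suite
#'
#' Re-runs the scenario under pure configuration transforms: longer/shorter
#' sequestration (`C-SEQ+`/`C-SEQ-`, +/- 10 saturation years for SOC and
#' silvo options), doubled adoption costs (`COST+`), reduced Western
#' livestock demand (`DIET`, -30%), 1.5 degC bioenergy demand (`BIO+`),
#' reduced tree strips (`TREE 20%`, `TREE 15%`) and halved or
#' three-quarter adoption caps (`MAX 75%`, `MAX 50%`). Reports cumulative
#' 2020--2050 mitigation relative to the unperturbed run.
#'
#' @param config a [world_config()] or `agri_world`.
#' @param which character vector of perturbation identifiers.
#' @param scenario_id,endpoint,years as in [run_scenario()].
#' @return data.frame: `perturbation`, `cumulative` (MtCO2e),
#'   `rel_change` versus the base run.
#' @export
sensitivity_suite <- function(config, which,
                              scenario_id = "agCO2", endpoint = 100,
                              years = seq(2020, 2050, by = 5)) {
  world <- if (inherits(config, "agri_world")) config else generate_world(config)
  scen <- scenario_config(scenario_id, endpoint = endpoint)
  base_model <- new_model(world, scen)
  base_run <- run_horizon(base_model, years)
  base_cum <- cumulative_stock(base_run$ledger, max(years))
  rows <- lapply(which, function(wid) {
    pert <- run_horizon(apply_perturbation(base_model, wid), years)
    cum <- cumulative_stock(pert$ledger, max(years))
    data.frame(perturbation = wid, cumulative = cum,
               rel_change = cum / base_cum - 1, stringsAsFactors = FALSE)
  })
  out <- rbind(data.frame(perturbation = "base", cumulative = base_cum,
                          rel_change = 0, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  attr(out, "base_model") <- base_model
  out
}
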
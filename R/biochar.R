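# Crop residue supply accounting and the biochar production chain. Feedstock
# carbon passes through pyrolysis: 45% carbon content per ton of dry biomass,
# half of that carbon retained in the char, and 79.6% of the retained carbon
# stored beyond 100 years once applied to soil, giving ~0.18 tCe of durable
# biochar carbon per tdm of input. Half of the feedstock energy content comes
# back as a bioenergy byproduct. Biochar competes for feedstock with
# livestock uses and exogenous bioenergy demand on a merit-order market.

#' Biochar chain parameters
#'
#' @param carbon_content carbon fraction of dry biomass feedstock, tC tdm-1.
#' @param retention fraction of feedstock carbon retained in the char.
#' @param storage_100yr fraction of retained carbon stored beyond 100 years.
#' @param pyrolysis_cost pyrolysis, storage, processing and application cost,
#'   USD2000 per tCO2e sequestered.
#' @param energy_byproduct fraction of feedstock available as bioenergy
#'   byproduct of pyrolysis.
#' @param residue_removable sustainably removable fraction of the technical
#'   crop residue potential.
#' @return a validated list of class `biochar_params`.
#' @export
biochar_params <- function(carbon_content = 0.45, retention = 0.50,
                           storage_100yr = 0.796, pyrolysis_cost = 35,
                           energy_byproduct = 0.50, residue_removable = 0.50) {
  fr <- c(carbon_content, retention, storage_100yr, energy_byproduct,
          residue_removable)
  if (any(fr <= 0) || any(fr > 1))
    stop("biochar chain fractions must lie in (0, 1]", call. = FALSE)
  if (pyrolysis_cost < 0) stop("pyrolysis cost must be >= 0", call. = FALSE)
  structure(list(carbon_content = carbon_content, retention = retention,
                 storage_100yr = storage_100yr, pyrolysis_cost = pyrolysis_cost,
                 energy_byproduct = energy_byproduct,
                 residue_removable = residue_removable),
            class = "biochar_params")
}

#' Crop residue potential
#'
#' Technical potential is production times the crop-specific residue-product
#' ratio, summed over crops; the sustainable potential is the removable
#' fraction (default 50%) of the technical potential.
#'
#' @param production crop production per crop aggregate, Mt dm yr-1.
#' @param rpr residue-product ratio per crop aggregate.
#' @param removable sustainably removable fraction.
#' @return list `technical` and `sustainable`, Mtdm yr-1.
#' @export
residue_potential <- function(production, rpr, removable = 0.50) {
  stopifnot(all(production >= 0), all(rpr >= 0), length(production) == length(rpr))
  technical <- sum(production * rpr)
  list(technical = technical, sustainable = removable * technical)
}

#' Residue recovery cost rescaled by GDP per capita
#'
#' Baling, recovery and transportation costs are scaled across regions in
#' proportion to GDP per capita relative to a reference region.
#'
#' @param base_cost reference-region cost, USD2000 tdm-1.
#' @param gdp_per_capita region GDP per capita, USD2000.
#' @param reference_gdp reference GDP per capita, USD2000 (> 0).
#' @return cost, USD2000 tdm-1.
#' @export
residue_cost <- function(base_cost, gdp_per_capita, reference_gdp) {
  if (!is.numeric(reference_gdp) || reference_gdp <= 0)
    stop("reference GDP must be positive", call. = FALSE)
  stopifnot(base_cost >= 0, gdp_per_capita > 0)
  base_cost * gdp_per_capita / reference_gdp
}

#' Biochar carbon conversion efficiency
#'
#' The product of carbon content, retention and 100-year storage fractions:
#' tCe of durably stored biochar carbon per tdm of biomass input. The full
#' precision value is used internally; `display = TRUE` rounds to two
#' decimals as conventionally reported.
#'
#' @param params a [biochar_params()] object.
#' @param display round to two decimals.
#' @return conversion efficiency, tCe tdm-1.
#' @export
conversion_efficiency <- function(params = biochar_params(), display = FALSE) {
  eff <- params$carbon_content * params$retention * params$storage_100yr
  if (display) round(eff, 2) else eff
}

#' Pyrolyze feedstock into biochar
#'
#' @param feedstock biomass input, Mtdm yr-1 (>= 0).
#' @param params a [biochar_params()] object.
#' @return list: `stored_c` (MtC of durable biochar carbon), `seq` (MtCO2e),
#'   `bioenergy_byproduct` (Mtdm-equivalent), `cost` (million USD2000).
#' @export
pyrolyze <- function(feedstock, params = biochar_params()) {
  stopifnot(feedstock >= 0)
  stored_c <- feedstock * conversion_efficiency(params)
  seq <- stored_c * CO2_PER_C
  list(stored_c = stored_c, seq = seq,
       bioenergy_byproduct = params$energy_byproduct * feedstock,
       cost = params$pyrolysis_cost * seq)
}

#' Construct a feedstock pool table
#'
#' @param source pool identifiers (e.g. `"crop_residues"`, `"silvo_biomass"`,
#'   `"logging_residues"`, `"other_wood"`, `"srp"`).
#' @param available available quantity, Mtdm yr-1.
#' @param unit_cost supply cost, USD2000 tdm-1.
#' @return data.frame of class `feedstock_pools`.
#' @export
feedstock_pools <- function(source, available, unit_cost) {
  stopifnot(all(available >= 0), all(unit_cost >= 0))
  structure(data.frame(source = source, available = available,
                       unit_cost = unit_cost, stringsAsFactors = FALSE),
            class = c("feedstock_pools", "data.frame"))
}

#' Merit-order feedstock allocation
#'
#' Serves the competing uses in priority order (livestock, then exogenous
#' bioenergy, then biochar), always drawing from the cheapest pool with
#' remaining supply. The market-clearing shadow price is the unit cost of the
#' most expensive pool actually drawn on. Demand beyond total supply is
#' reported as a shortfall per use, never raised as an error. Because biochar
#' is served last, raising exogenous bioenergy demand can never increase the
#' feedstock reaching biochar.
#'
#' @param pools a [feedstock_pools()] table.
#' @param demands named list/vector with `livestock`, `bioenergy`, `biochar`
#'   demands, Mtdm yr-1 (>= 0).
#' @return list: `allocation` (data.frame pool x use quantities),
#'   `served` and `shortfall` (named by use), `shadow_price`
#'   (USD2000 tdm-1), `total_allocated`.
#' @export
allocate_feedstock <- function(pools, demands) {
  demands <- as.list(demands)
  uses <- c("livestock", "bioenergy", "biochar")
  d <- vapply(uses, function(u) as.numeric(demands[[u]] %||% 0), numeric(1))
  if (any(d < 0)) stop("demands must be >= 0", call. = FALSE)
  p <- as.data.frame(pools)[order(pools$unit_cost), ]
  remaining <- p$available
  alloc <- matrix(0, nrow = nrow(p), ncol = length(uses),
                  dimnames = list(p$source, uses))
  served <- stats::setNames(numeric(length(uses)), uses)
  for (u in seq_along(uses)) {
    need <- d[u]
    for (i in seq_len(nrow(p))) {
      if (need <= 0) break
      take <- min(need, remaining[i])
      alloc[i, u] <- alloc[i, u] + take
      remaining[i] <- remaining[i] - take
      need <- need - take
    }
    served[u] <- d[u] - need
  }
  used <- rowSums(alloc) > 1e-12
  shadow <- if (any(used)) max(p$unit_cost[used]) else
    if (nrow(p)) min(p$unit_cost) else 0
  allocation <- data.frame(source = rep(p$source, times = length(uses)),
                           use = rep(uses, each = nrow(p)),
                           quantity = as.vector(alloc),
                           stringsAsFactors = FALSE)
  list(allocation = allocation, served = served,
       shortfall = stats::setNames(d - served, uses),
       shadow_price = shadow, total_allocated = sum(alloc))
}
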
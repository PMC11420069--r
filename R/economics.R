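# Ex-post economics: impacts of a mitigation scenario relative to the
# baseline on producers (gross turnover change, GHG tax paid, carbon subsidy
# received) and on government budgets (tax received minus subsidy paid).
# Taxes and subsidies are pure transfers, so producer and government net
# positions sum to the turnover change.

#' Conversion constants
#'
#' Currency deflator USD2000 to USD2022 (1.63, US GDP deflator) and 100-year
#' global warming potentials of the 4th IPCC Assessment Report (298 for N2O,
#' 25 for CH4).
#'
#' @return named list of class `conversion_constants`.
#' @export
conversion_constants <- function() {
  structure(list(usd2000_to_usd2022 = 1.63, gwp_n2o = 298, gwp_ch4 = 25),
            class = "conversion_constants")
}

#' Convert gas mass to CO2 equivalents
#'
#' @param gas `"CO2"`, `"N2O"` or `"CH4"`.
#' @param amount gas mass, Mt (>= 0).
#' @param constants a [conversion_constants()] object.
#' @return MtCO2e.
#' @export
co2e <- function(gas, amount, constants = conversion_constants()) {
  stopifnot(all(amount >= 0))
  gwp <- switch(gas,
                CO2 = 1, N2O = constants$gwp_n2o, CH4 = constants$gwp_ch4,
                stop("unknown gas: ", gas, call. = FALSE))
  amount * gwp
}

#' Convert USD2000 to USD2022
#'
#' Multiplies by the uniform 1.63 deflator. `display = TRUE` additionally
#' floors to the nearest 5, the granularity at which converted GHG prices are
#' conventionally labelled (100 -> 163 -> "160"; 200 -> 326 -> "325";
#' 150 -> 244.5 -> "240").
#'
#' @param x value in USD2000.
#' @param display floor to the nearest 5 for labelling.
#' @param constants a [conversion_constants()] object.
#' @return value in USD2022.
#' @export
to_usd2022 <- function(x, display = FALSE, constants = conversion_constants()) {
  out <- constants$usd2000_to_usd2022 * x
  if (display) floor(out / 5) * 5 else out
}

#' Gross turnover change versus the baseline
#'
#' Revenue difference summed over commodities:
#' `sum(p_scn * q_scn - p_base * q_base)`. Positive values indicate a
#' producer gain.
#'
#' @param prices_scn,qty_scn scenario prices and quantities (aligned vectors,
#'   optionally named by commodity).
#' @param prices_base,qty_base baseline prices and quantities.
#' @return turnover change in the input currency units.
#' @export
turnover_change <- function(prices_scn, qty_scn, prices_base, qty_base) {
  n <- length(prices_scn)
  if (length(qty_scn) != n || length(prices_base) != n || length(qty_base) != n)
    stop("mismatched commodity lists", call. = FALSE)
  if (!is.null(names(prices_scn)) && !is.null(names(prices_base)) &&
      !identical(names(prices_scn), names(prices_base)))
    stop("mismatched commodity lists", call. = FALSE)
  sum(prices_scn * qty_scn - prices_base * qty_base)
}

#' GHG tax and carbon subsidy payments
#'
#' Tax is agricultural GHG emissions times the GHG price; subsidy is CO2
#' removals on agricultural land times the GHG price. With emissions and
#' removals in GtCO2e and the price in USD tCO2e-1 the results are in
#' billion USD.
#'
#' @param emissions agricultural GHG emissions, GtCO2e yr-1.
#' @param removals CO2 removals on agricultural land, GtCO2e yr-1.
#' @param price GHG price, USD2022 tCO2e-1.
#' @return list `tax` and `subsidy`, billion USD2022.
#' @export
tax_and_subsidy <- function(emissions, removals, price) {
  stopifnot(emissions >= 0, removals >= 0, price >= 0)
  list(tax = emissions * price, subsidy = removals * price)
}

#' Producer and government net positions
#'
#' From per-row components (turnover change, tax, subsidy; same currency
#' year) computes `net_producer = turnover - tax + subsidy` and
#' `net_government = tax - subsidy`. The two always sum to the turnover
#' change (transfer neutrality).
#'
#' @param components data.frame with columns `turnover`, `tax`, `subsidy`
#'   (billion USD2022) and any identifier columns (scenario, region, sector).
#' @return the data.frame with `net_producer` and `net_government` appended,
#'   class `economic_ledger`.
#' @export
net_positions <- function(components) {
  need <- c("turnover", "tax", "subsidy")
  missing <- setdiff(need, names(components))
  if (length(missing))
    stop("missing component column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  components$net_producer <- components$turnover - components$tax +
    components$subsidy
  components$net_government <- components$tax - components$subsidy
  class(components) <- c("economic_ledger", "data.frame")
  components
}

#' Net producer revenue from sequestration options
#'
#' Carbon subsidy revenue minus the economic cost of the practices, the cost
#' being the area under the marginal abatement cost curve up to realized
#' adoption.
#'
#' @param subsidy carbon subsidy revenue, billion USD2022 (>= 0).
#' @param macc_area_cost area under the MACC, billion USD2022 (>= 0).
#' @return net revenue, billion USD2022.
#' @export
net_option_revenue <- function(subsidy, macc_area_cost) {
  stopifnot(subsidy >= 0, macc_area_cost >= 0)
  subsidy - macc_area_cost
}

#' MACC area cost of realized adoption
#'
#' Integral under the per-option marginal adoption cost curve
#' `c1 + s a` up to the realized share, times the land-type area: the
#' resource cost of moving that share of land into the practice.
#'
#' @param option one-row catalog slice (`c1`, `slope`).
#' @param share realized adoption share.
#' @param land_area land-type area, Mha.
#' @return cost, million USD2000 yr-1.
#' @export
macc_area_cost <- function(option, share, land_area) {
  adoption_cost(option, share) * land_area
}

#' Published economic components fixture
#'
#' Global Fig.-style turnover / tax / subsidy components (billion USD2022,
#' 2050, change versus baseline) for the three reported mitigation scenario
#' variants, as packaged plain-text data for consistency tests.
#'
#' @return data.frame with columns `scenario`, `turnover`, `tax`, `subsidy`.
#' @export
published_components <- function() {
  utils::read.csv(system.file("extdata", "published_components.csv",
                              package = "agrimacc"),
                  stringsAsFactors = FALSE)
}
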
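# Technology catalog and vintage-tracked carbon-flux dynamics. Each region
# carries five option variants: SOC enhancement on cropland and on pasture,
# the two silvo-pasture systems, and biochar on cropland. Sequestration rates
# are constant per vintage until a fixed saturation horizon, after which the
# cohort's flux drops to zero (20 yr for SOC, 30 yr for biochar and the
# 30-year silvo system, 10 yr for the bioenergy silvo system's biomass
# equilibrium). Options are additive on co-adopted land: SOC + biochar on
# cropland, SOC + silvo on pasture; the two silvo variants exclude each other
# on the same hectare.

OPTION_IDS <- c("soc_crop", "soc_pasture", "silvo_bioenergy", "silvo_carbon",
                "biochar")

# maximum adoption shares of the relevant land type
MAX_SHARE_SOC_CROP <- 0.90
MAX_SHARE_SOC_PASTURE <- 0.60
MAX_SHARE_SILVO <- 0.50       # combined over the two silvo variants
SATURATION_YEARS <- c(soc_crop = 20L, soc_pasture = 20L, silvo_bioenergy = 10L,
                      silvo_carbon = 30L, biochar = 30L)

#' Build the per-region option catalog
#'
#' Assembles the five sequestration option variants for one region, wiring in
#' the SOC and biochar coefficients drawn by the world generator and the
#' silvo-pasture coefficients produced by the growth simulator. Cost
#' parameters follow the quadratic adoption-cost scheme: marginal cost
#' `c1 + s * share`, with the slope `s` left `NA` until [calibrate_slope()]
#' fixes it (SOC options) or set from the silvo cost level. The biochar
#' variant carries no area cap (`max_share = 1`): its adoption is
#' feedstock-limited through the residue market, not area-limited.
#'
#' @param world an `agri_world`.
#' @param region_id region identifier.
#' @param rotations output of [simulate_all_rotations()] (or a list with the
#'   two `rotation_result`s for this region).
#' @return data.frame of class `option_catalog`, one row per option variant:
#'   `region`, `option`, `land_type`, `seq_coeff` (tCO2e ha-1 yr-1),
#'   `saturation_years`, `max_share`, `c1`, `slope` (USD2000 ha-1), `yield_k`,
#'   `combine_group`.
#' @export
build_catalog <- function(world, region_id, rotations) {
  rot <- if (!is.null(rotations[[region_id]])) rotations[[region_id]] else rotations
  if (is.null(rot$bioenergy_10yr) || is.null(rot$carbon_30yr))
    stop("missing silvo-pasture coefficients for region ", region_id, call. = FALSE)
  reg <- world$regions[world$regions$id == region_id, ]
  grp <- reg$group
  cat <- data.frame(
    region = region_id,
    option = OPTION_IDS,
    land_type = c("cropland", "pasture", "pasture", "pasture", "cropland"),
    seq_coeff = c(region_coeff(world, region_id, "soc_crop"),
                  region_coeff(world, region_id, "soc_pasture"),
                  rot$bioenergy_10yr$annualized_seq,
                  rot$carbon_30yr$annualized_seq,
                  region_coeff(world, region_id, "biochar")),
    saturation_years = as.integer(SATURATION_YEARS[OPTION_IDS]),
    max_share = c(MAX_SHARE_SOC_CROP, MAX_SHARE_SOC_PASTURE, MAX_SHARE_SILVO,
                  MAX_SHARE_SILVO, 1.0),
    # SOC marginal-cost intercepts are zero (slope-only calibration); silvo
    # systems carry establishment/maintenance costs, the 30-yr carbon system
    # costing 8% of the bioenergy system; biochar cost is borne per tCO2e in
    # the pyrolysis chain, not per hectare.
    c1 = c(0, 0, 60, 60 * 0.08, 0),
    slope = c(NA_real_, NA_real_, 400, 150, 200),
    yield_k = c(yield_k_for_group(grp), 0, 0, 0, yield_k_for_group(grp)),
    combine_group = c("crop_soc", "pasture_soc", "silvo", "silvo", "crop_biochar"),
    stringsAsFactors = FALSE)
  class(cat) <- c("option_catalog", "data.frame")
  cat
}

yield_k_for_group <- function(group) {
  switch(group, AFR = 1.5, LAM = 1.2, ASIA = 0.7, 0)
}

#' Yield co-benefit of carbon sequestration
#'
#' Annual percent yield increase of crop aggregates per tCO2 ha-1 yr-1
#' sequestered: 1.5 in Africa, 1.2 in Latin America, 0.7 in Asia, zero
#' elsewhere.
#'
#' @param group region group (`"AFR"`, `"LAM"`, `"ASIA"`, `"NORTH"`,
#'   `"OTHER_SOUTH"`).
#' @param seq_rate sequestration rate, tCO2 ha-1 yr-1 (>= 0).
#' @return annual yield increase, percent per year.
#' @export
yield_co_benefit <- function(group, seq_rate) {
  stopifnot(seq_rate >= 0)
  yield_k_for_group(group) * seq_rate
}

#' Grazing biomass lost to tree strips
#'
#' Converting pasture to silvo-pasture plants trees on 25% of the hectare;
#' grazing biomass supply declines proportionally, with no offsetting pasture
#' productivity gain assumed.
#'
#' @param silvo_area silvo-pasture area, Mha (>= 0).
#' @param grazing_yield pasture biomass yield, t ha-1 yr-1.
#' @return lost grazing biomass supply, Mt yr-1.
#' @export
grazing_penalty <- function(silvo_area, grazing_yield) {
  stopifnot(silvo_area >= 0)
  TREE_STRIP_SHARE * grazing_yield * silvo_area
}

#' Vintage-tracked adoption ledger
#'
#' An adoption ledger records cohorts ("vintages") of land entering a
#' practice: region, option, adoption year, area and the cohort's
#' sequestration coefficient. A cohort sequesters at its constant coefficient
#' until its saturation horizon, then contributes nothing.
#'
#' @return an empty `adoption_ledger`.
#' @export
new_ledger <- function() {
  structure(data.frame(region = character(), option = character(),
                       adoption_year = integer(), area = numeric(),
                       seq_coeff = numeric(), saturation_years = integer(),
                       stringsAsFactors = FALSE),
            class = c("adoption_ledger", "data.frame"))
}

#' @rdname new_ledger
#' @param ledger an `adoption_ledger`.
#' @param region,option identifiers of the adopting region and option.
#' @param year adoption year of the new cohort.
#' @param area cohort area, Mha (>= 0).
#' @param seq_coeff cohort sequestration coefficient, tCO2e ha-1 yr-1.
#' @param saturation_years cohort saturation horizon, years.
#' @export
add_vintage <- function(ledger, region, option, year, area, seq_coeff,
                        saturation_years) {
  stopifnot(area >= 0, seq_coeff >= 0)
  if (area == 0) return(ledger)
  row <- data.frame(region = region, option = option,
                    adoption_year = as.integer(year), area = area,
                    seq_coeff = seq_coeff,
                    saturation_years = as.integer(saturation_years),
                    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(ledger), row)
  class(out) <- c("adoption_ledger", "data.frame")
  out
}

#' Annual sequestration flux of the ledger
#'
#' Sums `area * seq_coeff` over all cohorts still inside their saturation
#' horizon at `year`: a cohort adopted in year `t0` contributes while
#' `year - t0 < saturation_years` and zero afterwards.
#'
#' @param ledger an `adoption_ledger`.
#' @param year evaluation year.
#' @param option,region optional filters.
#' @return flux in MtCO2e yr-1 (Mha times tCO2e ha-1 yr-1).
#' @export
annual_flux <- function(ledger, year, option = NULL, region = NULL) {
  df <- as.data.frame(ledger)
  if (!is.null(option)) df <- df[df$option %in% option, ]
  if (!is.null(region)) df <- df[df$region %in% region, ]
  if (nrow(df) == 0) return(0)
  active <- (year - df$adoption_year >= 0) &
    (year - df$adoption_year < df$saturation_years)
  sum(df$area[active] * df$seq_coeff[active])
}

#' Cumulative sequestered stock of the ledger
#'
#' Telescoped form of the annual flux: each cohort contributes
#' `area * seq_coeff * min(max(T - t0 + 1, 0), saturation_years)` by the end
#' of year `T` (adoption-year flux counts as the first year).
#'
#' @inheritParams annual_flux
#' @export
cumulative_stock <- function(ledger, year, option = NULL, region = NULL) {
  df <- as.data.frame(ledger)
  if (!is.null(option)) df <- df[df$option %in% option, ]
  if (!is.null(region)) df <- df[df$region %in% region, ]
  if (nrow(df) == 0) return(0)
  yrs <- pmin(pmax(year - df$adoption_year + 1, 0), df$saturation_years)
  sum(df$area * df$seq_coeff * yrs)
}

# total adopted share of a land type per option/combine-group in one region
adopted_area <- function(ledger, region, options) {
  df <- as.data.frame(ledger)
  sum(df$area[df$region == region & df$option %in% options])
}
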
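# Carbon footprint of plate waste: production, transport and disposal
# emissions per category, per kg of waste, per serving, and as a share of the
# footprint of all food supplied. Aggregate category waste is decomposed
# across food items in proportion to the served item mix (the same proxy the
# nutrition stage uses), then item/category emission factors are applied.

#' Production emissions for a set of waste masses
#'
#' @param masses Data frame with columns `food_item_id`, `category`,
#'   `mass_kg`: wasted (or served) mass per item.
#' @param campaign A validated `pw_campaign` (provides the factor table;
#'   item-level rows override category-level rows).
#' @return Named numeric: production kgCO2e per category (zero-mass
#'   categories absent).
#' @export
production_emissions <- function(masses, campaign) {
  ef <- vapply(seq_len(nrow(masses)), function(i) {
    resolve_factor(campaign, masses$food_item_id[i],
                   masses$category[i])$production_ef_kgco2e_per_kg
  }, numeric(1))
  e <- masses$mass_kg * ef
  tapply(e, masses$category, sum)
}

#' Transport and disposal emissions for waste masses
#'
#' Transport covers the central-kitchen-to-school distance applied to the
#' wasted fraction of food (`mass x EF_transport x distance`); hauling to the
#' disposal site is folded into the per-kg disposal factor of the configured
#' method (`mass x EF_disposal`).
#'
#' @param masses As in [production_emissions()].
#' @param campaign A validated `pw_campaign`.
#' @param distance_km Central kitchen to school distance.
#' @param disposal_ef_kg Per-kg disposal emission factor (from
#'   the factor row of the configured disposal method).
#' @return List of two named numerics per category: `transport_kgco2e`,
#'   `disposal_kgco2e`.
#' @export
transport_and_disposal_emissions <- function(masses, campaign, distance_km,
                                             disposal_ef_kg) {
  stopifnot(distance_km >= 0, disposal_ef_kg >= 0)
  tef <- vapply(seq_len(nrow(masses)), function(i) {
    resolve_factor(campaign, masses$food_item_id[i],
                   masses$category[i])$transport_ef_kgco2e_per_kg_km
  }, numeric(1))
  list(transport_kgco2e = tapply(masses$mass_kg * tef * distance_km,
                                 masses$category, sum),
       disposal_kgco2e = tapply(masses$mass_kg * disposal_ef_kg,
                                masses$category, sum))
}

#' Average emission factor per serving
#'
#' Divides a category's total emissions by its serving count. By the
#' reporting convention for starchy food, the divisor for the starchy
#' category is the mean of the starchy and bread serving counts.
#'
#' @param total_kgco2e Category total emissions.
#' @param servings_count Number of servings (>= 1); pass the starchy/bread
#'   mean for the starchy category.
#' @return kgCO2e per serving.
#' @export
per_serving_factor <- function(total_kgco2e, servings_count) {
  if (any(servings_count < 1)) {
    pw_stop("pw_undefined_ratio", "servings_count must be >= 1")
  }
  total_kgco2e / servings_count
}

#' Waste emissions as a share of the supplied-food footprint
#'
#' @param waste_kgco2e Waste emissions in the numerator (production-related
#'   by the headline convention).
#' @param supplied_total_kgco2e Production footprint of all food supplied
#'   during the collection days (> 0).
#' @return Percent share.
#' @export
waste_share_of_supply <- function(waste_kgco2e, supplied_total_kgco2e) {
  if (any(supplied_total_kgco2e <= 0)) {
    pw_stop("pw_undefined_ratio", "supplied-food footprint must be > 0")
  }
  100 * waste_kgco2e / supplied_total_kgco2e
}

# Served and wasted item masses (kg) per category for one case, decomposing
# aggregate category waste proportionally to the served item mix.
case_item_masses <- function(campaign, case_id, accounts = NULL) {
  if (is.null(accounts)) accounts <- day_accounts(campaign)
  accounts <- accounts[accounts$case_id == case_id, , drop = FALSE]
  menus <- campaign$menus[campaign$menus$case_id == case_id, , drop = FALSE]
  m <- data.table::as.data.table(menus)
  m <- merge(m, data.table::as.data.table(
    campaign$dishes[, c("dish_id", "category")]), by = "dish_id")
  ch <- data.table::as.data.table(
    accounts[, c("date", "school_id", "category", "children")])
  m <- merge(m, ch, by = c("date", "school_id", "category"))
  r <- data.table::as.data.table(campaign$recipes)
  m <- merge(m, r, by = "dish_id", allow.cartesian = TRUE)
  served_items <- m[, list(served_kg = sum(grams_per_serving * children) / 1000),
                    by = c("category", "food_item_id")]
  cat_served <- served_items[, list(cat_served_kg = sum(served_kg)),
                             by = "category"]
  cat_waste <- data.table::as.data.table(accounts)[
    , list(waste_kg = sum(waste_g) / 1000), by = "category"]
  out <- merge(served_items, cat_served, by = "category")
  out <- merge(out, cat_waste, by = "category")
  out[, waste_item_kg := waste_kg * served_kg / cat_served_kg]
  as.data.frame(out)
}

#' Full emission account for one case
#'
#' Builds the per-category production/transport/disposal emissions of plate
#' waste, category and case totals, average emission factors per kg of waste
#' and per serving (starchy uses the starchy/bread mean serving count), the
#' production footprint of all food supplied, and the share of the supply
#' footprint embodied in waste — both the headline production-based share
#' and the all-components variant.
#'
#' @param campaign A validated `pw_campaign`.
#' @param case_id Case to account.
#' @param accounts Optional precomputed [day_accounts()].
#' @return List with `per_category` data frame, `totals`, `supply` and
#'   per-meal footprints.
#' @export
emission_account <- function(campaign, case_id, accounts = NULL) {
  if (is.null(accounts)) accounts <- day_accounts(campaign)
  acc_case <- accounts[accounts$case_id == case_id, , drop = FALSE]
  if (!nrow(acc_case)) pw_stop("pw_validation_error", "unknown case: ", case_id)
  items <- case_item_masses(campaign, case_id, accounts)
  cfg <- case_config(campaign, case_id)
  dist <- cfg$transport_distance_km
  if (is.null(dist)) pw_stop("pw_config_error", "transport_distance_km unset")
  def <- disposal_factor(campaign)

  waste_masses <- data.frame(food_item_id = items$food_item_id,
                             category = items$category,
                             mass_kg = items$waste_item_kg)
  prod <- production_emissions(waste_masses, campaign)
  td <- transport_and_disposal_emissions(waste_masses, campaign, dist, def)

  cats <- sort(unique(items$category))
  get <- function(v) ifelse(is.na(v[cats]), 0, v[cats])
  per_cat <- data.frame(
    category = cats,
    waste_kg = tapply(items$waste_item_kg, items$category, sum)[cats],
    production_kgco2e = get(prod),
    transport_kgco2e = get(td$transport_kgco2e),
    disposal_kgco2e = get(td$disposal_kgco2e))
  per_cat$total_kgco2e <- per_cat$production_kgco2e +
    per_cat$transport_kgco2e + per_cat$disposal_kgco2e
  per_cat$avg_ef_per_kg_waste <- ifelse(per_cat$waste_kg > 0,
                                        per_cat$total_kgco2e / per_cat$waste_kg,
                                        NA_real_)

  # serving counts: children served per category-day, starchy uses the
  # starchy/bread mean
  serv_counts <- tapply(acc_case$children, acc_case$category, sum)
  divisor <- vapply(cats, function(cc) {
    if (cc == "starchy" && !is.na(serv_counts["bread"])) {
      mean(c(serv_counts[["starchy"]], serv_counts[["bread"]]))
    } else serv_counts[[cc]]
  }, numeric(1))
  per_cat$servings <- divisor
  per_cat$avg_ef_per_serving <- per_serving_factor(per_cat$total_kgco2e, divisor)

  totals <- list(
    production_kgco2e = sum(per_cat$production_kgco2e),
    transport_kgco2e = sum(per_cat$transport_kgco2e),
    disposal_kgco2e = sum(per_cat$disposal_kgco2e),
    total_kgco2e = sum(per_cat$total_kgco2e),
    waste_kg = sum(per_cat$waste_kg))
  totals$avg_ef_per_kg_waste <- if (totals$waste_kg > 0) {
    totals$total_kgco2e / totals$waste_kg
  } else NA_real_

  supplied_masses <- data.frame(food_item_id = items$food_item_id,
                                category = items$category,
                                mass_kg = items$served_kg)
  supply_prod <- sum(production_emissions(supplied_masses, campaign))
  meals <- sum(tapply(acc_case$children, paste(acc_case$date, acc_case$school_id),
                      max))
  list(case_id = case_id,
       per_category = per_cat,
       totals = totals,
       supply = list(
         supplied_food_total_kgco2e = supply_prod,
         waste_share_of_supply_pct =
           waste_share_of_supply(totals$production_kgco2e, supply_prod),
         waste_share_all_components_pct =
           waste_share_of_supply(totals$total_kgco2e, supply_prod)),
       per_meal = list(
         meals = meals,
         waste_kgco2e_per_meal_production = totals$production_kgco2e / meals,
         waste_kgco2e_per_meal_all = totals$total_kgco2e / meals,
         supply_kgco2e_per_meal = supply_prod / meals))
}

case_config <- function(campaign, case_id) {
  for (cs in campaign$config$cases) {
    if (identical(cs$case_id, case_id)) return(cs)
  }
  pw_stop("pw_config_error", "case not in config: ", case_id)
}
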
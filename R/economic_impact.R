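# Economic impact of plate waste: each category gets an average cost per kg
# equal to the volume-weighted mean market price of the items served within
# it; waste cost is waste mass times that rate, summed to the case total and
# normalised per day, per kg, per meal and against budgets.

#' Volume-weighted average cost per kg of a category
#'
#' @param masses_kg Item masses procured/served within the category.
#' @param prices_eur_kg Matching per-item market prices (EUR/kg).
#' @return `sum(price * mass) / sum(mass)` in EUR/kg.
#' @export
category_cost_per_kg <- function(masses_kg, prices_eur_kg) {
  stopifnot(length(masses_kg) == length(prices_eur_kg))
  if (any(!is.finite(prices_eur_kg)) || any(prices_eur_kg < 0)) {
    pw_stop("pw_integrity_error", "prices must be finite and >= 0")
  }
  if (sum(masses_kg) <= 0) {
    pw_stop("pw_undefined_ratio", "category procured mass must be > 0")
  }
  sum(prices_eur_kg * masses_kg) / sum(masses_kg)
}

#' Cost of a category's waste
#'
#' @param category_waste_kg Waste mass (kg), >= 0.
#' @param cost_per_kg Category average cost (EUR/kg), >= 0.
#' @return EUR.
#' @export
waste_cost <- function(category_waste_kg, cost_per_kg) {
  stopifnot(all(category_waste_kg >= 0), all(cost_per_kg >= 0))
  category_waste_kg * cost_per_kg
}

#' Case-level derived cost metrics
#'
#' @param total_cost_eur Total plate-waste cost.
#' @param total_waste_kg Total waste mass (kg).
#' @param days Collection days (>= 1).
#' @param meals Lunches served during the collection days (>= 1); `NA` to
#'   skip the per-meal metrics.
#' @param full_price_eur Full meal price paid by parents; `NA` to skip.
#' @param procurement_budget_eur Food procurement budget; `NA` to skip.
#' @return List: `daily_cost_eur`, `cost_per_kg_eur`, `cost_per_meal_eur`,
#'   `share_of_full_price_pct`, `share_of_procurement_budget_pct` (the
#'   optional ones `NA` when their input is missing).
#' @export
derived_cost_metrics <- function(total_cost_eur, total_waste_kg, days,
                                 meals = NA, full_price_eur = NA,
                                 procurement_budget_eur = NA) {
  if (days < 1) pw_stop("pw_undefined_ratio", "days must be >= 1")
  if (total_waste_kg <= 0) {
    pw_stop("pw_undefined_ratio", "total waste mass must be > 0")
  }
  per_meal <- if (!is.na(meals) && meals >= 1) total_cost_eur / meals else NA_real_
  list(
    daily_cost_eur = total_cost_eur / days,
    cost_per_kg_eur = total_cost_eur / total_waste_kg,
    cost_per_meal_eur = per_meal,
    share_of_full_price_pct =
      if (!is.na(per_meal) && !is.na(full_price_eur) && full_price_eur > 0)
        100 * per_meal / full_price_eur else NA_real_,
    share_of_procurement_budget_pct =
      if (!is.na(procurement_budget_eur) && procurement_budget_eur > 0)
        100 * total_cost_eur / procurement_budget_eur else NA_real_)
}

#' Full cost account for one case
#'
#' Waste within each category is decomposed across items proportionally to
#' the served item mix (same reconstruction as the nutrition and carbon
#' stages), so the category cost equals both `waste_kg x weighted-mean price`
#' and the item-level cost sum. Amounts are carried at full precision;
#' rounding happens only in report tables.
#'
#' @param campaign A validated `pw_campaign`.
#' @param case_id Case to account.
#' @param accounts Optional precomputed [day_accounts()].
#' @return List with `per_category` (waste_kg, cost_per_kg_eur,
#'   waste_cost_eur, cost share, avg cost per serving), `totals` and the
#'   derived metrics.
#' @export
cost_account <- function(campaign, case_id, accounts = NULL) {
  if (is.null(accounts)) accounts <- day_accounts(campaign)
  acc_case <- accounts[accounts$case_id == case_id, , drop = FALSE]
  if (!nrow(acc_case)) pw_stop("pw_validation_error", "unknown case: ", case_id)
  items <- case_item_masses(campaign, case_id, accounts)
  items$price <- vapply(seq_len(nrow(items)), function(i) {
    resolve_price(campaign, items$food_item_id[i], items$category[i])
  }, numeric(1))

  cats <- sort(unique(items$category))
  per_cat <- do.call(rbind, lapply(cats, function(cc) {
    it <- items[items$category == cc, , drop = FALSE]
    cpk <- category_cost_per_kg(it$served_kg, it$price)
    wkg <- sum(it$waste_item_kg) # item decomposition sums back to category waste
    data.frame(category = cc, waste_kg = wkg, cost_per_kg_eur = cpk,
               waste_cost_eur = waste_cost(wkg, cpk))
  }))

  serv_counts <- tapply(acc_case$children, acc_case$category, sum)
  per_cat$servings <- vapply(per_cat$category, function(cc) {
    if (cc == "starchy" && !is.na(serv_counts["bread"])) {
      mean(c(serv_counts[["starchy"]], serv_counts[["bread"]]))
    } else serv_counts[[cc]]
  }, numeric(1))
  per_cat$avg_cost_per_serving_eur <- per_cat$waste_cost_eur / per_cat$servings

  total_cost <- sum(per_cat$waste_cost_eur)
  per_cat$cost_share_pct <- if (total_cost > 0) {
    100 * per_cat$waste_cost_eur / total_cost
  } else 0
  total_waste_kg <- sum(per_cat$waste_kg)
  n_days <- length(unique(paste(acc_case$date, acc_case$school_id)))

  cfg <- case_config(campaign, case_id)
  meals <- if (!is.null(cfg$meals_served)) cfg$meals_served else
    sum(tapply(acc_case$children, paste(acc_case$date, acc_case$school_id), max))
  derived <- if (total_waste_kg > 0) {
    derived_cost_metrics(
      total_cost, total_waste_kg, n_days, meals,
      if (is.null(cfg$full_price_eur)) NA else cfg$full_price_eur,
      if (is.null(cfg$procurement_budget_eur)) NA else cfg$procurement_budget_eur)
  } else {
    # nothing wasted: costs are zero, per-kg rate undefined
    list(daily_cost_eur = 0, cost_per_kg_eur = NA_real_,
         cost_per_meal_eur = 0, share_of_full_price_pct = 0,
         share_of_procurement_budget_pct = 0)
  }

  list(case_id = case_id, per_category = per_cat,
       totals = c(list(total_cost_eur = total_cost,
                       total_waste_kg = total_waste_kg,
                       n_days = n_days, meals = meals), derived))
}
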
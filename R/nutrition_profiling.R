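# Nutrition profiling: turn served dishes and aggregate category waste into
# energy/nutrient amounts for served, wasted and consumed lunches, and the
# resulting percentage losses. Aggregate waste carries no composition of its
# own; it is assigned the nutrient density of the served mix of its category
# that day (the only reconstruction consistent with aggregate weighing and
# per-nutrient waste reporting).

#' Nutrient profile of one serving of a dish
#'
#' Sums, over the dish's recipe items, `grams/100 x profile_per_100g` from
#' the food-composition table.
#'
#' @param dish_id Dish identifier.
#' @param campaign A validated `pw_campaign` (provides recipes and
#'   composition).
#' @return A [nutrient_profile()] per single serving.
#' @export
dish_profile <- function(dish_id, campaign) {
  rec <- campaign$recipes[campaign$recipes$dish_id == dish_id, , drop = FALSE]
  if (!nrow(rec)) {
    pw_stop("pw_integrity_error", "dish has no recipe: ", dish_id)
  }
  comp <- campaign$composition
  idx <- match(rec$food_item_id, comp$food_item_id)
  if (anyNA(idx)) {
    pw_stop("pw_integrity_error", "no composition record for item(s): ",
            paste(rec$food_item_id[is.na(idx)], collapse = ", "))
  }
  mat <- as.matrix(comp[idx, pw_nutrients, drop = FALSE])
  as_profile(colSums(mat * (rec$grams_per_serving / 100)))
}

#' Nutrient content of a category's aggregate waste
#'
#' Waste collected for a category-day is assumed compositionally identical to
#' the served mix of that category, so its nutrient content is the served
#' category profile scaled by the wasted fraction of the served mass.
#'
#' @param waste_g Aggregate waste mass of the category that day (grams).
#' @param dish_ids Dishes of the category served that day.
#' @param children Number of children served.
#' @param campaign A validated `pw_campaign`.
#' @return A [nutrient_profile()] at aggregate (all-children) scale.
#' @export
waste_profile <- function(waste_g, dish_ids, children, campaign) {
  dishes <- campaign$dishes[match(dish_ids, campaign$dishes$dish_id), ,
                            drop = FALSE]
  served_g <- sum(served_mass(dishes$avg_serving_g, children))
  if (served_g <= 0) {
    if (waste_g > 0) {
      pw_stop("pw_validation_error", "nonzero waste with zero served mass")
    }
    return(zero_profile())
  }
  served_profile <- Reduce(profile_add,
                           lapply(dish_ids, dish_profile, campaign = campaign))
  profile_scale(served_profile, children * waste_g / served_g)
}

#' Per-lunch nutrition of one menu day
#'
#' For one (date, school) day-unit: the served profile is the sum of the dish
#' profiles of the day's menu (one serving per dish, i.e. per child per
#' lunch); the wasted profile is the sum over categories of the category
#' waste profile normalised per child; intake is served minus wasted,
#' component-wise, floored at zero with flags. Percentage losses are
#' `100 x wasted / served` per component (missing where nothing of a
#' component was served).
#'
#' @param date,school_id Day-unit key.
#' @param campaign A validated `pw_campaign`.
#' @param accounts Day accounts from [day_accounts()] (recomputed if `NULL`).
#' @return List with `date`, `school_id`, `case_id`, profiles `served`,
#'   `wasted`, `intake` (per child per lunch), `loss_pct` (named vector, NA
#'   where undefined) and `floored` (components floored during subtraction).
#' @export
menu_nutrition <- function(date, school_id, campaign, accounts = NULL) {
  if (is.null(accounts)) accounts <- day_accounts(campaign)
  day_acc <- accounts[accounts$date == date & accounts$school_id == school_id, ,
                      drop = FALSE]
  if (!nrow(day_acc)) {
    pw_stop("pw_validation_error", "no accounts for ", date, " ", school_id)
  }
  menus <- campaign$menus
  day_menu <- menus[menus$date == date & menus$school_id == school_id, ,
                    drop = FALSE]
  dish_cat <- campaign$dishes$category[match(day_menu$dish_id,
                                             campaign$dishes$dish_id)]
  served <- Reduce(profile_add,
                   lapply(day_menu$dish_id, dish_profile, campaign = campaign))
  wasted <- zero_profile()
  for (i in seq_len(nrow(day_acc))) {
    ids <- day_menu$dish_id[dish_cat == day_acc$category[i]]
    wp <- waste_profile(day_acc$waste_g[i], ids, day_acc$children[i], campaign)
    wasted <- profile_add(wasted, profile_scale(wp, 1 / day_acc$children[i]))
  }
  intake <- profile_subtract(served, wasted, warn = FALSE)
  loss <- ifelse(unclass(served) > 0, 100 * unclass(wasted) / unclass(served),
                 NA_real_)
  list(date = date, school_id = school_id, case_id = day_acc$case_id[1],
       served = served, wasted = wasted, intake = intake,
       loss_pct = stats::setNames(loss, pw_nutrients),
       floored = attr(intake, "floored"))
}

# per-serving nutrient profile of every dish, as a dishes x nutrients matrix
dish_profile_matrix <- function(campaign) {
  rec <- campaign$recipes
  comp <- campaign$composition
  idx <- match(rec$food_item_id, comp$food_item_id)
  if (anyNA(idx)) {
    pw_stop("pw_integrity_error", "no composition record for item(s): ",
            paste(unique(rec$food_item_id[is.na(idx)]), collapse = ", "))
  }
  contrib <- as.matrix(comp[idx, pw_nutrients, drop = FALSE]) *
    (rec$grams_per_serving / 100)
  rowsum(contrib, rec$dish_id)
}

#' Nutrition results for every day-unit of a campaign
#'
#' Vectorised equivalent of calling [menu_nutrition()] on each (date, school)
#' day-unit.
#'
#' @param campaign A validated `pw_campaign`.
#' @return Data frame with one row per (date, school): identifier columns,
#'   then `served_`, `wasted_`, `intake_` and `loss_` columns for each of the
#'   23 nutrient components, all on the per-child-per-lunch scale, plus
#'   `n_floored` (count of intake components floored at zero).
#' @export
campaign_nutrition <- function(campaign) {
  accounts <- day_accounts(campaign)
  profs <- dish_profile_matrix(campaign)
  menus <- campaign$menus
  menus$category <- campaign$dishes$category[match(menus$dish_id,
                                                   campaign$dishes$dish_id)]
  unit_key <- paste(menus$case_id, menus$date, menus$school_id, sep = "\r")
  served <- rowsum(profs[menus$dish_id, , drop = FALSE], unit_key)

  # per (unit, category) served profile, scaled by that category's wasted
  # fraction of served mass, summed back to units
  uc_key <- paste(unit_key, menus$category, sep = "\r")
  cat_prof <- rowsum(profs[menus$dish_id, , drop = FALSE], uc_key)
  acc_key <- paste(accounts$case_id, accounts$date, accounts$school_id,
                   accounts$category, sep = "\r")
  ratio <- (accounts$waste_g / accounts$served_g)[match(rownames(cat_prof),
                                                        acc_key)]
  unit_of_uc <- sub("\r[^\r]*$", "", rownames(cat_prof))
  wasted <- rowsum(cat_prof * ratio, unit_of_uc)
  wasted <- wasted[rownames(served), , drop = FALSE]

  intake <- served - wasted
  n_floored <- rowSums(intake < 0)
  intake[intake < 0] <- 0
  loss <- ifelse(served > 0, 100 * wasted / served, NA_real_)

  ids <- do.call(rbind, strsplit(rownames(served), "\r", fixed = TRUE))
  out <- data.frame(date = ids[, 2], school_id = ids[, 3], case_id = ids[, 1])
  colnames(served) <- paste0("served_", pw_nutrients)
  colnames(wasted) <- paste0("wasted_", pw_nutrients)
  colnames(intake) <- paste0("intake_", pw_nutrients)
  colnames(loss) <- paste0("loss_", pw_nutrients)
  out <- cbind(out, served, wasted, intake, loss)
  out$n_floored <- unname(n_floored)
  rownames(out) <- NULL
  out[order(out$case_id, out$date, out$school_id), ]
}
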
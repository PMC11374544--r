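# Waste accounting: served amounts, waste percentages, waste per child and
# intake per child, per category-day and aggregated per case.

#' Served mass of a dish
#'
#' The served amount of a dish is the average edible serving (mean of the
#' three weighed servings) multiplied by the number of children served.
#'
#' @param avg_serving_g Average edible serving mass in grams (> 0).
#' @param children Number of children served (integer >= 1).
#' @return Served mass in grams.
#' @examples
#' served_mass(120, 100)  # 12000
#' @export
served_mass <- function(avg_serving_g, children) {
  if (!all(is.finite(avg_serving_g)) || any(avg_serving_g <= 0)) {
    pw_stop("pw_validation_error", "avg_serving_g must be > 0")
  }
  if (any(children < 1)) pw_stop("pw_validation_error", "children must be >= 1")
  avg_serving_g * children
}

#' Waste as a percentage of served mass
#'
#' @param waste_g Waste mass (grams), >= 0.
#' @param served_g Served mass (grams), > 0.
#' @return Percentage `100 * waste_g / served_g`. Values above 100 are
#'   possible when aggregate waste exceeds nominal served mass; callers flag
#'   them, this function never clips.
#' @export
waste_percentage <- function(waste_g, served_g) {
  if (any(served_g <= 0)) {
    pw_stop("pw_undefined_ratio", "waste percentage undefined: served mass 0")
  }
  100 * waste_g / served_g
}

#' Mass per child
#' @param mass_g Aggregate mass in grams.
#' @param children Number of children served (>= 1).
#' @return `mass_g / children`.
#' @export
per_child <- function(mass_g, children) {
  if (any(children < 1)) pw_stop("pw_validation_error", "children must be >= 1")
  mass_g / children
}

#' Intake per child
#'
#' Average serving minus average waste per child. A negative difference
#' (aggregate waste exceeding the nominal serving, e.g. children taking
#' seconds) is floored at zero and flagged rather than silently clipped.
#'
#' @param avg_serving_g Average serving per child (grams).
#' @param waste_per_child_g Waste per child (grams).
#' @return Numeric vector with attribute `flagged` (logical vector marking
#'   entries that were floored).
#' @export
intake_per_child <- function(avg_serving_g, waste_per_child_g) {
  stopifnot(all(avg_serving_g >= 0), all(waste_per_child_g >= 0))
  d <- avg_serving_g - waste_per_child_g
  flagged <- d < 0
  d[flagged] <- 0
  structure(d, flagged = flagged)
}

#' Per category-day waste accounts for one or more cases
#'
#' Joins the aggregate waste observations with the menus served that day to
#' produce one account row per (date, school, category): served mass (sum of
#' dish servings of the category times children), waste mass, waste
#' percentage, waste per child and intake per child. The analysis day-unit is
#' a (date, school) pair, matching day-level collection.
#'
#' @param campaign A validated `pw_campaign`.
#' @return Data frame with columns date, school_id, case_id, category,
#'   serving_g (per-child category serving), served_g, waste_g, children,
#'   waste_pct, waste_per_child_g, intake_per_child_g, flag_waste_gt_served,
#'   flag_neg_intake.
#' @export
day_accounts <- function(campaign) {
  dt <- data.table::as.data.table(campaign$menus)
  dishes <- data.table::as.data.table(
    campaign$dishes[, c("dish_id", "category", "avg_serving_g")])
  dt <- merge(dt, dishes, by = "dish_id", allow.cartesian = TRUE)
  serving <- dt[, list(serving_g = sum(avg_serving_g)),
                by = c("date", "school_id", "case_id", "category")]
  obs <- data.table::as.data.table(campaign$observations)
  acc <- merge(serving, obs,
               by = c("date", "school_id", "case_id", "category"),
               all = TRUE)
  if (any(is.na(acc$serving_g))) {
    bad <- acc[is.na(acc$serving_g)]
    pw_stop("pw_integrity_error",
            "waste observed for a category with no served dish: ",
            paste(unique(paste(bad$date, bad$school_id, bad$category)),
                  collapse = "; "))
  }
  # a served category with no observation row means zero waste was recorded
  day_children <- acc[!is.na(children_served),
                      list(ch = children_served[1]),
                      by = c("date", "school_id")]
  acc <- merge(acc, day_children, by = c("date", "school_id"), all.x = TRUE)
  acc[is.na(waste_mass_g), waste_mass_g := 0]
  acc[is.na(children_served), children_served := ch]
  acc[, ch := NULL]
  if (any(is.na(acc$children_served))) {
    pw_stop("pw_integrity_error", "no children count derivable for some days")
  }
  acc[, served_g := served_mass(serving_g, children_served)]
  acc[, waste_pct := waste_percentage(waste_mass_g, served_g)]
  acc[, waste_per_child_g := per_child(waste_mass_g, children_served)]
  ipc <- intake_per_child(acc$serving_g, acc$waste_per_child_g)
  acc[, intake_per_child_g := as.numeric(ipc)]
  acc[, flag_neg_intake := attr(ipc, "flagged")]
  acc[, flag_waste_gt_served := waste_mass_g > served_g]
  out <- as.data.frame(acc)
  names(out)[names(out) == "waste_mass_g"] <- "waste_g"
  names(out)[names(out) == "children_served"] <- "children"
  out[order(out$case_id, out$date, out$school_id, out$category), ]
}

#' Aggregate a case's day accounts
#'
#' Sums served and waste masses per category and in total, and builds the
#' per-day-unit series (total waste kg, waste percentage of served, waste per
#' child in grams) used for descriptive statistics and between-case testing.
#' Day-level statistics pool the collection days of a case across its
#' schools, so a case observed in two schools for two weeks contributes
#' around twenty day-units.
#'
#' @param accounts Day-account rows (from [day_accounts()]) of a single case.
#' @return List with `case_id`, `per_category` (data frame: days observed,
#'   dishes served, served_kg, waste_kg, waste_pct, mean serving_g, daily
#'   waste-percentage and waste-per-child series as list columns), `totals`
#'   (served_kg, waste_kg, waste_pct, n_days, waste_per_day_kg) and `daily`
#'   (data frame of per day-unit totals).
#' @export
aggregate_case <- function(accounts) {
  if (length(unique(accounts$case_id)) != 1) {
    pw_stop("pw_validation_error", "aggregate_case requires a single case_id")
  }
  acc <- data.table::as.data.table(accounts)
  per_cat <- acc[, list(
    n_days = .N,
    served_kg = sum(served_g) / 1000,
    waste_kg = sum(waste_g) / 1000,
    waste_pct = waste_percentage(sum(waste_g), sum(served_g)),
    serving_g = mean(serving_g),
    daily_waste_pct = list(waste_pct),
    daily_waste_per_child_g = list(waste_per_child_g),
    daily_serving_g = list(serving_g)
  ), by = "category"]
  daily <- acc[, list(
    served_g = sum(served_g),
    waste_g = sum(waste_g),
    children = max(children),
    serving_g = sum(serving_g)
  ), by = c("date", "school_id")]
  daily[, waste_pct := waste_percentage(waste_g, served_g)]
  daily[, waste_per_child_g := waste_g / children]
  n_days <- nrow(daily)
  totals <- list(
    served_kg = sum(acc$served_g) / 1000,
    waste_kg = sum(acc$waste_g) / 1000,
    waste_pct = waste_percentage(sum(acc$waste_g), sum(acc$served_g)),
    n_days = n_days,
    waste_per_day_kg = sum(acc$waste_g) / 1000 / n_days,
    n_flags = sum(accounts$flag_neg_intake | accounts$flag_waste_gt_served))
  list(case_id = accounts$case_id[1],
       per_category = as.data.frame(per_cat),
       totals = totals,
       daily = as.data.frame(daily))
}
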
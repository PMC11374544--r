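# Guideline compliance: each menu-day's nutrition (as served and as actually
# consumed after waste adjustment) is judged against configurable national
# school-lunch bounds. Bounds are closed intervals: a value equal to a bound
# is compliant. Besides the plain profile components, derived energy-share
# quantities (protein/fat/carbohydrate as percent of energy, Atwater factors
# 4/9/4 kcal per g) can be bounded.

derived_quantities <- c("protein_pct_energy", "fat_pct_energy",
                        "carbohydrate_pct_energy")

quantity_value <- function(profile, quantity) {
  p <- unclass(profile)
  if (quantity %in% pw_nutrients) return(p[[quantity]])
  if (quantity %in% derived_quantities) {
    if (p[["energy_kcal"]] <= 0) return(NA_real_)
    g <- switch(quantity,
                protein_pct_energy = 4 * p[["protein_g"]],
                fat_pct_energy = 9 * p[["fat_g"]],
                carbohydrate_pct_energy = 4 * p[["carbohydrate_g"]])
    return(100 * g / p[["energy_kcal"]])
  }
  pw_stop("pw_config_error", "guideline quantity not recognised: ", quantity)
}

#' Check one menu against guideline bounds
#'
#' @param profile A per-child-per-lunch [nutrient_profile()] (as-served or
#'   as-consumed).
#' @param guidelines Guideline-bounds data frame (`quantity`, `lower`,
#'   `upper`, `units`, `basis`); `NA` bounds mean unbounded on that side.
#' @param basis `"as_served"` or `"as_consumed"`; rows whose `basis` is not
#'   `"both"` apply only to the matching basis.
#' @return Data frame with one row per guideline row: `quantity`, `value`,
#'   `verdict` in {below, within, above, no_bound}.
#' @export
check_menu <- function(profile, guidelines, basis = c("as_served", "as_consumed")) {
  basis <- match.arg(basis)
  g <- guidelines
  applies <- is.na(g$basis) | g$basis %in% c("both", basis)
  g <- g[applies, , drop = FALSE]
  value <- vapply(g$quantity, quantity_value, numeric(1), profile = profile)
  verdict <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    lo <- g$lower[i]; hi <- g$upper[i]
    verdict[i] <-
      if (is.na(lo) && is.na(hi)) "no_bound"
      else if (is.na(value[i])) NA_character_
      else if (!is.na(lo) && value[i] < lo) "below"
      else if (!is.na(hi) && value[i] > hi) "above"
      else "within"
  }
  data.frame(quantity = g$quantity, value = value, verdict = verdict,
             basis = basis, row.names = NULL, stringsAsFactors = FALSE)
}

#' Share of menus compliant with a bounded quantity
#'
#' @param results Row-bound output of [check_menu()] over a set of menus.
#' @param quantity Quantity name to summarise.
#' @return Percent of menus with verdict "within" among menus where the
#'   quantity has a bound; `NA_real_` when no menu carries a bound for it.
#' @export
compliance_share <- function(results, quantity) {
  v <- results$verdict[results$quantity == quantity]
  v <- v[!is.na(v) & v != "no_bound"]
  if (!length(v)) return(NA_real_)
  100 * sum(v == "within") / length(v)
}

#' Compliance evaluation for a whole campaign
#'
#' Runs [check_menu()] on every menu-day of every case, on both the as-served
#' and the as-consumed (waste-adjusted) profile, and summarises compliance
#' shares per case, basis and quantity.
#'
#' @param campaign A validated `pw_campaign`.
#' @param nutrition Optional precomputed [campaign_nutrition()] output.
#' @return List with `verdicts` (per menu-day rows) and `shares` (case_id,
#'   basis, quantity, share_pct, n_menus).
#' @export
campaign_compliance <- function(campaign, nutrition = NULL) {
  if (is.null(nutrition)) nutrition <- campaign_nutrition(campaign)
  g <- campaign$guidelines
  verdicts <- list()
  for (i in seq_len(nrow(nutrition))) {
    for (basis in c("as_served", "as_consumed")) {
      pref <- if (basis == "as_served") "served_" else "intake_"
      prof <- as_profile(as.numeric(nutrition[i, paste0(pref, pw_nutrients)]))
      res <- check_menu(prof, g, basis)
      res$date <- nutrition$date[i]
      res$school_id <- nutrition$school_id[i]
      res$case_id <- nutrition$case_id[i]
      verdicts[[length(verdicts) + 1L]] <- res
    }
  }
  verdicts <- do.call(rbind, verdicts)
  combos <- unique(verdicts[, c("case_id", "basis", "quantity")])
  shares <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- verdicts$case_id == combos$case_id[i] &
      verdicts$basis == combos$basis[i]
    data.frame(combos[i, ],
               share_pct = compliance_share(verdicts[sel, ], combos$quantity[i]),
               n_menus = sum(sel & verdicts$quantity == combos$quantity[i]),
               row.names = NULL)
  }))
  list(verdicts = verdicts, shares = shares)
}
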
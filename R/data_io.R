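# Tabular input/output with schema validation. All campaign data live in
# delimited text files (comma, "." decimal, UTF-8); masses are grams
# internally, kg only at presentation.
#
# File schemas (one header row each):
#   observations.csv  date, school_id, case_id, category, waste_mass_g,
#                     children_served [, season]
#   menus.csv         date, school_id, case_id, dish_id
#   dishes.csv        dish_id, name, category, serving1_g, serving2_g,
#                     serving3_g, avg_serving_g
#   recipes.csv       dish_id, food_item_id, grams_per_serving
#   composition.csv   food_item_id, <the 23 pw_nutrients columns, per 100 g>
#   factors.csv       scope, scope_type (item|category|disposal),
#                     production_ef_kgco2e_per_kg,
#                     transport_ef_kgco2e_per_kg_km, disposal_ef_kgco2e_per_kg
#   prices.csv        scope, scope_type (item|category), price_eur_per_kg
#   guidelines.csv    quantity, lower, upper, units, basis
#   config.yaml       cases (case_id, transport_distance_km, full_price_eur,
#                     procurement_budget_eur, meals_served), disposal_method

pw_files <- c("observations", "menus", "dishes", "recipes", "composition",
              "factors", "prices", "guidelines")

pw_schemas <- function() list(
  observations = c("date", "school_id", "case_id", "category", "waste_mass_g",
                   "children_served"),
  menus        = c("date", "school_id", "case_id", "dish_id"),
  dishes       = c("dish_id", "name", "category", "serving1_g", "serving2_g",
                   "serving3_g", "avg_serving_g"),
  recipes      = c("dish_id", "food_item_id", "grams_per_serving"),
  composition  = c("food_item_id", pw_nutrients),
  factors      = c("scope", "scope_type", "production_ef_kgco2e_per_kg",
                   "transport_ef_kgco2e_per_kg_km", "disposal_ef_kgco2e_per_kg"),
  prices       = c("scope", "scope_type", "price_eur_per_kg"),
  guidelines   = c("quantity", "lower", "upper", "units", "basis"))

read_table_checked <- function(path, name) {
  if (!file.exists(path)) {
    pw_stop("pw_io_error", "input file not found: ", path)
  }
  df <- as.data.frame(data.table::fread(path, colClasses = NULL,
                                        na.strings = c("NA", "")))
  missing <- setdiff(pw_schemas()[[name]], names(df))
  if (length(missing)) {
    pw_stop("pw_schema_error", name, ".csv: missing column(s): ",
            paste(missing, collapse = ", "))
  }
  df
}

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    pw_stop("pw_validation_error", what, " must be finite and >= 0")
  }
}

#' Load and validate a full campaign dataset
#'
#' Reads the eight delimited input files plus the YAML config from `dir`
#' and cross-validates them: every category code must be one of the seven
#' [pw_categories]; every menu entry must resolve to a dish, every recipe item
#' to a composition record, and every (item, category) pair occurring in
#' served menus to an emission factor and a price (item-level rows override
#' category-level rows); `(date, school_id, category)` is unique in the
#' observation table; each dish's `avg_serving_g` must equal the mean of its
#' three weighed servings to within 1e-9 relative tolerance. Loading is
#' idempotent: loading twice yields identical objects.
#'
#' @param dir Directory holding `observations.csv`, `menus.csv`, `dishes.csv`,
#'   `recipes.csv`, `composition.csv`, `factors.csv`, `prices.csv`,
#'   `guidelines.csv` and `config.yaml`.
#' @param config_path Path to the YAML config (defaults to `config.yaml`
#'   inside `dir`).
#' @return A `pw_campaign` list with one data frame per input table plus the
#'   parsed `config`.
#' @export
load_campaign <- function(dir, config_path = file.path(dir, "config.yaml")) {
  tabs <- lapply(stats::setNames(pw_files, pw_files), function(nm) {
    read_table_checked(file.path(dir, paste0(nm, ".csv")), nm)
  })
  config <- yaml::read_yaml(config_path)
  campaign <- structure(c(tabs, list(config = config)), class = "pw_campaign")
  validate_campaign(campaign)
  campaign
}

#' Validate a campaign object against all type invariants
#'
#' Called by [load_campaign()]; exported so in-memory campaigns (e.g. from
#' [generate_campaign()]) can be checked with the same rules.
#'
#' @param campaign A `pw_campaign` list.
#' @return The campaign, invisibly, if valid; otherwise a classed error
#'   (`pw_schema_error`, `pw_validation_error` or `pw_integrity_error`).
#' @export
validate_campaign <- function(campaign) {
  obs <- campaign$observations
  dishes <- campaign$dishes
  menus <- campaign$menus
  recipes <- campaign$recipes
  comp <- campaign$composition

  bad_cat <- setdiff(unique(c(obs$category, dishes$category)), pw_categories)
  if (length(bad_cat)) {
    pw_stop("pw_validation_error", "unknown food category code(s): ",
            paste(bad_cat, collapse = ", "))
  }
  check_nonneg(obs$waste_mass_g, "waste_mass_g")
  if (any(obs$children_served < 1 | obs$children_served %% 1 != 0)) {
    pw_stop("pw_validation_error", "children_served must be integer >= 1")
  }
  key <- paste(obs$date, obs$school_id, obs$category, sep = "\r")
  if (anyDuplicated(key)) {
    pw_stop("pw_validation_error",
            "(date, school_id, category) not unique in observations")
  }
  if (any(!grepl("^\\d{4}-\\d{2}-\\d{2}$", c(obs$date, menus$date)))) {
    pw_stop("pw_validation_error", "dates must be ISO-8601 (YYYY-MM-DD)")
  }

  m <- as.matrix(dishes[, c("serving1_g", "serving2_g", "serving3_g")])
  if (any(m <= 0)) {
    pw_stop("pw_validation_error", "serving measurements must be > 0")
  }
  rel <- abs(dishes$avg_serving_g - rowMeans(m)) / pmax(rowMeans(m), 1e-300)
  if (any(rel > 1e-9)) {
    pw_stop("pw_validation_error",
            "avg_serving_g must equal the mean of the three measurements: ",
            paste(dishes$dish_id[rel > 1e-9], collapse = ", "))
  }

  check_nonneg(recipes$grams_per_serving, "recipe grams_per_serving")
  rsum <- tapply(recipes$grams_per_serving, recipes$dish_id, sum)
  if (any(rsum <= 0)) {
    pw_stop("pw_validation_error", "recipe grams must sum > 0 for dish(es): ",
            paste(names(rsum)[rsum <= 0], collapse = ", "))
  }

  dangle <- function(ids, universe, what) {
    bad <- setdiff(unique(ids), universe)
    if (length(bad)) {
      pw_stop("pw_integrity_error", "dangling ", what, ": ",
              paste(bad, collapse = ", "))
    }
  }
  dangle(menus$dish_id, dishes$dish_id, "menu dish_id")
  dangle(recipes$dish_id, dishes$dish_id, "recipe dish_id")
  dangle(recipes$food_item_id, comp$food_item_id,
         "recipe food_item_id (no composition record)")
  if (anyDuplicated(comp$food_item_id)) {
    pw_stop("pw_validation_error", "duplicate composition food_item_id")
  }
  for (nut in pw_nutrients) check_nonneg(comp[[nut]], paste0("composition ", nut))

  fac <- campaign$factors
  check_nonneg(fac$production_ef_kgco2e_per_kg, "production EF")
  check_nonneg(fac$transport_ef_kgco2e_per_kg_km, "transport EF")
  check_nonneg(fac$disposal_ef_kgco2e_per_kg, "disposal EF")
  check_nonneg(campaign$prices$price_eur_per_kg, "price")

  # every (item, category) pair reachable through served dishes must resolve
  pairs <- merge(recipes[, c("dish_id", "food_item_id")],
                 dishes[, c("dish_id", "category")], by = "dish_id")
  for (i in seq_len(nrow(pairs))) {
    resolve_factor(campaign, pairs$food_item_id[i], pairs$category[i])
    resolve_price(campaign, pairs$food_item_id[i], pairs$category[i])
  }

  g <- campaign$guidelines
  both <- !is.na(g$lower) & !is.na(g$upper)
  if (any(g$lower[both] > g$upper[both])) {
    pw_stop("pw_validation_error", "guideline lower bound exceeds upper for: ",
            paste(g$quantity[both][g$lower[both] > g$upper[both]],
                  collapse = ", "))
  }
  invisible(campaign)
}

# item-level rows override category-level rows
resolve_factor <- function(campaign, item, category) {
  fac <- campaign$factors
  row <- fac[fac$scope_type == "item" & fac$scope == item, , drop = FALSE]
  if (!nrow(row)) {
    row <- fac[fac$scope_type == "category" & fac$scope == category, ,
               drop = FALSE]
  }
  if (!nrow(row)) {
    pw_stop("pw_integrity_error", "no emission factor for item '", item,
            "' or category '", category, "'")
  }
  row[1, ]
}

resolve_price <- function(campaign, item, category) {
  pr <- campaign$prices
  row <- pr[pr$scope_type == "item" & pr$scope == item, , drop = FALSE]
  if (!nrow(row)) {
    row <- pr[pr$scope_type == "category" & pr$scope == category, ,
              drop = FALSE]
  }
  if (!nrow(row)) {
    pw_stop("pw_integrity_error", "no price for item '", item,
            "' or category '", category, "'")
  }
  row$price_eur_per_kg[1]
}

disposal_factor <- function(campaign) {
  method <- campaign$config$disposal_method
  fac <- campaign$factors
  row <- fac[fac$scope_type == "disposal" & fac$scope == method, , drop = FALSE]
  if (is.null(method) || !nrow(row)) {
    pw_stop("pw_config_error", "no disposal factor row for method '",
            if (is.null(method)) "<unset>" else method, "'")
  }
  row$disposal_ef_kgco2e_per_kg[1]
}

# %.17g survives a write/read round trip bit-identically for doubles
fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_,
         ifelse(x == floor(x) & abs(x) < 1e15,
                sprintf("%.0f", x), sprintf("%.17g", x)))
}

write_pw_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  data.table::fwrite(out, path, quote = "auto", na = "NA", bom = FALSE)
}

#' Write a campaign dataset to disk
#'
#' Writes the eight CSV files plus `config.yaml` so that [load_campaign()]
#' reproduces the in-memory object bit-identically on all numeric fields
#' (doubles are serialised with 17 significant digits).
#'
#' @param campaign A `pw_campaign` list.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in pw_files) {
    write_pw_csv(campaign[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  yaml::write_yaml(campaign$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write report tables mirroring the published table structure
#'
#' Emits one CSV per pipeline result table (waste accounting totals and daily
#' descriptives, nutrient composition of served/waste/intake, nutrient-loss
#' percentages, guideline compliance shares, emission accounts, cost accounts,
#' between-case comparisons) plus a machine-readable `results.json`. Files are
#' UTF-8, comma-delimited, "." decimals.
#'
#' @param results A `pw_results` list from [run_pipeline()] (or any subset of
#'   its tables).
#' @param out_dir Output directory; tables go under `out_dir/tables`.
#' @return Character vector of files written, invisibly.
#' @export
write_report_tables <- function(results, out_dir) {
  tab_dir <- file.path(out_dir, "tables")
  dir.create(tab_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(tab_dir)) pw_stop("pw_io_error", "cannot create ", tab_dir)
  written <- character()
  for (nm in names(results$tables)) {
    path <- file.path(tab_dir, paste0(nm, ".csv"))
    write_pw_csv(results$tables[[nm]], path)
    written <- c(written, path)
  }
  json_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(results$summary, json_path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(c(written, json_path))
}
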
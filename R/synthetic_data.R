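# Synthetic campaign generator. Emulates a two-case aggregate-selective
# plate-waste collection campaign with known (planted) ground truth: daily
# per-category waste fractions are Beta-distributed around case-specific
# means, serving sizes come from three weighed servings per dish, children
# counts are uniform per day-unit. The preset tables (composition, emission
# factors, prices, guideline bounds) are internally consistent toy values,
# NOT any study's confidential inputs.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Construct a synthetic-campaign specification
#'
#' @param seed Integer RNG seed.
#' @param cases List of case descriptors: `case_id`, `n_days` (collection
#'   day-units pooled over schools), `n_schools`, `children_range` (inclusive
#'   integer range per day-unit), `waste_fractions` (named per-category mean
#'   daily waste fractions in (0, 1]; 0 allowed for "no waste"),
#'   `dessert_every` / `other_every` (serve dessert / an "other" dish every
#'   k-th day-unit; `Inf` = never), and config fields
#'   `transport_distance_km`, `full_price_eur`, `procurement_budget_eur`.
#' @param category_params Data frame: `category`, `serving_mean_g`,
#'   `serving_sd_g`, `concentration` (Beta concentration of daily waste
#'   fractions; `Inf` = deterministic fractions).
#' @param menu_library List with `dishes`, `recipes` data frames (see the
#'   data-io schemas; `avg_serving_g` is filled at generation time).
#' @param composition,factors,prices,guidelines Tables per the data-io
#'   schemas.
#' @param disposal_method Disposal route; must have a factor row.
#' @return A `pw_campaign_spec` list.
#' @export
campaign_spec <- function(seed, cases, category_params, menu_library,
                          composition, factors, prices, guidelines,
                          disposal_method = "composting") {
  spec <- list(seed = seed, cases = cases, category_params = category_params,
               menu_library = menu_library, composition = composition,
               factors = factors, prices = prices, guidelines = guidelines,
               disposal_method = disposal_method)
  class(spec) <- "pw_campaign_spec"
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  cp <- spec$category_params
  if (any(cp$serving_sd_g >= cp$serving_mean_g / 2)) {
    pw_stop("pw_validation_error",
            "infeasible spec: serving SD must be < mean/2")
  }
  if (any(cp$concentration <= 0)) {
    pw_stop("pw_validation_error", "Beta concentrations must be > 0")
  }
  for (cs in spec$cases) {
    f <- cs$waste_fractions
    if (any(f < 0 | f > 1)) {
      pw_stop("pw_validation_error", "waste fractions must lie in [0, 1]")
    }
    if (cs$n_days < 1 || cs$n_schools < 1) {
      pw_stop("pw_validation_error", "n_days and n_schools must be >= 1")
    }
  }
  items <- unique(spec$menu_library$recipes$food_item_id)
  if (length(setdiff(items, spec$composition$food_item_id))) {
    pw_stop("pw_integrity_error", "menu library references undefined items")
  }
  invisible(spec)
}

rbeta_mean <- function(n, mean, concentration) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  if (!is.finite(concentration)) return(rep(mean, n))
  stats::rbeta(n, mean * concentration, (1 - mean) * concentration)
}

rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

#' Generate a complete synthetic campaign
#'
#' Realises the specification into a validated in-memory `pw_campaign` plus a
#' ground-truth record of the planted parameters and their analytic
#' expectations. Per day-unit and category: children are uniform integers in
#' the case range, the daily waste fraction is Beta with the planted mean and
#' concentration, and the waste mass is fraction times the served mass. Each
#' dish's three serving measurements are Normal (truncated positive) around
#' the category serving mean. Deterministic under a fixed seed.
#'
#' @param spec A `pw_campaign_spec`.
#' @param seed Seed override (defaults to `spec$seed`).
#' @return List with `campaign` (a validated `pw_campaign`) and
#'   `ground_truth` (planted fractions and expected aggregate waste
#'   percentages per case).
#' @export
generate_campaign <- function(spec, seed = spec$seed) {
  validate_spec(spec)
  with_seed(seed, {
    cp <- spec$category_params
    rownames(cp) <- cp$category
    lib_dishes <- spec$menu_library$dishes

    # one measured average serving per dish for the whole campaign
    meas <- t(vapply(seq_len(nrow(lib_dishes)), function(i) {
      cc <- lib_dishes$category[i]
      rnorm_pos(3, cp[cc, "serving_mean_g"], cp[cc, "serving_sd_g"])
    }, numeric(3)))
    dishes <- data.frame(dish_id = lib_dishes$dish_id, name = lib_dishes$name,
                         category = lib_dishes$category,
                         serving1_g = meas[, 1], serving2_g = meas[, 2],
                         serving3_g = meas[, 3],
                         avg_serving_g = rowMeans(meas))

    gt_cases <- list(); config_cases <- list()
    obs_acc <- list(); menu_acc <- list()
    core <- c("starchy", "bread", "protein", "vegetable", "fruit")
    for (cs in spec$cases) {
      n_units <- cs$n_days
      schools <- paste0(cs$case_id, "_school", seq_len(cs$n_schools))
      exp_waste <- 0; exp_served <- 0
      cap <- n_units * length(pw_categories)
      o <- list(date = character(cap), school = character(cap),
                category = character(cap), waste = numeric(cap),
                children = integer(cap), dish = character(cap))
      k <- 0L
      for (u in seq_len(n_units)) {
        date <- format(as.Date("2023-01-09") + (u - 1) %/% cs$n_schools,
                       "%Y-%m-%d")
        school <- schools[(u - 1) %% cs$n_schools + 1]
        children <- if (cs$children_range[1] == cs$children_range[2]) {
          cs$children_range[1]
        } else sample(cs$children_range[1]:cs$children_range[2], 1)
        cats <- core
        if (is.finite(cs$other_every) && u %% cs$other_every == 0) {
          cats <- c(setdiff(cats, c("starchy", "protein")), "other")
        }
        if (is.finite(cs$dessert_every) && u %% cs$dessert_every == 0) {
          cats <- c(setdiff(cats, "fruit"), "dessert")
        }
        for (cc in cats) {
          cat_dishes <- dishes$dish_id[dishes$category == cc]
          dish <- cat_dishes[(u - 1) %% length(cat_dishes) + 1]
          served_g <- dishes$avg_serving_g[dishes$dish_id == dish] * children
          frac <- rbeta_mean(1, cs$waste_fractions[[cc]],
                             cp[cc, "concentration"])
          k <- k + 1L
          o$date[k] <- date; o$school[k] <- school; o$category[k] <- cc
          o$waste[k] <- frac * served_g; o$children[k] <- children
          o$dish[k] <- dish
          exp_waste <- exp_waste +
            cs$waste_fractions[[cc]] * cp[cc, "serving_mean_g"]
          exp_served <- exp_served + cp[cc, "serving_mean_g"]
        }
      }
      idx <- seq_len(k)
      obs_acc[[cs$case_id]] <- data.frame(
        date = o$date[idx], school_id = o$school[idx], case_id = cs$case_id,
        category = o$category[idx], waste_mass_g = o$waste[idx],
        children_served = o$children[idx])
      menu_acc[[cs$case_id]] <- data.frame(
        date = o$date[idx], school_id = o$school[idx], case_id = cs$case_id,
        dish_id = o$dish[idx])
      gt_cases[[cs$case_id]] <- list(
        case_id = cs$case_id, n_days = cs$n_days,
        waste_fractions = as.list(cs$waste_fractions),
        expected_total_waste_pct = 100 * exp_waste / exp_served)
      config_cases[[length(config_cases) + 1L]] <- list(
        case_id = cs$case_id,
        transport_distance_km = cs$transport_distance_km,
        full_price_eur = cs$full_price_eur,
        procurement_budget_eur = cs$procurement_budget_eur)
    }

    campaign <- structure(list(
      observations = do.call(rbind, c(obs_acc, list(make.row.names = FALSE))),
      menus = do.call(rbind, c(menu_acc, list(make.row.names = FALSE))),
      dishes = dishes,
      recipes = spec$menu_library$recipes,
      composition = spec$composition,
      factors = spec$factors,
      prices = spec$prices,
      guidelines = spec$guidelines,
      config = list(cases = config_cases,
                    disposal_method = spec$disposal_method,
                    seed = seed)), class = "pw_campaign")
    validate_campaign(campaign)
    list(campaign = campaign,
         ground_truth = list(seed = seed, cases = gt_cases))
  })
}

toy_item <- function(id, ...) {
  p <- nutrient_profile(...)
  as.data.frame(c(list(food_item_id = id), as.list(unclass(p))))
}

# preset tables are deterministic; build them once per session
preset_cache <- new.env(parent = emptyenv())
memo <- function(key, builder) {
  if (is.null(preset_cache[[key]])) preset_cache[[key]] <- builder()
  preset_cache[[key]]
}

preset_composition <- function() memo("composition", build_composition)

build_composition <- function() {
  rbind(
    toy_item("pasta", energy_kcal = 160, protein_g = 6, carbohydrate_g = 31,
             soluble_sugars_g = 1, fat_g = 1, fibre_g = 2, vit_B1_mg = 0.1,
             vit_B3_mg = 1.5, K_mg = 60, P_mg = 80, Fe_mg = 1.2, Zn_mg = 0.8,
             Cu_mg = 0.1, vit_B9_ug = 7, Na_mg = 2, Ca_mg = 10,
             vit_B2_mg = 0.03, vit_B6_mg = 0.05, vit_A_ug = 1, vit_C_mg = 0,
             cholesterol_mg = 0),
    toy_item("rice", energy_kcal = 130, protein_g = 2.5, carbohydrate_g = 28,
             soluble_sugars_g = 0.1, fat_g = 0.3, fibre_g = 1, vit_B1_mg = 0.02,
             vit_B3_mg = 0.4, K_mg = 35, P_mg = 43, Fe_mg = 0.2, Zn_mg = 0.5,
             Cu_mg = 0.07, vit_B9_ug = 3, Na_mg = 1, Ca_mg = 10),
    toy_item("potato", energy_kcal = 85, protein_g = 2, carbohydrate_g = 18,
             soluble_sugars_g = 1, fat_g = 0.1, fibre_g = 1.8, vit_C_mg = 13,
             K_mg = 400, P_mg = 50, Fe_mg = 0.6, vit_B6_mg = 0.3,
             vit_B9_ug = 18, Na_mg = 6, Ca_mg = 9, vit_B1_mg = 0.08,
             Cu_mg = 0.1, Zn_mg = 0.3, vit_B3_mg = 1.3),
    toy_item("tomato_sauce", energy_kcal = 30, protein_g = 1.3,
             carbohydrate_g = 5, soluble_sugars_g = 4, fat_g = 0.3,
             fibre_g = 1.5, vit_C_mg = 10, vit_A_ug = 42, K_mg = 240,
             vit_B9_ug = 15, Na_mg = 10, Ca_mg = 14, Fe_mg = 0.5,
             vit_B6_mg = 0.1, vit_B1_mg = 0.05, Cu_mg = 0.1, P_mg = 25,
             Zn_mg = 0.2, vit_B3_mg = 0.6),
    toy_item("olive_oil", energy_kcal = 900, fat_g = 100, vit_A_ug = 36,
             vit_D_ug = 0),
    toy_item("bread_white", energy_kcal = 270, protein_g = 9,
             carbohydrate_g = 50, soluble_sugars_g = 3, fat_g = 3.5,
             fibre_g = 3, vit_B1_mg = 0.15, vit_B2_mg = 0.08, vit_B3_mg = 1.8,
             vit_B9_ug = 25, Na_mg = 500, K_mg = 120, Ca_mg = 25, P_mg = 90,
             Fe_mg = 1.2, Zn_mg = 0.9, Cu_mg = 0.2, vit_B6_mg = 0.07),
    toy_item("beef", energy_kcal = 250, protein_g = 26, fat_g = 15,
             cholesterol_mg = 70, Fe_mg = 2.5, Zn_mg = 6, vit_B12_ug = 2,
             vit_B3_mg = 5, vit_B6_mg = 0.4, vit_B2_mg = 0.2, vit_B1_mg = 0.07,
             K_mg = 320, P_mg = 200, Na_mg = 60, vit_D_ug = 0.2, Cu_mg = 0.08,
             vit_B9_ug = 6, Ca_mg = 8),
    toy_item("fish_cod", energy_kcal = 100, protein_g = 22, fat_g = 1,
             cholesterol_mg = 50, vit_D_ug = 1.5, vit_B12_ug = 1.2,
             vit_B3_mg = 2.1, K_mg = 400, P_mg = 200, Na_mg = 80, Fe_mg = 0.4,
             Zn_mg = 0.5, vit_B6_mg = 0.25, vit_B1_mg = 0.07, Cu_mg = 0.03,
             vit_B9_ug = 7, Ca_mg = 15, vit_B2_mg = 0.07),
    toy_item("cheese", energy_kcal = 350, protein_g = 25, carbohydrate_g = 2,
             soluble_sugars_g = 1, fat_g = 27, cholesterol_mg = 90,
             Ca_mg = 800, P_mg = 500, Na_mg = 600, Zn_mg = 3, vit_A_ug = 250,
             vit_B2_mg = 0.35, vit_B12_ug = 1.5, vit_D_ug = 0.5, K_mg = 100,
             Fe_mg = 0.2, Cu_mg = 0.03, vit_B9_ug = 20, vit_B1_mg = 0.03,
             vit_B6_mg = 0.08, vit_B3_mg = 0.1),
    toy_item("legumes", energy_kcal = 120, protein_g = 8, carbohydrate_g = 20,
             soluble_sugars_g = 1, fat_g = 0.8, fibre_g = 7, vit_B9_ug = 60,
             Fe_mg = 2.2, K_mg = 370, P_mg = 130, Zn_mg = 1.1, Cu_mg = 0.25,
             Ca_mg = 40, Na_mg = 5, vit_B1_mg = 0.15, vit_B6_mg = 0.15,
             vit_B3_mg = 0.6, vit_C_mg = 1, vit_B2_mg = 0.06),
    toy_item("egg", energy_kcal = 140, protein_g = 12.5, carbohydrate_g = 1,
             soluble_sugars_g = 1, fat_g = 9.5, cholesterol_mg = 370,
             vit_A_ug = 180, vit_D_ug = 1.7, vit_B12_ug = 1.1, vit_B2_mg = 0.45,
             Fe_mg = 1.5, P_mg = 200, Zn_mg = 1.2, Na_mg = 140, K_mg = 130,
             Ca_mg = 50, vit_B9_ug = 50, vit_B1_mg = 0.09, Cu_mg = 0.06,
             vit_B6_mg = 0.12, vit_B3_mg = 0.1),
    toy_item("carrot", energy_kcal = 35, protein_g = 1, carbohydrate_g = 8,
             soluble_sugars_g = 5, fat_g = 0.2, fibre_g = 3, vit_A_ug = 830,
             vit_C_mg = 6, K_mg = 320, vit_B9_ug = 19, Ca_mg = 33, Na_mg = 70,
             Fe_mg = 0.3, P_mg = 35, vit_B6_mg = 0.14, vit_B1_mg = 0.07,
             Cu_mg = 0.05, Zn_mg = 0.24, vit_B3_mg = 0.98, vit_B2_mg = 0.06),
    toy_item("zucchini", energy_kcal = 20, protein_g = 1.3, carbohydrate_g = 3,
             soluble_sugars_g = 2, fat_g = 0.2, fibre_g = 1.1, vit_C_mg = 18,
             vit_A_ug = 10, K_mg = 260, vit_B9_ug = 24, Ca_mg = 16, Na_mg = 8,
             Fe_mg = 0.4, P_mg = 38, vit_B6_mg = 0.16, vit_B1_mg = 0.05,
             Cu_mg = 0.05, Zn_mg = 0.3, vit_B3_mg = 0.45, vit_B2_mg = 0.09),
    toy_item("salad", energy_kcal = 15, protein_g = 1, carbohydrate_g = 2,
             soluble_sugars_g = 1, fat_g = 0.2, fibre_g = 1.5, vit_B9_ug = 70,
             vit_A_ug = 130, vit_C_mg = 9, K_mg = 200, Ca_mg = 35, Na_mg = 10,
             Fe_mg = 0.9, P_mg = 30, vit_B6_mg = 0.08, vit_B1_mg = 0.06,
             Cu_mg = 0.03, Zn_mg = 0.2, vit_B3_mg = 0.4, vit_B2_mg = 0.08),
    toy_item("apple", energy_kcal = 52, protein_g = 0.3, carbohydrate_g = 14,
             soluble_sugars_g = 10, fat_g = 0.2, fibre_g = 2.4, vit_C_mg = 5,
             K_mg = 107, vit_B9_ug = 3, Ca_mg = 6, Na_mg = 1, Fe_mg = 0.1,
             P_mg = 11, vit_B6_mg = 0.04, vit_B1_mg = 0.02, Cu_mg = 0.03,
             Zn_mg = 0.04, vit_B3_mg = 0.1, vit_A_ug = 3, vit_B2_mg = 0.03),
    toy_item("pear", energy_kcal = 57, protein_g = 0.4, carbohydrate_g = 15,
             soluble_sugars_g = 10, fat_g = 0.1, fibre_g = 3.1, vit_C_mg = 4,
             K_mg = 116, vit_B9_ug = 7, Ca_mg = 9, Na_mg = 1, Fe_mg = 0.2,
             P_mg = 12, vit_B6_mg = 0.03, vit_B1_mg = 0.01, Cu_mg = 0.08,
             Zn_mg = 0.1, vit_B3_mg = 0.16, vit_A_ug = 1, vit_B2_mg = 0.03),
    toy_item("banana", energy_kcal = 89, protein_g = 1.1, carbohydrate_g = 23,
             soluble_sugars_g = 12, fat_g = 0.3, fibre_g = 2.6, vit_C_mg = 9,
             K_mg = 358, vit_B6_mg = 0.37, vit_B9_ug = 20, Ca_mg = 5,
             Na_mg = 1, Fe_mg = 0.3, P_mg = 22, vit_B1_mg = 0.03, Cu_mg = 0.08,
             Zn_mg = 0.15, vit_B3_mg = 0.67, vit_A_ug = 3, vit_B2_mg = 0.07),
    toy_item("orange", energy_kcal = 47, protein_g = 0.9, carbohydrate_g = 12,
             soluble_sugars_g = 9, fat_g = 0.1, fibre_g = 2.4, vit_C_mg = 53,
             K_mg = 181, vit_B9_ug = 30, Ca_mg = 40, Na_mg = 0, Fe_mg = 0.1,
             P_mg = 14, vit_B6_mg = 0.06, vit_B1_mg = 0.09, Cu_mg = 0.05,
             Zn_mg = 0.07, vit_B3_mg = 0.28, vit_A_ug = 11, vit_B2_mg = 0.04),
    toy_item("cake", energy_kcal = 380, protein_g = 5, carbohydrate_g = 55,
             soluble_sugars_g = 30, fat_g = 15, cholesterol_mg = 60,
             fibre_g = 1, Na_mg = 300, Ca_mg = 60, Fe_mg = 1, K_mg = 90,
             P_mg = 120, vit_A_ug = 100, vit_B2_mg = 0.15, vit_B1_mg = 0.05,
             vit_B9_ug = 10, vit_B12_ug = 0.2, vit_D_ug = 0.5, Zn_mg = 0.5,
             Cu_mg = 0.05, vit_B6_mg = 0.04, vit_B3_mg = 0.4),
    toy_item("pizza", energy_kcal = 250, protein_g = 10, carbohydrate_g = 32,
             soluble_sugars_g = 3, fat_g = 9, cholesterol_mg = 15, fibre_g = 2,
             Na_mg = 550, Ca_mg = 150, Fe_mg = 1.2, K_mg = 170, P_mg = 160,
             vit_A_ug = 75, vit_B2_mg = 0.15, vit_B1_mg = 0.1, vit_B9_ug = 25,
             vit_B12_ug = 0.3, vit_C_mg = 2, vit_D_ug = 0.1, Zn_mg = 1.2,
             Cu_mg = 0.1, vit_B6_mg = 0.09, vit_B3_mg = 1.6))
}

preset_menu_library <- function() memo("menu_library", build_menu_library)

build_menu_library <- function() {
  dishes <- data.frame(
    dish_id = c("pasta_tomato", "rice_oil", "potato_gnocchi", "pasta_oil",
                "bread_roll",
                "beef_roast", "baked_cod", "cheese_plate", "legume_stew",
                "omelette",
                "carrot_salad", "zucchini_saute", "green_salad",
                "apple_fruit", "pear_fruit", "banana_fruit", "orange_fruit",
                "sponge_cake", "margherita_pizza"),
    name = c("Pasta with tomato sauce", "Rice with olive oil",
             "Potato gnocchi with tomato", "Pasta with olive oil",
             "Bread roll", "Roast beef", "Baked cod", "Cheese plate",
             "Legume stew", "Omelette", "Carrot salad", "Sauteed zucchini",
             "Green salad", "Apple", "Pear", "Banana", "Orange",
             "Sponge cake", "Margherita pizza"),
    category = c(rep("starchy", 4), "bread", rep("protein", 5),
                 rep("vegetable", 3), rep("fruit", 4), "dessert", "other"))
  recipes <- rbind(
    data.frame(dish_id = "pasta_tomato",
               food_item_id = c("pasta", "tomato_sauce", "olive_oil"),
               grams_per_serving = c(90, 25, 5)),
    data.frame(dish_id = "rice_oil", food_item_id = c("rice", "olive_oil"),
               grams_per_serving = c(113, 7)),
    data.frame(dish_id = "potato_gnocchi",
               food_item_id = c("potato", "tomato_sauce", "olive_oil"),
               grams_per_serving = c(95, 20, 5)),
    data.frame(dish_id = "pasta_oil", food_item_id = c("pasta", "olive_oil"),
               grams_per_serving = c(112, 8)),
    data.frame(dish_id = "bread_roll", food_item_id = "bread_white",
               grams_per_serving = 50),
    data.frame(dish_id = "beef_roast", food_item_id = c("beef", "olive_oil"),
               grams_per_serving = c(92, 8)),
    data.frame(dish_id = "baked_cod", food_item_id = c("fish_cod", "olive_oil"),
               grams_per_serving = c(92, 8)),
    data.frame(dish_id = "cheese_plate", food_item_id = "cheese",
               grams_per_serving = 100),
    data.frame(dish_id = "legume_stew",
               food_item_id = c("legumes", "tomato_sauce"),
               grams_per_serving = c(88, 12)),
    data.frame(dish_id = "omelette", food_item_id = c("egg", "olive_oil"),
               grams_per_serving = c(93, 7)),
    data.frame(dish_id = "carrot_salad",
               food_item_id = c("carrot", "olive_oil"),
               grams_per_serving = c(75, 5)),
    data.frame(dish_id = "zucchini_saute",
               food_item_id = c("zucchini", "olive_oil"),
               grams_per_serving = c(75, 5)),
    data.frame(dish_id = "green_salad", food_item_id = c("salad", "olive_oil"),
               grams_per_serving = c(72, 8)),
    data.frame(dish_id = "apple_fruit", food_item_id = "apple",
               grams_per_serving = 150),
    data.frame(dish_id = "pear_fruit", food_item_id = "pear",
               grams_per_serving = 150),
    data.frame(dish_id = "banana_fruit", food_item_id = "banana",
               grams_per_serving = 150),
    data.frame(dish_id = "orange_fruit", food_item_id = "orange",
               grams_per_serving = 150),
    data.frame(dish_id = "sponge_cake", food_item_id = "cake",
               grams_per_serving = 100),
    data.frame(dish_id = "margherita_pizza", food_item_id = "pizza",
               grams_per_serving = 250))
  list(dishes = dishes, recipes = recipes)
}

preset_factors <- function() {
  cats <- pw_categories
  prod <- c(starchy = 1.7, bread = 1.1, protein = 3.5, vegetable = 0.55,
            fruit = 0.45, dessert = 2.4, other = 2.3)
  rbind(
    data.frame(scope = cats, scope_type = "category",
               production_ef_kgco2e_per_kg = prod[cats],
               transport_ef_kgco2e_per_kg_km = 0.0045,
               disposal_ef_kgco2e_per_kg = 0),
    data.frame(scope = "beef", scope_type = "item",
               production_ef_kgco2e_per_kg = 8.5,
               transport_ef_kgco2e_per_kg_km = 0.0045,
               disposal_ef_kgco2e_per_kg = 0),
    data.frame(scope = "composting", scope_type = "disposal",
               production_ef_kgco2e_per_kg = 0,
               transport_ef_kgco2e_per_kg_km = 0,
               disposal_ef_kgco2e_per_kg = 0.035))
}

preset_prices <- function() {
  p <- c(pasta = 2.0, rice = 2.2, potato = 1.1, tomato_sauce = 1.8,
         olive_oil = 8.0, bread_white = 4.5, beef = 11.0, fish_cod = 14.0,
         cheese = 9.0, legumes = 3.0, egg = 4.0, carrot = 1.2,
         zucchini = 1.8, salad = 2.5, apple = 1.8, pear = 2.0, banana = 1.7,
         orange = 1.6, cake = 6.0, pizza = 5.0)
  data.frame(scope = names(p), scope_type = "item", price_eur_per_kg = p,
             row.names = NULL)
}

# Illustrative school-lunch bounds; placeholder values, not a transcription
# of any national standard.
preset_guidelines <- function() {
  data.frame(
    quantity = c("energy_kcal", "protein_g", "fibre_g", "vit_C_mg", "Ca_mg",
                 "Fe_mg", "Na_mg", "protein_pct_energy", "fat_pct_energy",
                 "carbohydrate_pct_energy"),
    lower = c(600, 15, 5, 10, 200, 2.5, NA, 10, 25, 45),
    upper = c(850, NA, NA, NA, NA, NA, 1000, 15, 35, 60),
    units = c("kcal", "g", "g", "mg", "mg", "mg", "mg", "pct", "pct", "pct"),
    basis = "both")
}

#' Default two-case campaign specification
#'
#' Builds the shipped specification: two procurement cases with 20 and 19
#' collection day-units over two schools each, seven categories with planted
#' daily waste-fraction means chosen so the expected total waste percentage
#' is about 24 % in case A and about 42 % in case B, with fruit and
#' vegetable fractions above 0.5 in case B. Children counts are uniform in
#' 140-220 per day-unit; daily fractions use Beta concentration 50 (day-to-day
#' SD of roughly 5-7 percentage points). Composition, emission-factor, price
#' and guideline tables are internally consistent toy values.
#'
#' @param seed Integer seed (default 20170901).
#' @param n_days Length-2 integer vector of day-units per case (default
#'   `c(20, 19)`).
#' @return A `pw_campaign_spec`.
#' @export
paperlike_preset <- function(seed = 20170901, n_days = c(20, 19)) {
  frac_a <- c(starchy = 0.18, bread = 0.30, protein = 0.10, vegetable = 0.40,
              fruit = 0.30, dessert = 0.15, other = 0.10)
  frac_b <- c(starchy = 0.35, bread = 0.40, protein = 0.28, vegetable = 0.55,
              fruit = 0.55, dessert = 0.20, other = 0.118)
  category_params <- data.frame(
    category = pw_categories,
    serving_mean_g = c(120, 50, 100, 80, 150, 100, 250),
    serving_sd_g = c(8, 4, 7, 6, 10, 6, 15),
    concentration = 50)
  cases <- list(
    list(case_id = "CASE_A", n_days = n_days[1], n_schools = 2,
         children_range = c(140, 220), waste_fractions = frac_a,
         dessert_every = 10, other_every = 7,
         transport_distance_km = 6, full_price_eur = 6.2,
         procurement_budget_eur = 5000),
    list(case_id = "CASE_B", n_days = n_days[2], n_schools = 2,
         children_range = c(140, 220), waste_fractions = frac_b,
         dessert_every = 5, other_every = 7,
         transport_distance_km = 12, full_price_eur = 5.0,
         procurement_budget_eur = 4500))
  campaign_spec(seed = seed, cases = cases, category_params = category_params,
                menu_library = preset_menu_library(),
                composition = preset_composition(),
                factors = preset_factors(), prices = preset_prices(),
                guidelines = preset_guidelines(),
                disposal_method = "composting")
}

#' Write a generated campaign plus its ground truth to disk
#'
#' @param generated Output of [generate_campaign()].
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_generated_campaign <- function(generated, dir) {
  write_campaign(generated$campaign, dir)
  jsonlite::write_json(generated$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
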
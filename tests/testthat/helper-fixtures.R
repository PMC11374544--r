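# Fixtures are built in code: a hand-sized single-case campaign for unit
# tests, a shrunken randomized campaign factory for property suites, and
# independent oracles (pair-counting permutation test, integer-arithmetic
# weighted means) used to cross-check the implementation.

tiny_composition <- function() {
  rbind(
    as.data.frame(c(list(food_item_id = "unit_item"),
                    as.list(unclass(nutrient_profile(energy_kcal = 200))))),
    as.data.frame(c(list(food_item_id = "item_a"),
                    as.list(unclass(nutrient_profile(
                      energy_kcal = 100, protein_g = 10, Ca_mg = 50))))),
    as.data.frame(c(list(food_item_id = "item_b"),
                    as.list(unclass(nutrient_profile(
                      energy_kcal = 300, fat_g = 20, Fe_mg = 2))))))
}

# one case, one day-unit, one starchy dish of 100 g unit_item
minimal_campaign <- function(waste_g = 2500, children = 100,
                             avg_serving = 100) {
  dishes <- data.frame(dish_id = "d1", name = "Unit dish",
                       category = "starchy",
                       serving1_g = avg_serving, serving2_g = avg_serving,
                       serving3_g = avg_serving, avg_serving_g = avg_serving)
  camp <- structure(list(
    observations = data.frame(date = "2023-01-09", school_id = "s1",
                              case_id = "X", category = "starchy",
                              waste_mass_g = waste_g,
                              children_served = children),
    menus = data.frame(date = "2023-01-09", school_id = "s1", case_id = "X",
                       dish_id = "d1"),
    dishes = dishes,
    recipes = data.frame(dish_id = "d1", food_item_id = "unit_item",
                         grams_per_serving = 100),
    composition = tiny_composition(),
    factors = rbind(
      data.frame(scope = "starchy", scope_type = "category",
                 production_ef_kgco2e_per_kg = 3.54,
                 transport_ef_kgco2e_per_kg_km = 0.0045,
                 disposal_ef_kgco2e_per_kg = 0),
      data.frame(scope = "composting", scope_type = "disposal",
                 production_ef_kgco2e_per_kg = 0,
                 transport_ef_kgco2e_per_kg_km = 0,
                 disposal_ef_kgco2e_per_kg = 0.035)),
    prices = data.frame(scope = "unit_item", scope_type = "item",
                        price_eur_per_kg = 2),
    guidelines = data.frame(quantity = "energy_kcal", lower = 100, upper = NA,
                            units = "kcal", basis = "both"),
    config = list(cases = list(list(case_id = "X", transport_distance_km = 5,
                                    full_price_eur = 5,
                                    procurement_budget_eur = 1000)),
                  disposal_method = "composting")),
    class = "pw_campaign")
  validate_campaign(camp)
  camp
}

# shrunken randomized campaign: one case, few day-units, random planted
# fractions; reuses the preset menu library and tables
small_random_campaign <- function(seed, n_days = 2) {
  spec <- paperlike_preset(seed = seed)
  fr <- stats::runif(7, 0.02, 0.9)
  names(fr) <- pw_categories
  spec$cases <- list(modifyList(spec$cases[[1]], list(
    n_days = n_days, n_schools = 1,
    waste_fractions = fr,
    dessert_every = 2, other_every = 3)))
  spec$category_params$concentration <- stats::runif(1, 10, 100)
  generate_campaign(spec, seed = seed)
}

# independent Mann-Whitney oracle: enumerate every split of the pooled
# values and count x>y pairs directly (no ranks)
mwu_permutation_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); N <- length(pooled)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  centre <- n1 * (N - n1) / 2
  combos <- utils::combn(N, n1)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  list(U = u_obs, p_value = mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9))
}

# integer-arithmetic weighted-mean oracle: masses in integer grams, prices in
# integer cents/kg; returns EUR/kg. Products and sums of moderate integers
# are exact in doubles, so this is an exact-fraction computation.
weighted_mean_oracle <- function(mass_g_int, price_cents_int) {
  num <- sum(as.numeric(mass_g_int) * as.numeric(price_cents_int))
  den <- sum(as.numeric(mass_g_int))
  (num / den) / 100
}
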
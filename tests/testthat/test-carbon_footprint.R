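test_that("production emissions are mass x factor with item override", {
  camp <- minimal_campaign()
  zero <- production_emissions(
    data.frame(food_item_id = "unit_item", category = "starchy", mass_kg = 0),
    camp)
  expect_equal(unname(zero[["starchy"]]), 0)

  # 10 kg at EF 3.54 kgCO2e/kg -> 35.4 kgCO2e
  e <- production_emissions(
    data.frame(food_item_id = "unit_item", category = "starchy", mass_kg = 10),
    camp)
  expect_equal(unname(e[["starchy"]]), 35.4)

  # mixed-item category equals the item-wise brute-force sum; item-level
  # factor rows override the category row
  camp$factors <- rbind(camp$factors,
                        data.frame(scope = "item_a", scope_type = "item",
                                   production_ef_kgco2e_per_kg = 9,
                                   transport_ef_kgco2e_per_kg_km = 0.001,
                                   disposal_ef_kgco2e_per_kg = 0))
  masses <- data.frame(food_item_id = c("unit_item", "item_a", "item_b"),
                       category = "starchy", mass_kg = c(2, 3, 4))
  got <- production_emissions(masses, camp)
  expect_equal(unname(got[["starchy"]]), 2 * 3.54 + 3 * 9 + 4 * 3.54)

  expect_error(
    production_emissions(data.frame(food_item_id = "x", category = "fruit",
                                    mass_kg = 1), camp),
    class = "pw_integrity_error")
})

test_that("transport and disposal emissions are linear in mass and distance", {
  camp <- minimal_campaign()
  m <- data.frame(food_item_id = "unit_item", category = "starchy",
                  mass_kg = 5)
  td0 <- transport_and_disposal_emissions(m, camp, distance_km = 0,
                                          disposal_ef_kg = 0.035)
  expect_equal(unname(td0$transport_kgco2e[["starchy"]]), 0)

  td <- transport_and_disposal_emissions(m, camp, 10, 0.035)
  m2 <- transform(m, mass_kg = 10)
  td2 <- transport_and_disposal_emissions(m2, camp, 10, 0.035)
  expect_equal(unname(td2$transport_kgco2e[["starchy"]]),
               2 * unname(td$transport_kgco2e[["starchy"]]))
  expect_equal(unname(td2$disposal_kgco2e[["starchy"]]),
               2 * unname(td$disposal_kgco2e[["starchy"]]))
  expect_equal(unname(td$transport_kgco2e[["starchy"]]), 5 * 0.0045 * 10)
  expect_equal(unname(td$disposal_kgco2e[["starchy"]]), 5 * 0.035)
})

test_that("per-serving factors use the starchy/bread mean divisor", {
  expect_equal(per_serving_factor(0, 123), 0)
  # reconstructed serving counts whose mean is the printed divisor
  expect_equal(mean(c(4000, 3514)), 3757)
  expect_equal(per_serving_factor(100, mean(c(4000, 3514))), 100 / 3757)
  set.seed(3)
  for (i in 1:25) {
    tot <- stats::runif(1, 0, 500); n <- sample.int(5000, 1)
    expect_identical(per_serving_factor(tot, n), tot / n)
  }
  expect_error(per_serving_factor(1, 0), class = "pw_undefined_ratio")
})

test_that("waste share of supply reproduces the printed percentages", {
  expect_equal(waste_share_of_supply(100, 100), 100)
  expect_equal(round(waste_share_of_supply(758.3, 3991), 1), 19.0)
  expect_equal(round(waste_share_of_supply(781.2, 2790), 1), 28.0)
  expect_error(waste_share_of_supply(1, 0), class = "pw_undefined_ratio")
})

test_that("emission accounts are additive and reproduce the EF ordering", {
  gen <- generate_campaign(paperlike_preset(seed = 6))
  accounts <- day_accounts(gen$campaign)
  for (cid in c("CASE_A", "CASE_B")) {
    em <- emission_account(gen$campaign, cid, accounts)
    pc <- em$per_category
    # additivity at both levels
    expect_equal(pc$total_kgco2e,
                 pc$production_kgco2e + pc$transport_kgco2e +
                   pc$disposal_kgco2e)
    expect_equal(em$totals$total_kgco2e, sum(pc$total_kgco2e))
    expect_equal(em$totals$production_kgco2e, sum(pc$production_kgco2e))
    # qualitative ordering: protein dishes highest per kg of waste,
    # fruit/vegetables lowest
    ef <- setNames(pc$avg_ef_per_kg_waste, pc$category)
    expect_equal(names(which.max(ef)), "protein")
    expect_true(all(sort(ef)[1:2] %in% ef[c("fruit", "vegetable")]))
    # component split: transport and disposal are small shares of the total
    expect_lt(em$totals$transport_kgco2e / em$totals$total_kgco2e, 0.08)
    expect_lt(em$totals$disposal_kgco2e / em$totals$total_kgco2e, 0.08)
  }
})

test_that("emissions scale linearly with waste masses", {
  gen <- small_random_campaign(seed = 21, n_days = 2)
  camp <- gen$campaign
  em1 <- emission_account(camp, camp$config$cases[[1]]$case_id)
  camp2 <- camp
  camp2$observations$waste_mass_g <- camp2$observations$waste_mass_g * 0.5
  em2 <- emission_account(camp2, camp$config$cases[[1]]$case_id)
  expect_equal(em2$totals$total_kgco2e, 0.5 * em1$totals$total_kgco2e)
  expect_equal(em2$totals$avg_ef_per_kg_waste, em1$totals$avg_ef_per_kg_waste)
})
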
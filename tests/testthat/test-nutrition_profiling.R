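test_that("dish profiles follow the composition table exactly", {
  camp <- minimal_campaign()
  # 100 g of an item with 200 kcal/100 g
  expect_equal(unclass(dish_profile("d1", camp))[["energy_kcal"]], 200)

  # two-item dish, 50 g each -> mean of the two per-100g profiles
  camp$recipes <- data.frame(dish_id = "d1",
                             food_item_id = c("item_a", "item_b"),
                             grams_per_serving = c(50, 50))
  p <- dish_profile("d1", camp)
  comp <- camp$composition
  a <- as.numeric(comp[comp$food_item_id == "item_a", pw_nutrients])
  b <- as.numeric(comp[comp$food_item_id == "item_b", pw_nutrients])
  expect_equal(as.numeric(unclass(p)), (a + b) / 2)

  camp$recipes$food_item_id <- c("item_a", "nope")
  expect_error(dish_profile("d1", camp), "nope", class = "pw_integrity_error")
})

test_that("random recipes match the integer-arithmetic summation oracle", {
  set.seed(5)
  for (rep in 1:20) {
    n_items <- 5
    ids <- paste0("it", seq_len(n_items))
    # integer composition (per 100 g) and integer grams keep doubles exact
    compvals <- matrix(sample.int(500, n_items * length(pw_nutrients),
                                  replace = TRUE),
                       nrow = n_items)
    comp <- data.frame(food_item_id = ids)
    comp[pw_nutrients] <- as.data.frame(compvals)
    grams <- sample.int(200, n_items)
    camp <- minimal_campaign()
    camp$composition <- comp
    camp$recipes <- data.frame(dish_id = "d1", food_item_id = ids,
                               grams_per_serving = grams)
    got <- as.numeric(unclass(dish_profile("d1", camp)))
    oracle <- as.numeric(t(compvals) %*% as.numeric(grams)) / 100
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("waste profiles are proportional to the served category mix", {
  camp <- minimal_campaign()
  zero <- waste_profile(0, "d1", 100, camp)
  expect_equal(sum(unclass(zero)), 0)

  full <- waste_profile(100 * 100, "d1", 100, camp)     # waste == served
  expect_equal(unclass(full)[["energy_kcal"]], 200 * 100)

  quarter <- waste_profile(0.25 * 100 * 100, "d1", 100, camp)
  expect_equal(as.numeric(unclass(quarter)),
               0.25 * as.numeric(unclass(dish_profile("d1", camp))) * 100)

  expect_error(waste_profile(10, character(0), 100, camp),
               class = "pw_validation_error")
})

test_that("menu nutrition conserves components and bounds losses", {
  # zero-waste day: intake = served, all losses 0
  camp0 <- minimal_campaign(waste_g = 0)
  mn0 <- menu_nutrition("2023-01-09", "s1", camp0)
  expect_equal(unclass(mn0$intake), unclass(mn0$served), ignore_attr = TRUE)
  expect_equal(unname(mn0$loss_pct[!is.na(mn0$loss_pct)]),
               rep(0, sum(!is.na(mn0$loss_pct))))

  # uniform 50 % waste -> 50 % loss on every served component
  gen <- generate_campaign(local({
    sp <- paperlike_preset(seed = 2)
    for (i in seq_along(sp$cases)) {
      sp$cases[[i]]$waste_fractions[] <- 0.5
    }
    sp$category_params$concentration <- Inf
    sp
  }))
  nut <- campaign_nutrition(gen$campaign)
  loss <- as.matrix(nut[, paste0("loss_", pw_nutrients)])
  expect_equal(unname(loss[!is.na(loss)]),
               rep(50, sum(!is.na(loss))), tolerance = 1e-9)

  # conservation pre-flooring: served = wasted + intake when nothing floored
  gen2 <- small_random_campaign(seed = 33, n_days = 3)
  nut2 <- campaign_nutrition(gen2$campaign)
  expect_true(all(nut2$n_floored == 0))
  for (comp in pw_nutrients) {
    expect_equal(nut2[[paste0("served_", comp)]],
                 nut2[[paste0("wasted_", comp)]] +
                   nut2[[paste0("intake_", comp)]],
                 tolerance = 1e-12, label = comp)
  }
})

test_that("losses are monotone in waste and bounded by category fractions", {
  gen <- small_random_campaign(seed = 44, n_days = 2)
  camp <- gen$campaign
  accounts <- day_accounts(camp)
  key <- unique(accounts[, c("date", "school_id")])[1, ]
  mn <- menu_nutrition(key$date, key$school_id, camp, accounts)

  # mixture bound: each loss component within the day's category fractions
  day_acc <- accounts[accounts$date == key$date &
                        accounts$school_id == key$school_id, ]
  fr <- day_acc$waste_g / day_acc$served_g
  loss <- mn$loss_pct[!is.na(mn$loss_pct)] / 100
  expect_true(all(loss >= min(fr) - 1e-12 & loss <= max(fr) + 1e-12))

  # monotonicity: bump one category's waste, no loss component decreases
  camp2 <- camp
  sel <- camp2$observations$date == key$date &
    camp2$observations$school_id == key$school_id
  bump <- which(sel)[1]
  camp2$observations$waste_mass_g[bump] <-
    camp2$observations$waste_mass_g[bump] * 1.2
  mn2 <- menu_nutrition(key$date, key$school_id, camp2)
  ok <- !is.na(mn$loss_pct)
  expect_true(all(mn2$loss_pct[ok] >= mn$loss_pct[ok] - 1e-12))
})
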
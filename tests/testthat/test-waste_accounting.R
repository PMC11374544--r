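test_that("elementary accounting operations match hand arithmetic", {
  expect_equal(served_mass(120, 100), 12000)
  expect_equal(served_mass(mean(c(100, 110, 120)), 10), 1100)
  expect_equal(served_mass(87.5, 1), 87.5)
  expect_error(served_mass(0, 10), class = "pw_validation_error")

  expect_equal(waste_percentage(0, 5000), 0)
  expect_equal(waste_percentage(5000, 5000), 100)
  expect_equal(waste_percentage(1250, 5000), 25)
  expect_error(waste_percentage(1, 0), class = "pw_undefined_ratio")

  expect_equal(per_child(500, 5), 100)
  expect_equal(per_child(0, 7), 0)
  # exact-fraction oracle: integer grams / integer children
  set.seed(11)
  for (i in 1:50) {
    w <- sample.int(1e6, 1); n <- sample.int(500, 1)
    expect_identical(per_child(w, n), as.numeric(w) / as.numeric(n))
  }

  expect_equal(as.numeric(intake_per_child(150, 50)), 100)
  expect_equal(as.numeric(intake_per_child(150, 150)), 0)
  floored <- intake_per_child(150, 160)
  expect_equal(as.numeric(floored), 0)
  expect_true(attr(floored, "flagged"))
})

test_that("day accounts obey mass conservation and flag anomalies", {
  camp <- minimal_campaign(waste_g = 2500, children = 100, avg_serving = 100)
  acc <- day_accounts(camp)
  expect_equal(acc$served_g, 10000)
  expect_equal(acc$waste_pct, 25)
  expect_equal(acc$waste_per_child_g, 25)
  expect_equal(acc$intake_per_child_g, 75)
  # conservation: served = waste + children * intake (no flag raised)
  expect_false(acc$flag_neg_intake)
  expect_equal(acc$served_g, acc$waste_g + acc$children * acc$intake_per_child_g)

  over <- day_accounts(minimal_campaign(waste_g = 11000))
  expect_true(over$flag_waste_gt_served)
  expect_true(over$flag_neg_intake)
  expect_gt(over$waste_pct, 100)   # flagged, never clipped
  expect_equal(over$intake_per_child_g, 0)
})

test_that("aggregation is order-invariant, additive and scale-equivariant", {
  gen <- small_random_campaign(seed = 101, n_days = 4)
  acc <- day_accounts(gen$campaign)
  agg <- aggregate_case(acc)

  # brute-force summation oracle over raw records
  expect_equal(agg$totals$waste_kg, sum(acc$waste_g) / 1000)
  expect_equal(agg$totals$served_kg, sum(acc$served_g) / 1000)
  expect_equal(agg$totals$waste_per_day_kg,
               sum(acc$waste_g) / 1000 / nrow(agg$daily))

  # permutation invariance
  set.seed(1)
  agg2 <- aggregate_case(acc[sample(nrow(acc)), ])
  expect_equal(agg2$totals, agg$totals)
  pc1 <- agg$per_category[order(agg$per_category$category),
                          c("served_kg", "waste_kg", "waste_pct")]
  pc2 <- agg2$per_category[order(agg2$per_category$category),
                           c("served_kg", "waste_kg", "waste_pct")]
  expect_equal(pc1, pc2, ignore_attr = TRUE)

  # scaling all masses by k scales totals by k, waste_pct unchanged
  k <- 3.5
  scaled <- acc
  for (col in c("served_g", "waste_g", "serving_g", "waste_per_child_g",
                "intake_per_child_g")) scaled[[col]] <- scaled[[col]] * k
  aggk <- aggregate_case(scaled)
  expect_equal(aggk$totals$waste_kg, k * agg$totals$waste_kg)
  expect_equal(aggk$totals$served_kg, k * agg$totals$served_kg)
  expect_equal(aggk$totals$waste_pct, agg$totals$waste_pct)

  mixed <- acc
  mixed$case_id <- rep_len(c("A", "B"), nrow(mixed))
  expect_error(aggregate_case(mixed), class = "pw_validation_error")
})

test_that("two equal day-units double totals and fix the daily median", {
  camp <- minimal_campaign()
  camp$observations <- rbind(camp$observations,
                             transform(camp$observations, date = "2023-01-10"))
  camp$menus <- rbind(camp$menus,
                      transform(camp$menus, date = "2023-01-10"))
  agg1 <- aggregate_case(day_accounts(minimal_campaign()))
  agg2 <- aggregate_case(day_accounts(camp))
  expect_equal(agg2$totals$waste_kg, 2 * agg1$totals$waste_kg)
  expect_equal(median(agg2$daily$waste_pct), agg1$daily$waste_pct)
})
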
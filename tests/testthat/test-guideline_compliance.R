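test_that("verdicts use closed bounds and match a brute-force interval test", {
  g <- data.frame(quantity = c("energy_kcal", "protein_g", "Na_mg"),
                  lower = c(600, 15, NA), upper = c(850, NA, 1000),
                  units = c("kcal", "g", "mg"), basis = "both")
  # exactly at the lower bound -> within (closed interval)
  at_bound <- nutrient_profile(energy_kcal = 600, protein_g = 15)
  v <- check_menu(at_bound, g, "as_served")
  expect_equal(v$verdict[v$quantity == "energy_kcal"], "within")
  expect_equal(v$verdict[v$quantity == "protein_g"], "within")

  # all-zero profile -> below every quantity with a lower bound
  v0 <- check_menu(nutrient_profile(), g, "as_served")
  expect_equal(v0$verdict[v0$quantity == "energy_kcal"], "below")
  expect_equal(v0$verdict[v0$quantity == "protein_g"], "below")
  expect_equal(v0$verdict[v0$quantity == "Na_mg"], "within")

  # randomized profiles vs randomized bounds vs brute-force interval oracle
  set.seed(9)
  for (rep in 1:30) {
    val <- stats::runif(3, 0, 1000)
    lo <- ifelse(stats::runif(3) < 0.3, NA, stats::runif(3, 0, 500))
    hi <- ifelse(stats::runif(3) < 0.3, NA, stats::runif(3, 500, 1000))
    gr <- data.frame(quantity = c("energy_kcal", "fibre_g", "K_mg"),
                     lower = lo, upper = hi, units = "x", basis = "both")
    prof <- nutrient_profile(energy_kcal = val[1], fibre_g = val[2],
                             K_mg = val[3])
    got <- check_menu(prof, gr, "as_served")$verdict
    oracle <- vapply(1:3, function(i) {
      if (is.na(lo[i]) && is.na(hi[i])) "no_bound"
      else if (!is.na(lo[i]) && val[i] < lo[i]) "below"
      else if (!is.na(hi[i]) && val[i] > hi[i]) "above"
      else "within"
    }, character(1))
    expect_identical(got, oracle)
  }
})

test_that("energy-share quantities derive from Atwater factors", {
  prof <- nutrient_profile(energy_kcal = 500, protein_g = 25, fat_g = 10,
                           carbohydrate_g = 50)
  g <- data.frame(quantity = c("protein_pct_energy", "fat_pct_energy",
                               "carbohydrate_pct_energy"),
                  lower = c(10, 25, 45), upper = c(25, 35, 60),
                  units = "pct", basis = "both")
  v <- check_menu(prof, g, "as_served")
  expect_equal(v$value, c(100 * 4 * 25 / 500, 100 * 9 * 10 / 500,
                          100 * 4 * 50 / 500))
  expect_error(check_menu(prof, data.frame(quantity = "mystery", lower = 1,
                                           upper = 2, units = "x",
                                           basis = "both"), "as_served"),
               class = "pw_config_error")
})

test_that("compliance shares count bounded menus only", {
  g <- data.frame(quantity = "energy_kcal", lower = 600, upper = NA,
                  units = "kcal", basis = "both")
  mk <- function(e) check_menu(nutrient_profile(energy_kcal = e), g, "as_served")
  all_in <- do.call(rbind, lapply(c(700, 800, 650), mk))
  expect_equal(compliance_share(all_in, "energy_kcal"), 100)
  half <- do.call(rbind, lapply(c(rep(700, 5), rep(100, 5)), mk))
  expect_equal(compliance_share(half, "energy_kcal"), 50)
  nob <- check_menu(nutrient_profile(energy_kcal = 1),
                    data.frame(quantity = "energy_kcal", lower = NA,
                               upper = NA, units = "kcal", basis = "both"),
                    "as_served")
  expect_true(is.na(compliance_share(nob, "energy_kcal")))
})

test_that("waste never improves compliance on lower-bounded quantities", {
  gen <- generate_campaign(paperlike_preset(seed = 12))
  camp <- gen$campaign
  lower_only <- camp$guidelines[!is.na(camp$guidelines$lower) &
                                  is.na(camp$guidelines$upper), ]
  camp$guidelines <- lower_only
  cp <- campaign_compliance(camp)
  for (q in unique(lower_only$quantity)) {
    for (cid in unique(cp$shares$case_id)) {
      s <- cp$shares[cp$shares$case_id == cid & cp$shares$quantity == q, ]
      served <- s$share_pct[s$basis == "as_served"]
      consumed <- s$share_pct[s$basis == "as_consumed"]
      expect_lte(consumed, served)
    }
  }
})

test_that("planted violation rates are recovered within binomial error", {
  # plant a threshold at the q-quantile of simulated served energy, then the
  # as-served compliance share must be ~ (1-q)
  gen <- generate_campaign(paperlike_preset(seed = 77, n_days = c(60, 1)))
  camp <- gen$campaign
  nut <- campaign_nutrition(camp)
  nut <- nut[nut$case_id == "CASE_A", ]
  q <- 0.3
  thr <- unname(stats::quantile(nut$served_energy_kcal, q, type = 7))
  camp$guidelines <- data.frame(quantity = "energy_kcal", lower = thr,
                                upper = NA, units = "kcal", basis = "both")
  cp <- campaign_compliance(camp, campaign_nutrition(camp))
  share <- cp$shares$share_pct[cp$shares$case_id == "CASE_A" &
                                 cp$shares$basis == "as_served"]
  n <- 60
  se <- 100 * sqrt(q * (1 - q) / n)
  expect_lt(abs(share - 100 * (1 - q)), 3 * se + 100 / n)
})
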
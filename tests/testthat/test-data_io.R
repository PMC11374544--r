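test_that("a minimal one-day campaign loads and validates", {
  camp <- minimal_campaign()
  d <- withr::local_tempdir()
  write_campaign(camp, d)
  loaded <- load_campaign(d)
  expect_s3_class(loaded, "pw_campaign")
  expect_equal(nrow(loaded$observations), 1)
  # idempotence
  expect_identical(load_campaign(d)$observations, loaded$observations)
})

test_that("schema and integrity violations are rejected with named errors", {
  camp <- minimal_campaign()
  d <- withr::local_tempdir()
  write_campaign(camp, d)

  # missing column -> schema error naming the column
  obs <- read.csv(file.path(d, "observations.csv"))
  write.csv(obs[, setdiff(names(obs), "waste_mass_g")],
            file.path(d, "observations.csv"), row.names = FALSE)
  expect_error(load_campaign(d), "waste_mass_g", class = "pw_schema_error")
  write.csv(obs, file.path(d, "observations.csv"), row.names = FALSE)

  # recipe item absent from composition -> integrity error naming the item
  camp2 <- minimal_campaign()
  camp2$recipes$food_item_id <- "ghost_item"
  expect_error(validate_campaign(camp2), "ghost_item",
               class = "pw_integrity_error")

  # missing factor for an item/category pair names the scope
  camp3 <- minimal_campaign()
  camp3$factors <- camp3$factors[camp3$factors$scope_type == "disposal", ]
  expect_error(validate_campaign(camp3), "starchy",
               class = "pw_integrity_error")
})

test_that("type-invariant violations are rejected (randomized corruption)", {
  corruptions <- list(
    function(cm) { cm$observations$waste_mass_g <- -1; cm },
    function(cm) { cm$observations$children_served <- 0; cm },
    function(cm) { cm$observations$category <- "sweets"; cm },
    function(cm) { cm$dishes$avg_serving_g <- cm$dishes$avg_serving_g * 1.5; cm },
    function(cm) { cm$dishes$serving2_g <- -5; cm },
    function(cm) { cm$recipes$grams_per_serving <- 0; cm },
    function(cm) { cm$guidelines$lower <- 900; cm$guidelines$upper <- 100; cm },
    function(cm) { cm$observations$date <- "09/01/2023"; cm },
    function(cm) {
      cm$observations <- rbind(cm$observations, cm$observations); cm
    })
  for (i in seq_along(corruptions)) {
    bad <- corruptions[[i]](minimal_campaign())
    expect_error(validate_campaign(bad), class = "pw_error")
  }
})

test_that("write-then-load round-trips a generated campaign bit-identically", {
  gen <- generate_campaign(paperlike_preset(seed = 7))
  d <- withr::local_tempdir()
  write_campaign(gen$campaign, d)
  loaded <- load_campaign(d)
  for (nm in c("observations", "menus", "dishes", "recipes", "composition",
               "factors", "prices", "guidelines")) {
    a <- gen$campaign[[nm]]; b <- loaded[[nm]]
    rownames(a) <- rownames(b) <- NULL
    for (col in names(a)) {
      if (is.numeric(a[[col]])) {
        expect_identical(as.numeric(a[[col]]), as.numeric(b[[col]]),
                         label = paste(nm, col))
      } else {
        expect_equal(as.character(a[[col]]), as.character(b[[col]]),
                     label = paste(nm, col))
      }
    }
  }
})

test_that("report tables are written and re-parse to the in-memory values", {
  res <- analyze_campaign(generate_campaign(paperlike_preset(seed = 3))$campaign)
  d <- withr::local_tempdir()
  files <- write_report_tables(res, d)
  expect_true(file.exists(file.path(d, "results.json")))
  for (nm in names(res$tables)) {
    path <- file.path(d, "tables", paste0(nm, ".csv"))
    expect_true(file.exists(path), label = nm)
    back <- as.data.frame(data.table::fread(path, na.strings = c("NA", "")))
    tab <- res$tables[[nm]]
    rownames(tab) <- NULL
    num <- vapply(tab, is.numeric, logical(1))
    for (col in names(tab)[num]) {
      expect_identical(as.numeric(back[[col]]), as.numeric(tab[[col]]),
                       label = paste(nm, col))
    }
  }
})
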
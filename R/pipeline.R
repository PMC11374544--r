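# End-to-end orchestration: chain accounting, nutrition, compliance, carbon,
# economics and between-case comparison over a loaded campaign, assemble the
# report tables and a machine-readable summary, and record a run manifest.
# Stages communicate through plain tables, so each can also be run standalone.

fmt_round <- function(x, digits = 2) round(x, digits)

#' Analyse a campaign through every pipeline stage
#'
#' @param campaign A validated `pw_campaign`.
#' @return A `pw_results` list: `accounts` (per category-day),
#'   `aggregates` (per case), `nutrition`, `compliance`, `carbon`, `costs`,
#'   `comparisons` (between the first two cases when exactly two are
#'   present), `tables` (report tables mirroring the published layout) and
#'   `summary` (nested list written to results.json).
#' @export
analyze_campaign <- function(campaign) {
  accounts <- day_accounts(campaign)
  case_ids <- unique(accounts$case_id)
  aggregates <- lapply(stats::setNames(case_ids, case_ids), function(cid) {
    aggregate_case(accounts[accounts$case_id == cid, ])
  })
  nutrition <- campaign_nutrition(campaign)
  compliance <- campaign_compliance(campaign, nutrition)
  carbon <- lapply(stats::setNames(case_ids, case_ids), function(cid) {
    emission_account(campaign, cid, accounts)
  })
  costs <- lapply(stats::setNames(case_ids, case_ids), function(cid) {
    cost_account(campaign, cid, accounts)
  })
  comparisons <- if (length(case_ids) == 2) {
    compare_all(aggregates[[1]], aggregates[[2]], nutrition, case_ids)
  } else NULL

  res <- list(accounts = accounts, aggregates = aggregates,
              nutrition = nutrition, compliance = compliance,
              carbon = carbon, costs = costs, comparisons = comparisons)
  res$tables <- build_tables(res)
  res$summary <- build_summary(res)
  structure(res, class = "pw_results")
}

compare_all <- function(agg1, agg2, nutrition, case_ids) {
  out <- list()
  add <- function(x, y, variable) {
    out[[length(out) + 1L]] <<- compare_cases(x, y, variable)
  }
  add(agg1$daily$waste_pct, agg2$daily$waste_pct, "total_waste_pct")
  add(agg1$daily$waste_per_child_g, agg2$daily$waste_per_child_g,
      "total_waste_per_child_g")
  for (cc in pw_categories) {
    s1 <- agg1$per_category[agg1$per_category$category == cc, ]
    s2 <- agg2$per_category[agg2$per_category$category == cc, ]
    if (!nrow(s1) || !nrow(s2)) next
    out[[length(out) + 1L]] <- compare_cases(
      s1$daily_waste_pct[[1]], s2$daily_waste_pct[[1]],
      variable = cc, exclude = c("other", "dessert"))
  }
  n1 <- nutrition[nutrition$case_id == case_ids[1], ]
  n2 <- nutrition[nutrition$case_id == case_ids[2], ]
  for (nut in pw_nutrients) {
    for (basis in c("served", "wasted", "intake", "loss")) {
      col <- paste0(basis, "_", nut)
      x <- n1[[col]]; y <- n2[[col]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) >= 3 && length(y) >= 3 &&
          (stats::sd(x) > 0 || stats::sd(y) > 0)) {
        add(x, y, col)
      }
    }
  }
  out
}

comparisons_table <- function(comparisons) {
  do.call(rbind, lapply(comparisons, function(cm) {
    data.frame(variable = cm$variable, n1 = cm$n1, n2 = cm$n2,
               test = cm$test_used,
               statistic = if (is.null(cm$statistic)) NA else cm$statistic,
               p_value = if (is.null(cm$p_value)) NA else cm$p_value,
               group1 = if (cm$test_used == "skipped") cm$skip_reason
                        else cm$descriptives[["group1"]],
               group2 = if (cm$test_used == "skipped") ""
                        else cm$descriptives[["group2"]],
               row.names = NULL)
  }))
}

build_tables <- function(res) {
  tables <- list()

  # Table 1 analogue: dishes, served and waste masses, waste per day
  tables$table1_masses <- do.call(rbind, lapply(res$aggregates, function(ag) {
    pc <- ag$per_category
    rbind(
      data.frame(case_id = ag$case_id, category = pc$category,
                 n_days = pc$n_days,
                 served_kg = fmt_round(pc$served_kg, 1),
                 waste_kg = fmt_round(pc$waste_kg, 1),
                 waste_per_day_kg = fmt_round(pc$waste_kg / ag$totals$n_days, 2)),
      data.frame(case_id = ag$case_id, category = "total",
                 n_days = ag$totals$n_days,
                 served_kg = fmt_round(ag$totals$served_kg, 1),
                 waste_kg = fmt_round(ag$totals$waste_kg, 1),
                 waste_per_day_kg = fmt_round(ag$totals$waste_per_day_kg, 2)))
  }))

  # Table 2 analogue: daily descriptives of serving size, waste % and waste
  # per child
  med_iqr <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    sprintf("%.1f (%.1f, %.1f)", q[2], q[1], q[3])
  }
  tables$table2_daily <- do.call(rbind, lapply(res$aggregates, function(ag) {
    pc <- ag$per_category
    rbind(
      do.call(rbind, lapply(seq_len(nrow(pc)), function(i) {
        data.frame(case_id = ag$case_id, category = pc$category[i],
                   n = pc$n_days[i],
                   serving_g = med_iqr(pc$daily_serving_g[[i]]),
                   waste_pct = med_iqr(pc$daily_waste_pct[[i]]),
                   waste_per_child_g = med_iqr(pc$daily_waste_per_child_g[[i]]))
      })),
      data.frame(case_id = ag$case_id, category = "total",
                 n = ag$totals$n_days,
                 serving_g = med_iqr(ag$daily$serving_g),
                 waste_pct = med_iqr(ag$daily$waste_pct),
                 waste_per_child_g = med_iqr(ag$daily$waste_per_child_g)))
  }))

  # Tables 3-4 analogue: per-lunch nutrient amounts served/wasted/consumed
  nut <- res$nutrition
  tables$table3_4_nutrition <- do.call(rbind, lapply(
    split(nut, nut$case_id), function(nn) {
      do.call(rbind, lapply(pw_nutrients, function(comp) {
        data.frame(case_id = nn$case_id[1], component = comp, n = nrow(nn),
                   served = fmt_round(mean(nn[[paste0("served_", comp)]]), 2),
                   wasted = fmt_round(mean(nn[[paste0("wasted_", comp)]]), 2),
                   intake = fmt_round(mean(nn[[paste0("intake_", comp)]]), 2))
      }))
    }))

  # Fig 1 analogue: loss percentages (mean+-SD and median (IQR))
  tables$fig1_losses <- do.call(rbind, lapply(
    split(nut, nut$case_id), function(nn) {
      do.call(rbind, lapply(pw_nutrients, function(comp) {
        v <- nn[[paste0("loss_", comp)]]
        v <- v[!is.na(v)]
        if (!length(v)) v <- NA_real_
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7,
                             na.rm = TRUE)
        data.frame(case_id = nn$case_id[1], component = comp,
                   mean = fmt_round(mean(v), 2), sd = fmt_round(stats::sd(v), 2),
                   median = fmt_round(q[2], 2), q1 = fmt_round(q[1], 2),
                   q3 = fmt_round(q[3], 2))
      }))
    }))

  tables$compliance_shares <- res$compliance$shares

  # Table 5 analogue: emission components, totals, per-kg and per-serving EFs
  tables$table5_carbon <- do.call(rbind, lapply(res$carbon, function(em) {
    pc <- em$per_category
    rbind(
      data.frame(case_id = em$case_id, category = pc$category,
                 waste_kg = fmt_round(pc$waste_kg, 1),
                 production_kgco2e = fmt_round(pc$production_kgco2e, 2),
                 transport_kgco2e = fmt_round(pc$transport_kgco2e, 2),
                 disposal_kgco2e = fmt_round(pc$disposal_kgco2e, 2),
                 total_kgco2e = fmt_round(pc$total_kgco2e, 2),
                 avg_ef_per_kg = fmt_round(pc$avg_ef_per_kg_waste, 2),
                 avg_ef_per_serving = fmt_round(pc$avg_ef_per_serving, 4)),
      data.frame(case_id = em$case_id, category = "total",
                 waste_kg = fmt_round(em$totals$waste_kg, 1),
                 production_kgco2e = fmt_round(em$totals$production_kgco2e, 2),
                 transport_kgco2e = fmt_round(em$totals$transport_kgco2e, 2),
                 disposal_kgco2e = fmt_round(em$totals$disposal_kgco2e, 2),
                 total_kgco2e = fmt_round(em$totals$total_kgco2e, 2),
                 avg_ef_per_kg = fmt_round(em$totals$avg_ef_per_kg_waste, 2),
                 avg_ef_per_serving = NA))
  }))

  # Table 6 analogue: waste costs
  tables$table6_costs <- do.call(rbind, lapply(res$costs, function(ca) {
    pc <- ca$per_category
    rbind(
      data.frame(case_id = ca$case_id, category = pc$category,
                 waste_kg = fmt_round(pc$waste_kg, 1),
                 cost_per_kg_eur = fmt_round(pc$cost_per_kg_eur, 2),
                 waste_cost_eur = fmt_round(pc$waste_cost_eur, 2),
                 cost_share_pct = fmt_round(pc$cost_share_pct, 1),
                 avg_cost_per_serving_eur =
                   fmt_round(pc$avg_cost_per_serving_eur, 4)),
      data.frame(case_id = ca$case_id, category = "total",
                 waste_kg = fmt_round(ca$totals$total_waste_kg, 1),
                 cost_per_kg_eur = fmt_round(ca$totals$cost_per_kg_eur, 2),
                 waste_cost_eur = fmt_round(ca$totals$total_cost_eur, 2),
                 cost_share_pct = 100,
                 avg_cost_per_serving_eur = NA))
  }))

  if (!is.null(res$comparisons)) {
    tables$comparisons <- comparisons_table(res$comparisons)
  }
  tables
}

build_summary <- function(res) {
  cases <- lapply(res$aggregates, function(ag) {
    cid <- ag$case_id
    em <- res$carbon[[cid]]; ca <- res$costs[[cid]]
    list(case_id = cid,
         n_days = ag$totals$n_days,
         served_kg = ag$totals$served_kg,
         waste_kg = ag$totals$waste_kg,
         waste_pct = ag$totals$waste_pct,
         waste_per_day_kg = ag$totals$waste_per_day_kg,
         median_daily_waste_pct = stats::median(ag$daily$waste_pct),
         carbon = c(em$totals, em$supply, em$per_meal),
         cost = ca$totals)
  })
  comps <- if (!is.null(res$comparisons)) {
    lapply(res$comparisons, function(cm) {
      list(variable = cm$variable, test = cm$test_used,
           p_value = cm$p_value)
    })
  } else NULL
  list(cases = cases, comparisons = comps)
}

#' Run the full pipeline on a campaign directory
#'
#' Loads (or first simulates) a campaign, runs every analysis stage, writes
#' the report tables, `results.json`, a plain-text run log and a
#' `manifest.json` with input digests so that identical config + inputs +
#' seed yield identical outputs.
#'
#' @param input_dir Directory with the campaign CSVs and `config.yaml`; when
#'   `simulate = TRUE` the directory is created from the default preset
#'   first.
#' @param out_dir Output directory.
#' @param simulate Generate the campaign with [paperlike_preset()] before
#'   analysing.
#' @param seed Seed for simulation (ignored otherwise).
#' @return The `pw_results`, invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir, simulate = FALSE, seed = 1L) {
  t0 <- Sys.time()
  log_lines <- character()
  say <- function(level, ...) {
    line <- sprintf("%s [%s] %s", format(Sys.time(), "%H:%M:%S"), level,
                    paste0(...))
    log_lines <<- c(log_lines, line)
  }
  if (simulate) {
    gen <- generate_campaign(paperlike_preset(seed = seed))
    write_generated_campaign(gen, input_dir)
    say("INFO", "simulated campaign written to ", input_dir)
  }
  campaign <- load_campaign(input_dir)
  say("INFO", "loaded campaign: ", nrow(campaign$observations),
      " observations, ", length(campaign$config$cases), " cases")
  res <- analyze_campaign(campaign)
  for (ag in res$aggregates) {
    say("INFO", sprintf("%s: served %.1f kg, waste %.1f kg (%.1f%%)",
                        ag$case_id, ag$totals$served_kg, ag$totals$waste_kg,
                        ag$totals$waste_pct))
    if (ag$totals$n_flags > 0) {
      say("WARNING", ag$case_id, ": ", ag$totals$n_flags,
          " flagged account rows (waste > served or negative intake)")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- write_report_tables(res, out_dir)
  inputs <- list.files(input_dir, pattern = "\\.(csv|yaml|json)$",
                       full.names = TRUE)
  manifest <- list(
    seed = if (simulate) seed else NULL,
    package_version = as.character(utils::packageVersion("platewaste")),
    input_digests = as.list(tools::md5sum(inputs)),
    outputs = basename(files),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(res)
}
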
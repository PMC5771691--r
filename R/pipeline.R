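#' Configure an end-to-end analysis run
#'
#' Collects every option the pipeline stages need, validates it up front,
#' and fixes the seed. The input can be a path to a measurement file, a
#' tibble of measurement records, a tibble of group summaries (mean/SEM/n
#' cells, as published tables provide), or a [cohort_spec()] to generate a
#' synthetic cohort. The configuration is serialised into every output
#' directory so a run can be reproduced from its artifacts alone.
#'
#' @param input One of: a file path, a measurement-record data frame, a
#'   group-summary data frame (columns `region`, `genotype`, `age_months`,
#'   `mean`, `sem`, `n`), a `cohort_spec`, or `"nhe6"` for the packaged
#'   published summaries.
#' @param regions Regions to fit trajectories for (default cortex and
#'   cerebellum).
#' @param growth_phase_end Months separating growth from degeneration
#'   (default 6).
#' @param control_genotype,test_genotype Genotype labels for baseline and
#'   counterfactual fits.
#' @param atrophy_measures Measure kinds included in the percent-decrease
#'   stage (default the histology measures).
#' @param var_equal Pooled (TRUE, default) or Welch t tests.
#' @param alpha Significance level used for flagging in the report.
#' @param seed Seed for any generation step.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = "nhe6",
                            regions = c("cortex", "cerebellum"),
                            growth_phase_end = 6,
                            control_genotype = "WT",
                            test_genotype = "MUT",
                            atrophy_measures = c("tissue_area", "thickness",
                                                 "width"),
                            var_equal = TRUE,
                            alpha = 0.05,
                            seed = 1L) {
  if (is.null(input) || (is.data.frame(input) && nrow(input) == 0)) {
    abort("pipeline input is empty")
  }
  if (is.character(input) && length(input) == 1 && input != "nhe6" &&
      !file.exists(input)) {
    abort(paste0("input file does not exist: ", input))
  }
  stopifnot(growth_phase_end > 0, alpha > 0, alpha < 1)
  structure(
    list(
      input = input, regions = regions,
      growth_phase_end = growth_phase_end,
      control_genotype = control_genotype, test_genotype = test_genotype,
      atrophy_measures = atrophy_measures,
      var_equal = var_equal, alpha = alpha, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

# Resolve the configured input into a group-summary table.
.pipeline_cells <- function(config) {
  input <- config$input
  if (inherits(input, "cohort_spec")) {
    recs <- gen_cohort(input)
    return(summarize_groups(recs))
  }
  if (is.character(input) && length(input) == 1) {
    if (input == "nhe6") return(nhe6_group_summaries())
    recs <- read_measurements(input)
    return(summarize_groups(recs))
  }
  if (is.data.frame(input)) {
    if (all(c("mean", "sem", "n") %in% names(input))) return(as_tibble(input))
    return(summarize_groups(validate_measurements(input)))
  }
  abort("unsupported pipeline input")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — input resolution, group summaries,
#' baseline trajectory fits, counterfactual fits, atrophy percentages,
#' group statistics, and the report — writing each stage's outputs to
#' `out_dir` before the next stage begins. A failed stage halts the run,
#' leaves the earlier outputs in place, and writes a machine-readable
#' `error.json`. Two runs with the same configuration and seed produce
#' byte-identical numeric tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the stage outputs (`cells`, `fits`,
#'   `coefficients`, `atrophy`, `tests`, `report_path`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(level, msg) {
    cat(sprintf("%s [%s] %s\n",
      format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, msg),
      file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    log_line("INFO", paste0("stage ", name, " start"))
    result <- tryCatch(expr, error = function(e) {
      log_line("ERROR", paste0("stage ", name, " failed: ",
        conditionMessage(e)))
      jsonlite::write_json(
        list(stage = name, error = conditionMessage(e)),
        file.path(out_dir, "error.json"), auto_unbox = TRUE
      )
      abort(paste0("pipeline stage '", name, "' failed: ",
        conditionMessage(e)))
    })
    log_line("INFO", paste0("stage ", name, " done"))
    result
  }

  cfg_serial <- config
  if (inherits(cfg_serial$input, "cohort_spec")) {
    cfg_serial$input <- list(cohort_spec = unclass(cfg_serial$input))
    cfg_serial$input$cohort_spec$trajectories <-
      as.data.frame(cfg_serial$input$cohort_spec$trajectories)
  } else if (is.data.frame(cfg_serial$input)) {
    cfg_serial$input <- "<in-memory data frame>"
  }
  yaml::write_yaml(unclass(cfg_serial), file.path(out_dir, "config.yaml"))
  log_line("INFO", paste0("braintraj ",
    as.character(utils::packageVersion("braintraj")),
    " seed=", config$seed,
    " config_hash=", rlang::hash(config)))

  cells <- stage("summaries", {
    cells <- .pipeline_cells(config)
    write_table(cells, file.path(out_dir, "group_summaries.tsv"))
    cells
  })

  fits <- stage("growth_model", {
    traj <- cells[cells$measure_kind == "gross_area" &
                  cells$region %in% config$regions, ]
    if (nrow(traj) == 0) {
      list()
    } else {
      purrr::map(setNames(config$regions, config$regions), function(rg) {
        d <- traj[traj$region == rg, ]
        ctrl <- d[d$genotype == config$control_genotype, ]
        test <- d[d$genotype == config$test_genotype, ]
        ctrl <- ctrl[order(ctrl$age_months), ]
        test <- test[order(test$age_months), ]
        baseline <- fit_baseline(
          tibble(t = ctrl$age_months, area = ctrl$mean),
          growth_phase_end = config$growth_phase_end,
          region = rg, genotype = config$control_genotype
        )
        mut_anchors <- tibble(t = test$age_months, area = test$mean)
        list(
          baseline = baseline,
          undergrowth = fit_counterfactual(mut_anchors, baseline,
            "undergrowth_only", genotype = config$test_genotype),
          degeneration = fit_counterfactual(mut_anchors, baseline,
            "degeneration_only", genotype = config$test_genotype)
        )
      })
    }
  })

  coefficients <- stage("counterfactuals", {
    coefs <- purrr::map_dfr(fits, function(f) {
      dplyr::bind_rows(tidy(f$baseline), tidy(f$undergrowth),
        tidy(f$degeneration))
    })
    if (nrow(coefs) > 0) {
      write_table(coefs, file.path(out_dir, "coefficients.tsv"))
      write_table(coefs, file.path(out_dir, "coefficients.json"))
    }
    coefs
  })

  atrophy <- stage("atrophy", {
    at <- cells[cells$measure_kind %in% config$atrophy_measures, ]
    if (nrow(at) == 0) {
      tibble()
    } else {
      keys <- intersect(c("measure_kind", "region", "subregion", "age_months"),
        names(at))
      out <- at |>
        dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
        dplyr::group_modify(function(d, key) {
          ref <- d[d$genotype == config$control_genotype, ]
          test <- d[d$genotype == config$test_genotype, ]
          if (nrow(ref) != 1 || nrow(test) != 1) return(tibble())
          percent_decrease(ref[, c("mean", "sem", "n")],
            test[, c("mean", "sem", "n")])
        }) |>
        dplyr::ungroup()
      if (nrow(out) > 0) write_table(out, file.path(out_dir, "atrophy.tsv"))
      out
    }
  })

  tests <- stage("stats", {
    keys <- intersect(
      c("panel", "cohort", "measure_kind", "region", "subregion",
        "age_label", "age_months"),
      names(cells)
    )
    out <- cells |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::group_modify(function(d, key) {
        ref <- d[d$genotype == config$control_genotype, ]
        test <- d[d$genotype == config$test_genotype, ]
        if (nrow(ref) != 1 || nrow(test) != 1) return(tibble())
        if (ref$n + test$n < 3 || (ref$n == 1 && test$n == 1)) return(tibble())
        t_test_two_sample(ref[, c("mean", "sem", "n")],
          test[, c("mean", "sem", "n")], var_equal = config$var_equal)
      }) |>
      dplyr::ungroup()
    if (nrow(out) > 0) {
      out$stars <- p_stars(out$p.value)
      write_table(out, file.path(out_dir, "tests.tsv"))
    }
    out
  })

  outputs <- list(cells = cells, fits = fits, coefficients = coefficients,
    atrophy = atrophy, tests = tests)

  report_path <- stage("report", {
    md <- pipeline_report(outputs, alpha = config$alpha)
    path <- file.path(out_dir, "report.md")
    writeLines(md, path)
    path
  })
  outputs$report_path <- report_path
  log_line("INFO", "run complete")
  invisible(outputs)
}

#' Render a human-readable report of pipeline outputs
#'
#' One markdown document: per-phase coefficient tables for every model
#' variant with infeasibility markers on negative fitted coefficients,
#' percent-decrease summaries, and the group tests with figure-style
#' significance stars. Sections with no content are omitted.
#'
#' @param outputs The list returned by [run_pipeline()] (or a compatible
#'   list with elements `coefficients`, `atrophy`, `tests`).
#' @param alpha Significance level used for in-text flagging.
#' @return The report as a character vector of markdown lines.
#' @export
pipeline_report <- function(outputs, alpha = 0.05) {
  fmt <- function(x) formatC(x, digits = 4, format = "g")
  lines <- c("# Brain-trajectory analysis report", "")
  coefs <- outputs$coefficients
  if (!is.null(coefs) && nrow(coefs) > 0) {
    lines <- c(lines, "## Growth / degeneration coefficients (month^-1)", "")
    lines <- c(lines,
      "| region | variant | interval (mo) | rate | G | D | |",
      "|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(coefs))) {
      r <- coefs[i, ]
      flag <- if (!r$feasible) "INFEASIBLE (negative coefficient)" else ""
      lines <- c(lines, sprintf("| %s | %s | %g-%g | %s | %s | %s | %s |",
        r$region, r$model_variant, r$t_start, r$t_end,
        fmt(r$rate), fmt(r$G), fmt(r$D), flag))
    }
    lines <- c(lines, "")
  }
  atrophy <- outputs$atrophy
  if (!is.null(atrophy) && nrow(atrophy) > 0) {
    lines <- c(lines, "## Percent decrease vs control", "")
    for (i in seq_len(nrow(atrophy))) {
      r <- atrophy[i, ]
      where <- paste(
        stats::na.omit(c(r$region,
          if ("subregion" %in% names(r)) r$subregion else NULL)),
        collapse = " / ")
      lines <- c(lines, sprintf("- %s %s: %.0f%% +/- %.0f%% decrease",
        where, r$measure_kind, r$percent_decrease, r$uncertainty))
    }
    lines <- c(lines, "")
  }
  tests <- outputs$tests
  if (!is.null(tests) && nrow(tests) > 0) {
    lines <- c(lines, "## Group comparisons", "")
    for (i in seq_len(nrow(tests))) {
      r <- tests[i, ]
      where <- paste(
        stats::na.omit(c(r$region,
          if ("subregion" %in% names(r)) r$subregion else NULL)),
        collapse = " / ")
      lines <- c(lines, sprintf(
        "- %s %s at %g mo: t = %.3f, df = %g, p = %.3g %s",
        where, r$measure_kind, r$age_months, r$statistic, r$df, r$p.value,
        p_stars(r$p.value)))
    }
    lines <- c(lines, "")
  }
  lines
}
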
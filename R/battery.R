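#' Build the one-action rule set of a scenario
#'
#' The reference experiment applies a single directive type to a fixed list
#' of prominent features: scenario `"exp_keep"` yields
#' `feature exp-keep name=<features>`, and so on. `"norst"` yields an empty
#' rule set.
#'
#' @param scenario one of the five rule scenarios.
#' @param features character vector of feature names the directive targets.
#' @return A `rst_ruleset`.
#' @export
scenario_rules <- function(scenario, features) {
  if (!scenario %in% RULE_SCENARIOS) {
    abort(paste0("unknown scenario '", scenario, "'"))
  }
  if (scenario == "norst") return(parse_rules(character()))
  parse_rules(sprintf("feature %s name=%s", gsub("_", "-", scenario, fixed = TRUE),
                      paste(features, collapse = ",")))
}

#' Run the full 10-experiment scenario battery on one cohort
#'
#' Runs every combination of DP mode (manual, MLDP) and rule scenario
#' (norst, exp-keep, exp-remove, pref-keep, pref-remove) on byte-identical
#' Monte-Carlo splits (or the single dual-center split) and assembles the
#' comparison table of mean/SD/CI95 balanced accuracy with ANOVA p-values
#' against the norst baseline. A failed experiment is flagged in the table;
#' the battery continues.
#'
#' @param cohort a feature-table tibble.
#' @param input_features the feature names the directives target (e.g. the
#'   planted prominent features of a synthetic twin).
#' @param config an [experiment_config()].
#' @param dp_modes,scenarios subsets to run (defaults: all).
#' @return A `rst_battery`: `$reports` (named list of `rst_eval`),
#'   `$comparison` (one row per experiment), `$splits`.
#' @export
rst_battery <- function(cohort, input_features, config = experiment_config(),
                        dp_modes = c("manual", "mldp"),
                        scenarios = RULE_SCENARIOS) {
  check_feature_table(cohort)
  missing <- setdiff(input_features, feature_names(cohort))
  if (length(missing)) {
    abort(paste0("input_features absent from cohort: ", paste(missing, collapse = ", ")))
  }
  splits <- if (config$dual_center) NULL else {
    make_mccv_splits(cohort, folds = config$folds,
                     test_fraction = config$test_fraction,
                     master_seed = config$master_seed)
  }
  reports <- list()
  failures <- list()
  for (dp in dp_modes) {
    for (sc in scenarios) {
      key <- paste(dp, sc, sep = ".")
      res <- tryCatch(
        run_experiment(cohort, dp_mode = dp, rule_scenario = sc,
                       rules = if (sc == "norst") NULL else scenario_rules(sc, input_features),
                       config = config, splits = splits),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[key]] <- conditionMessage(res)
      } else {
        reports[[key]] <- res
      }
    }
  }
  comparison <- if (length(reports) >= 2) compare_scenarios(reports) else {
    bind_rows(purrr::map(reports, glance))
  }
  if (length(failures)) {
    comparison <- bind_rows(comparison, purrr::imap(failures, function(msg, key) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      tibble(dp_mode = parts[1], rule_scenario = parts[2], n_folds = NA_integer_,
             mean_bacc = NA_real_, sd_bacc = NA_real_, ci95_lo = NA_real_,
             ci95_hi = NA_real_, p_vs_norst = NA_real_)
    }))
  }
  structure(list(reports = reports, comparison = comparison, splits = splits,
                 failures = failures),
            class = "rst_battery")
}

#' @export
print.rst_battery <- function(x, ...) {
  cat("<rst_battery>", length(x$reports), "experiment(s)\n")
  print(as.data.frame(x$comparison), digits = 3)
  invisible(x)
}

#' Audit a rule file against a cohort without running anything
#'
#' Parses, validates and compiles the rules, printing the parse results,
#' conflicts and compiled directive summary.
#'
#' @param rules a `rst_ruleset`, rule text, or a path with `file = TRUE`.
#' @param cohort a feature-table tibble or a cohort CSV path.
#' @param file interpret character inputs as file paths.
#' @return Invisibly, `list(ruleset, conflicts, directives)`; aborts on
#'   fatal conflicts.
#' @export
rst_validate_rules <- function(rules, cohort, file = FALSE) {
  rs <- if (inherits(rules, "rst_ruleset")) rules else parse_rules(rules, file = file)
  tbl <- if (is.character(cohort)) read_feature_table(cohort) else cohort
  print(rs)
  confl <- validate_rules(rs)
  if (nrow(confl)) {
    cat("conflicts:\n")
    print(as.data.frame(confl[c("scope", "target", "type", "severity")]))
  } else {
    cat("no conflicts\n")
  }
  d <- compile_rules(rs, tbl) # aborts on fatal conflicts / unknown explicit names
  print(d)
  invisible(list(ruleset = rs, conflicts = confl, directives = d))
}

#' Write an evaluation report to JSON and CSV
#'
#' @param report a `rst_eval`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return The directory, invisibly.
#' @export
write_eval_report <- function(report, dir, stem = paste(report$dp_mode,
                                                        report$rule_scenario,
                                                        sep = "_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tidy(report), file.path(dir, paste0(stem, "_folds.csv")))
  jsonlite::write_json(
    list(dp_mode = report$dp_mode, rule_scenario = report$rule_scenario,
         classifier = report$classifier, master_seed = report$master_seed,
         aggregate = glance(report), folds = report$folds,
         selected_features = report$selected,
         pipelines = purrr::map(report$pipelines, function(s) {
           if (is.null(s)) NULL else s$steps
         })),
    file.path(dir, paste0(stem, ".json")), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
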
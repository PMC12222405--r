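#' Monte-Carlo cross-validation splits with split reuse
#'
#' Repeated stratified random train/test splits, fully determined by
#' `(n, folds, test_fraction, master_seed)` so every experiment on a cohort
#' reuses byte-identical splits. The test size is `round_half_up(test_fraction
#' * n)`; per-class test counts follow the largest-remainder rule, and both
#' classes are guaranteed present in both parts.
#'
#' @param table a feature-table tibble.
#' @param folds number of Monte-Carlo repetitions.
#' @param test_fraction test fraction in (0, 0.5).
#' @param master_seed integer master seed.
#' @return Tibble with columns `fold`, `train_ids`, `test_ids` (list
#'   columns), `seed`.
#' @export
make_mccv_splits <- function(table, folds = 100, test_fraction = 0.2,
                             master_seed = 1L) {
  check_feature_table(table)
  n <- nrow(table)
  if (n < 10) abort("need n >= 10 samples")
  if (test_fraction <= 0 || test_fraction >= 0.5) {
    abort("test_fraction must be in (0, 0.5)")
  }
  y <- table$label
  if (any(table(y) < 2)) {
    abort("a class is too small to appear in both train and test parts")
  }
  n_test <- round_half_up(test_fraction * n)
  ## largest-remainder per-class allocation, each class >= 1 in both parts
  cls <- levels(y)
  n_cls <- as.integer(table(y)[cls])
  exact <- n_cls * n_test / n
  base <- floor(exact)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(-(exact - base))[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  base <- pmax(pmin(base, n_cls - 1L), 1L)
  purrr::map(seq_len(folds), function(f) {
    fseed <- derive_seed(master_seed, "mccv", f)
    test_ids <- with_seed(fseed, {
      unlist(lapply(seq_along(cls), function(ci) {
        ids <- table$sample_id[y == cls[ci]]
        sample(ids, base[ci])
      }))
    })
    tibble(fold = f, train_ids = list(setdiff(table$sample_id, test_ids)),
           test_ids = list(lex_order(test_ids)), seed = fseed)
  }) |> bind_rows()
}

#' Experiment configuration
#'
#' Bundles every tunable of one experiment; all randomness flows from
#' `master_seed` via [derive_seed()], so no wall-clock seeding exists.
#'
#' @param folds Monte-Carlo fold count (single-center mode).
#' @param test_fraction test split fraction.
#' @param classifier `"xgboost"`, `"random_forest"`, `"svm"` or `"dlda"`.
#' @param master_seed integer master seed.
#' @param budget manual-pipeline SFS feature budget.
#' @param mldp_budget candidate count for the MLDP search.
#' @param mldp_inner_folds inner CV folds of the search.
#' @param contamination,smote_k manual-pipeline hyperparameters.
#' @param cfg a [preference_config()].
#' @param dual_center evaluate center 1 -> center 2 instead of MCCV.
#' @param train_center center label used for training in dual-center mode
#'   (default: first sorted center).
#' @param scorer SFS scorer callback.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(folds = 100, test_fraction = 0.2,
                              classifier = "xgboost", master_seed = 1L,
                              budget = 20, mldp_budget = 30,
                              mldp_inner_folds = 5, contamination = 0.1,
                              smote_k = 5, cfg = preference_config(),
                              dual_center = FALSE, train_center = NULL,
                              scorer = NULL) {
  structure(list(folds = folds, test_fraction = test_fraction,
                 classifier = classifier, master_seed = as.integer(master_seed),
                 budget = budget, mldp_budget = mldp_budget,
                 mldp_inner_folds = mldp_inner_folds,
                 contamination = contamination, smote_k = smote_k, cfg = cfg,
                 dual_center = dual_center, train_center = train_center,
                 scorer = scorer),
            class = "experiment_config")
}

#' Run one (cohort, DP mode, rule scenario) experiment
#'
#' Per fold: the manual or searched pipeline is fitted on the training rows
#' under the compiled rules, test rows are transformed (feature subsetting
#' and scaling only), the classifier is trained and scored by confusion
#' metrics. In dual-center mode there is exactly one "fold": the training
#' center vs the other center. Failed folds are recorded, never silently
#' skipped.
#'
#' @param cohort a feature-table tibble.
#' @param dp_mode `"manual"` or `"mldp"`.
#' @param rule_scenario one of `"norst"`, `"exp_keep"`, `"exp_remove"`,
#'   `"pref_keep"`, `"pref_remove"` (a label recorded in the report; the
#'   rules themselves come from `rules`).
#' @param rules a `rst_ruleset` (or rule-file text parsed with
#'   [parse_rules()]); must be `NULL`/empty for `"norst"` and non-empty
#'   otherwise.
#' @param config an [experiment_config()].
#' @param splits optional precomputed [make_mccv_splits()] tibble (pass the
#'   same object to every experiment on a cohort to guarantee split reuse).
#' @return A `rst_eval` report: per-fold metrics, selected feature sets and
#'   pipeline specs, plus aggregates via [glance.rst_eval()].
#' @export
run_experiment <- function(cohort, dp_mode = c("manual", "mldp"),
                           rule_scenario = "norst", rules = NULL,
                           config = experiment_config(), splits = NULL) {
  dp_mode <- match.arg(dp_mode)
  if (!rule_scenario %in% RULE_SCENARIOS) {
    abort(paste0("rule_scenario must be one of: ", paste(RULE_SCENARIOS, collapse = ", ")))
  }
  check_feature_table(cohort)
  has_rules <- !is.null(rules) && nrow(rules) > 0
  if (rule_scenario == "norst" && has_rules) {
    abort("scenario 'norst' must not carry rules")
  }
  if (rule_scenario != "norst" && !has_rules) {
    abort(paste0("scenario '", rule_scenario, "' requires a non-empty rule set"))
  }
  d <- if (has_rules) compile_rules(rules, cohort, quiet = TRUE) else empty_directives(cohort)

  if (config$dual_center) {
    if (!"center" %in% names(cohort)) abort("dual-center mode requires a center column")
    centers <- lex_order(unique(cohort$center))
    trc <- config$train_center %||% centers[1]
    if (!trc %in% centers) abort(paste0("unknown train_center '", trc, "'"))
    splits <- tibble(fold = 1L,
                     train_ids = list(cohort$sample_id[cohort$center == trc]),
                     test_ids = list(cohort$sample_id[cohort$center != trc]),
                     seed = derive_seed(config$master_seed, "dual"))
  } else if (is.null(splits)) {
    splits <- make_mccv_splits(cohort, folds = config$folds,
                               test_fraction = config$test_fraction,
                               master_seed = config$master_seed)
  }

  fold_rows <- vector("list", nrow(splits))
  selected <- vector("list", nrow(splits))
  pipelines <- vector("list", nrow(splits))
  for (i in seq_len(nrow(splits))) {
    f <- splits$fold[i]
    res <- tryCatch({
      tr <- cohort[cohort$sample_id %in% splits$train_ids[[i]], ]
      te <- cohort[cohort$sample_id %in% splits$test_ids[[i]], ]
      fseed <- derive_seed(config$master_seed, "experiment", dp_mode, f)
      fp <- if (dp_mode == "manual") {
        fit_manual_pipeline(tr, d, budget = config$budget, cfg = config$cfg,
                            seed = fseed, contamination = config$contamination,
                            smote_k = config$smote_k, scorer = config$scorer)
      } else {
        mldp_search(tr, d, budget = config$mldp_budget,
                    inner_folds = config$mldp_inner_folds,
                    classifier = config$classifier, cfg = config$cfg,
                    seed = fseed, scorer = config$scorer)$best_fit
      }
      clf <- train_classifier(fp$table, config$classifier,
                              seed = derive_seed(fseed, "clf"))
      pred <- predict(clf, apply_pipeline(fp, te))
      met <- confusion_metrics(te$label, pred, positive_class(cohort))
      list(met = bind_cols(tibble(fold = f, n_train = nrow(tr), n_test = nrow(te)),
                           met, tibble(error = NA_character_)),
           feats = fp$features, spec = fp$spec)
    }, error = function(e) {
      list(met = tibble(fold = f, n_train = NA_integer_, n_test = NA_integer_,
                        TP = NA_integer_, FP = NA_integer_, TN = NA_integer_,
                        FN = NA_integer_, SENS = NA_real_, SPEC = NA_real_,
                        PPV = NA_real_, NPV = NA_real_, ACC = NA_real_,
                        BACC = NA_real_, error = conditionMessage(e)),
           feats = character(), spec = NULL)
    })
    fold_rows[[i]] <- res$met
    selected[[i]] <- res$feats
    pipelines[[i]] <- res$spec
  }
  structure(list(dp_mode = dp_mode, rule_scenario = rule_scenario,
                 folds = bind_rows(fold_rows), selected = selected,
                 pipelines = pipelines, splits = splits,
                 all_features = feature_names(cohort),
                 classifier = config$classifier,
                 master_seed = config$master_seed),
            class = "rst_eval")
}

#' @export
print.rst_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<rst_eval> %s / %s: %d fold(s), mean BACC %.3f (SD %.3f)\n",
              x$dp_mode, x$rule_scenario, nrow(x$folds),
              g$mean_bacc, g$sd_bacc))
  invisible(x)
}

#' Per-fold metric records of an evaluation report
#' @param x a `rst_eval`.
#' @param ... unused.
#' @return Tibble with one row per fold (counts, the six metrics, error
#'   message for failed folds).
#' @export
tidy.rst_eval <- function(x, ...) {
  mutate(x$folds, dp_mode = x$dp_mode, rule_scenario = x$rule_scenario,
         .before = 1)
}

#' Aggregate statistics of an evaluation report
#'
#' Mean, SD and normal-approximation CI95 (`mean +/- 1.96 * SD / sqrt(F)`)
#' over successful folds, per metric.
#'
#' @param x a `rst_eval`.
#' @param ... unused.
#' @return One-row tibble.
#' @export
glance.rst_eval <- function(x, ...) {
  ok <- x$folds[is.na(x$folds$error), ]
  agg <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    m <- mean(v); s <- if (length(v) > 1) sd(v) else 0
    ci <- 1.96 * s / sqrt(length(v))
    c(m, s, m - ci, m + ci)
  }
  b <- agg(ok$BACC); a <- agg(ok$ACC)
  tibble(dp_mode = x$dp_mode, rule_scenario = x$rule_scenario,
         n_folds = nrow(x$folds), n_failed = sum(!is.na(x$folds$error)),
         mean_bacc = b[1], sd_bacc = b[2], ci95_lo = b[3], ci95_hi = b[4],
         mean_acc = a[1],
         mean_sens = mean(ok$SENS, na.rm = TRUE),
         mean_spec = mean(ok$SPEC, na.rm = TRUE))
}

#' Per-feature occurrence across folds
#'
#' Fraction of successful folds whose final model contains each feature of
#' the cohort. Features under `exp-keep` occur at 1.0 and under `exp-remove`
#' at 0.0 by construction.
#'
#' @param report a `rst_eval`.
#' @return Tibble with columns `feature` and `occurrence` in `[0, 1]`,
#'   sorted by decreasing occurrence.
#' @export
feature_occurrence <- function(report) {
  stopifnot(inherits(report, "rst_eval"))
  ok <- which(is.na(report$folds$error))
  if (!length(ok)) abort("report has no successful fold")
  sel <- report$selected[ok]
  occ <- vapply(report$all_features,
                function(f) mean(vapply(sel, function(s) f %in% s, logical(1))),
                numeric(1))
  tibble(feature = report$all_features, occurrence = unname(occ)) |>
    arrange(dplyr::desc(.data$occurrence), .data$feature)
}

#' Compare rule scenarios sharing identical splits
#'
#' Builds a comparison table (mean, SD, CI95 of fold BACC per scenario) and,
#' for every scenario other than the `norst` baseline, a one-way ANOVA
#' p-value of its fold-BACC distribution against the baseline's. Reports on
#' non-identical splits are rejected (the comparison would be invalid);
#' single-fold (dual-center) input yields `NA` p-values.
#'
#' @param reports list of `rst_eval` sharing splits; exactly one must have
#'   scenario `"norst"` per DP mode (the baseline).
#' @return Tibble with one row per report (`dp_mode`, `rule_scenario`,
#'   `n_folds`, `mean_bacc`, `sd_bacc`, `ci95_lo`, `ci95_hi`, `p_vs_norst`).
#' @export
compare_scenarios <- function(reports) {
  stopifnot(length(reports) >= 2, all(vapply(reports, inherits, TRUE, "rst_eval")))
  ref <- reports[[1]]$splits[c("fold", "train_ids", "test_ids")]
  for (r in reports[-1]) {
    if (!identical(r$splits[c("fold", "train_ids", "test_ids")], ref)) {
      abort("reports do not share identical splits; comparison invalid")
    }
  }
  rows <- purrr::map(reports, function(r) {
    base <- purrr::detect(reports, function(b) {
      b$dp_mode == r$dp_mode && b$rule_scenario == "norst"
    })
    g <- glance(r)
    p <- NA_real_
    if (r$rule_scenario != "norst" && !is.null(base)) {
      p <- anova_p(r$folds$BACC, base$folds$BACC)
    }
    bind_cols(g[c("dp_mode", "rule_scenario", "n_folds", "mean_bacc",
                  "sd_bacc", "ci95_lo", "ci95_hi")],
              tibble(p_vs_norst = p))
  })
  bind_rows(rows)
}

## one-way ANOVA p-value across two fold-BACC vectors; single-fold -> NA
anova_p <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
  v <- c(a, b)
  gm <- tapply(v, grp, mean)
  ss_between <- sum(tabulate(grp) * (gm - mean(v))^2)
  if (ss_between < 1e-14) return(1) # identical group means
  an <- anova(lm(v ~ grp))
  unname(an[["Pr(>F)"]][1])
}
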
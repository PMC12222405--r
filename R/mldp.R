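#' Hyperparameter ranges for the MLDP pipeline search
#'
#' One config block declaring the search space: isolation-forest
#' contamination 0.02–0.2, SMOTE k 3–7, SFS budget 5–30, redundancy
#' correlation cutoff 0.8–0.98, undersampling target ratio 0.8–1.0.
#'
#' @param contamination,smote_k,sfs_k,redundancy_r,undersample_ratio
#'   two-element `c(lo, hi)` ranges.
#' @return A named list of ranges.
#' @export
mldp_ranges <- function(contamination = c(0.02, 0.2), smote_k = c(3, 7),
                        sfs_k = c(5, 30), redundancy_r = c(0.8, 0.98),
                        undersample_ratio = c(0.8, 1.0)) {
  list(contamination = contamination, smote_k = smote_k, sfs_k = sfs_k,
       redundancy_r = redundancy_r, undersample_ratio = undersample_ratio)
}

#' Draw a random pipeline specification
#'
#' Seeded draw of a pipeline length (0–7 searched steps), a step subset from
#' the catalog (each algorithm at most once, `sfs` forced last, random order
#' otherwise) and hyperparameters from [mldp_ranges()].
#'
#' @param seed integer seed.
#' @param ranges hyperparameter ranges, see [mldp_ranges()].
#' @return A [pipeline_spec()].
#' @export
sample_pipeline_spec <- function(seed, ranges = mldp_ranges()) {
  with_seed(seed, {
    len <- sample(0:length(PIPELINE_CATALOG), 1)
    chosen <- if (len) sample(PIPELINE_CATALOG, len) else character()
    chosen <- c(setdiff(chosen, "sfs"), intersect(chosen, "sfs"))
    steps <- lapply(chosen, function(nm) {
      params <- switch(nm,
        smote = list(k_neighbors = sample(ranges$smote_k[1]:ranges$smote_k[2], 1)),
        undersample = list(target_ratio = runif(1, ranges$undersample_ratio[1],
                                                ranges$undersample_ratio[2])),
        outlier_iforest = list(contamination = runif(1, ranges$contamination[1],
                                                     ranges$contamination[2])),
        redundancy_filter = list(r_threshold = runif(1, ranges$redundancy_r[1],
                                                     ranges$redundancy_r[2])),
        sfs = list(k = sample(ranges$sfs_k[1]:ranges$sfs_k[2], 1)),
        list())
      list(name = nm, params = params)
    })
    pipeline_spec(steps)
  })
}

#' Automated rule-honoring pipeline search (MLDP)
#'
#' Seeded random search over preprocessing pipeline compositions and
#' hyperparameters: each candidate is fitted fold-wise under inner stratified
#' cross-validation and scored by the mean balanced accuracy of the
#' classifier on the (pipeline-transformed) held-out rows. Rules are
#' enforced inside every candidate — explicit directives unconditionally,
#' preferential ones through the slack scheme. The best candidate (ties:
#' higher score, then shorter pipeline, then lexicographic serialized spec)
#' is refitted on the full training table and returned with the full audit
#' trail.
#'
#' @param table a feature-table tibble (training rows).
#' @param d a `rst_directives`.
#' @param budget number of candidate pipelines to draw (>= 1).
#' @param inner_folds inner stratified CV folds.
#' @param classifier passed to [train_classifier()].
#' @param cfg a [preference_config()].
#' @param seed master seed; candidates are re-seeded by derivation.
#' @param ranges hyperparameter ranges, see [mldp_ranges()].
#' @param scorer SFS scorer used inside candidate pipelines.
#' @return A `rst_mldp_search`: `$best_spec`, `$best_fit` (a fitted
#'   pipeline on the full table), `$records` (one row per candidate with
#'   inner-CV balanced accuracy, rank and failure reason if any).
#' @export
mldp_search <- function(table, d = empty_directives(table), budget = 30,
                        inner_folds = 5, classifier = "dlda",
                        cfg = preference_config(), seed = 1L,
                        ranges = mldp_ranges(), scorer = NULL) {
  check_feature_table(table)
  if (budget < 1) abort("budget must be >= 1")
  records <- vector("list", budget)
  for (b in seq_len(budget)) {
    cand_seed <- derive_seed(seed, "candidate", b)
    spec <- sample_pipeline_spec(cand_seed, ranges)
    # inner CV re-seeded per candidate from the master seed
    fold <- stratified_folds(table$label, inner_folds,
                             derive_seed(cand_seed, "inner"))
    bacc <- tryCatch({
      vals <- vapply(seq_len(inner_folds), function(f) {
        tr <- table[fold != f, ]
        va <- table[fold == f, ]
        fp <- fit_pipeline(spec, tr, d, cfg = cfg,
                           seed = derive_seed(cand_seed, "fold", f),
                           scorer = scorer)
        if (!length(fp$features)) abort("pipeline removed all features")
        clf <- train_classifier(fp$table, classifier,
                                seed = derive_seed(cand_seed, "clf", f))
        pred <- predict(clf, apply_pipeline(fp, va))
        confusion_metrics(va$label, pred, positive_class(table))$BACC
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    }, error = function(e) structure(NA_real_, reason = conditionMessage(e)))
    records[[b]] <- tibble(
      candidate = b, spec = list(spec), n_steps = length(spec$steps),
      inner_cv_bacc = as.numeric(bacc), seed = cand_seed,
      spec_json = as.character(spec_json(spec)),
      failure = attr(bacc, "reason") %||% NA_character_)
  }
  records <- bind_rows(records)
  ok <- !is.na(records$inner_cv_bacc)
  if (!any(ok)) {
    abort(paste0("all ", budget, " candidate pipelines failed:\n",
                 paste(sprintf("  candidate %d [%s]: %s", records$candidate,
                               records$spec_json, records$failure),
                       collapse = "\n")))
  }
  ord <- order(-records$inner_cv_bacc, records$n_steps, records$spec_json,
               method = "radix", na.last = TRUE)
  records$rank <- NA_integer_
  records$rank[ord] <- seq_len(nrow(records))
  best <- records[ord[1], ]
  best_fit <- fit_pipeline(best$spec[[1]], table, d, cfg = cfg,
                           seed = derive_seed(best$seed, "refit"), scorer = scorer)
  structure(list(best_spec = best$spec[[1]], best_fit = best_fit,
                 best_bacc = best$inner_cv_bacc, records = records),
            class = "rst_mldp_search")
}

#' @export
print.rst_mldp_search <- function(x, ...) {
  cat("<rst_mldp_search>", nrow(x$records), "candidate(s); best inner-CV BACC",
      sprintf("%.3f", x$best_bacc), "\n  best:", format(x$best_spec), "\n")
  invisible(x)
}

#' Per-algorithm occurrence across best pipelines
#'
#' For a set of fold-level best pipeline specifications, the fraction of
#' folds whose pipeline contains each catalog algorithm.
#'
#' @param specs list of [pipeline_spec()] (one best pipeline per fold).
#' @return Tibble with columns `algorithm` and `occurrence` in `[0, 1]`.
#' @export
describe_pipeline_complexity <- function(specs) {
  if (!length(specs)) abort("need at least one completed fold")
  hits <- vapply(PIPELINE_CATALOG, function(a) {
    mean(vapply(specs, function(s) {
      a %in% vapply(s$steps, `[[`, "", "name")
    }, logical(1)))
  }, numeric(1))
  tibble(algorithm = PIPELINE_CATALOG, occurrence = unname(hits))
}
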
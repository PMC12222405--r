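#' Pipeline specifications
#'
#' A `rst_pipeline_spec` is an ordered list of preprocessing steps (name +
#' hyperparameters) — the unit the MLDP search optimizes over. The implicit
#' step 0, applying explicit rules, is always present and never searched;
#' each algorithm appears at most once; `sfs`, if present, is last.
#'
#' @param steps list of `list(name = <catalog name>, params = list(...))`.
#' @return A `rst_pipeline_spec`.
#' @export
pipeline_spec <- function(steps = list()) {
  nms <- vapply(steps, `[[`, "", "name")
  bad <- setdiff(nms, PIPELINE_CATALOG)
  if (length(bad)) abort(paste0("unknown pipeline step(s): ", paste(bad, collapse = ", ")))
  if (anyDuplicated(nms)) abort("each algorithm may appear at most once")
  if ("sfs" %in% nms && nms[length(nms)] != "sfs") abort("sfs must be the final step")
  structure(list(steps = steps), class = "rst_pipeline_spec")
}

#' @export
format.rst_pipeline_spec <- function(x, ...) {
  if (!length(x$steps)) return("explicit_rules")
  paste(c("explicit_rules", vapply(x$steps, function(s) {
    if (length(s$params)) {
      paste0(s$name, "(", paste(sprintf("%s=%s", names(s$params),
                                        vapply(s$params, format, "")), collapse = ","), ")")
    } else s$name
  }, "")), collapse = " -> ")
}

#' @export
print.rst_pipeline_spec <- function(x, ...) {
  cat("<rst_pipeline_spec>", format(x), "\n")
  invisible(x)
}

## canonical serialization used for deterministic tie-breaks and replay
spec_json <- function(spec) {
  jsonlite::toJSON(spec$steps, auto_unbox = TRUE, digits = NA)
}

#' Fit a preprocessing pipeline on training rows
#'
#' Applies explicit rules first, then each step of `spec` in order, threading
#' the directive map through every rule-aware operator. Resampling and
#' outlier removal touch only the training rows; scaling parameters and the
#' final feature subset are recorded so the fitted pipeline can be replayed
#' on validation rows (which are never resampled or outlier-filtered).
#'
#' @param spec a [pipeline_spec()].
#' @param table a feature-table tibble (training rows).
#' @param d a `rst_directives`.
#' @param cfg a [preference_config()].
#' @param seed integer seed; each step draws a derived sub-seed.
#' @param scorer SFS scorer callback.
#' @return A `rst_fitted_pipeline`: `$table` the fully preprocessed training
#'   table, `$features` the surviving feature set, `$transforms` the fitted
#'   stateless transforms for validation rows, `$steps` the `rst_step` chain.
#' @export
fit_pipeline <- function(spec, table, d = empty_directives(table),
                         cfg = preference_config(), seed = 1L,
                         scorer = NULL) {
  stopifnot(inherits(spec, "rst_pipeline_spec"))
  steps <- list()
  s0 <- apply_explicit_rules(table, d)
  steps[["explicit_rules"]] <- s0
  cur <- s0$table
  transforms <- list()
  for (i in seq_along(spec$steps)) {
    st <- spec$steps[[i]]
    p <- st$params %||% list()
    sseed <- derive_seed(seed, "step", i, st$name)
    step <- switch(st$name,
      smote = guided_smote(cur, d, k_neighbors = p$k_neighbors %||% 5,
                           target_ratio = p$target_ratio %||% 1, seed = sseed),
      undersample = guided_undersample(cur, d, target_ratio = p$target_ratio %||% 1,
                                       cfg = cfg, seed = sseed),
      outlier_iforest = guided_outlier_removal(cur, d,
                                               contamination = p$contamination %||% 0.1,
                                               cfg = cfg, seed = sseed),
      redundancy_filter = guided_redundancy_filter(cur, d,
                                                   r_threshold = p$r_threshold %||% 0.9),
      scale_zscore = scale_features(cur, "zscore"),
      scale_minmax = scale_features(cur, "minmax"),
      sfs = guided_sfs(cur, d, k = min(p$k %||% 10, length(feature_names(cur))),
                       scorer = scorer, cfg = cfg, seed = sseed,
                       inner_folds = p$inner_folds %||% 3),
      abort(paste0("unknown step: ", st$name)))
    if (st$name %in% c("scale_zscore", "scale_minmax")) {
      transforms[[length(transforms) + 1L]] <- step$params
    }
    steps[[st$name]] <- step
    cur <- step$table
  }
  structure(list(spec = spec, table = cur, features = feature_names(cur),
                 transforms = transforms, steps = steps, seed = seed,
                 log = vapply(steps, `[[`, "", "log")),
            class = "rst_fitted_pipeline")
}

#' Replay a fitted pipeline on validation rows
#'
#' Validation rows pass only through the stateless/fitted transforms:
#' scaling with training-fitted parameters, then subsetting to the final
#' feature set. They are never resampled or outlier-filtered.
#'
#' @param fp a `rst_fitted_pipeline`.
#' @param new_table a feature-table tibble.
#' @return The transformed tibble, restricted to the pipeline's features.
#' @export
apply_pipeline <- function(fp, new_table) {
  stopifnot(inherits(fp, "rst_fitted_pipeline"))
  cur <- new_table
  for (params in fp$transforms) {
    feats <- intersect(names(if (params$method == "zscore") params$center else params$min),
                       feature_names(cur))
    cur[feats] <- as.data.frame(apply_scale_params(feature_matrix(cur, feats), params, feats))
  }
  missing <- setdiff(fp$features, names(cur))
  if (length(missing)) {
    abort(paste0("new data lacks pipeline feature(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  cur[c(intersect(RESERVED_COLS, names(cur)), fp$features)]
}

#' @export
print.rst_fitted_pipeline <- function(x, ...) {
  cat("<rst_fitted_pipeline>", format(x$spec), "\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' The fixed manual preprocessing pipeline
#'
#' Applies, in order: explicit rules, SMOTE imbalance correction,
#' isolation-forest outlier removal, and sequential forward selection down
#' to `budget` features — the fixed pipeline with preset hyperparameters
#' against which the automated search is compared. Per-cohort feature
#' budgets in the reference experiments are 20 (glioma twin), 20 (prostate
#' twin) and 10 (DLBCL twin).
#'
#' @param table a feature-table tibble (training rows).
#' @param d a `rst_directives`.
#' @param budget SFS feature budget (must be >= the `exp-keep` count).
#' @param cfg a [preference_config()].
#' @param seed integer seed.
#' @param contamination isolation-forest contamination.
#' @param smote_k SMOTE neighbor count.
#' @param target_ratio post-SMOTE minority/majority ratio.
#' @param scorer SFS scorer callback.
#' @return A `rst_fitted_pipeline`.
#' @export
fit_manual_pipeline <- function(table, d = empty_directives(table), budget,
                                cfg = preference_config(), seed = 1L,
                                contamination = 0.1, smote_k = 5,
                                target_ratio = 1, scorer = NULL) {
  spec <- pipeline_spec(list(
    list(name = "smote", params = list(k_neighbors = smote_k, target_ratio = target_ratio)),
    list(name = "outlier_iforest", params = list(contamination = contamination)),
    list(name = "sfs", params = list(k = budget))))
  fit_pipeline(spec, table, d, cfg = cfg, seed = seed, scorer = scorer)
}
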
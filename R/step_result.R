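#' Preference configuration for guided preprocessing
#'
#' The tolerance parameters that operationalize how far a preferential rule
#' may bend an algorithm's own ranking before being overruled:
#' `sfs_slack` (epsilon) is the relative score slack in sequential forward
#' selection, `outlier_slack` (gamma) widens/tightens the isolation-forest
#' removal quantile for pref-remove/pref-keep samples, and
#' `undersample_weight` (w) multiplies/divides the removal draw weight.
#' Setting `sfs_slack = 0`, `outlier_slack = 0`, `undersample_weight = 1`
#' makes every preferential rule a no-op.
#'
#' @param sfs_slack fraction in `[0, 1)`.
#' @param outlier_slack fraction in `[0, 1)`.
#' @param undersample_weight multiplier `>= 1`.
#' @return A `preference_config` list.
#' @export
preference_config <- function(sfs_slack = 0.05, outlier_slack = 0.25,
                              undersample_weight = 4) {
  if (sfs_slack < 0 || sfs_slack >= 1) abort("sfs_slack must be in [0, 1)")
  if (outlier_slack < 0 || outlier_slack >= 1) abort("outlier_slack must be in [0, 1)")
  if (undersample_weight < 1) abort("undersample_weight must be >= 1")
  structure(list(sfs_slack = sfs_slack, outlier_slack = outlier_slack,
                 undersample_weight = undersample_weight),
            class = "preference_config")
}

## every guided operator returns one of these
new_step_result <- function(table, removed_samples = character(),
                            removed_features = character(),
                            selected_features = character(),
                            honored = NULL, log = "") {
  honored <- honored %||% tibble(target = character(), action = character(),
                                 honored = logical())
  structure(list(table = table, removed_samples = removed_samples,
                 removed_features = removed_features,
                 selected_features = selected_features,
                 honored_preferences = honored, log = log),
            class = "rst_step")
}

## honored-preferences bookkeeping: explicit directives are always honored;
## preferential ones are honored when the realized outcome matches the wish
honored_tbl <- function(d, scope, kept, removed) {
  acts <- d[[scope]]
  acts <- acts[acts != "none"]
  if (!length(acts)) {
    return(tibble(target = character(), action = character(), honored = logical()))
  }
  tibble(target = names(acts), action = unname(acts)) |>
    mutate(honored = dplyr::case_when(
      .data$action %in% c("exp_keep", "pref_keep") ~ .data$target %in% kept,
      TRUE ~ .data$target %in% removed
    ))
}

#' @export
print.rst_step <- function(x, ...) {
  cat("<rst_step>", x$log, "\n")
  cat(sprintf("  table: %d x %d | removed samples: %d | removed features: %d | selected: %d\n",
              nrow(x$table), length(feature_names(x$table)),
              length(x$removed_samples), length(x$removed_features),
              length(x$selected_features)))
  invisible(x)
}

#' Tidy a preprocessing step result
#' @param x a `rst_step`.
#' @param ... unused.
#' @return Tibble of per-target outcomes (removals, selections, honored
#'   preferences).
#' @export
tidy.rst_step <- function(x, ...) {
  bind_rows(
    tibble(target = x$removed_samples, outcome = "removed_sample"),
    tibble(target = x$removed_features, outcome = "removed_feature"),
    tibble(target = x$selected_features, outcome = "selected_feature"),
    if (nrow(x$honored_preferences)) {
      tibble(target = x$honored_preferences$target,
             outcome = ifelse(x$honored_preferences$honored,
                              "preference_honored", "preference_overruled"))
    }
  )
}
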
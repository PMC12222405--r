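#' Apply explicit (hard) rules to a feature table
#'
#' Deletes every `exp-remove` feature and sample; `exp-keep` targets are left
#' in place and remain protected in all downstream guided operators (which
#' consult the same directive map). Always the first pipeline step.
#'
#' @param table a feature-table tibble.
#' @param d a `rst_directives` compiled against this table (or a superset).
#' @return A `rst_step`.
#' @export
apply_explicit_rules <- function(table, d) {
  check_feature_table(table)
  rm_feat <- intersect(dir_targets(d, "feature", "exp_remove"), feature_names(table))
  rm_samp <- intersect(dir_targets(d, "sample", "exp_remove"), table$sample_id)
  out <- table
  if (length(rm_feat)) out <- out[setdiff(names(out), rm_feat)]
  if (length(rm_samp)) {
    kept <- out[!out$sample_id %in% rm_samp, ]
    if (any(table(kept$label) == 0)) {
      abort("removing exp-remove samples would empty a class")
    }
    out <- kept
  }
  new_step_result(out, removed_samples = rm_samp, removed_features = rm_feat,
                  honored = honored_tbl(d, "feature", kept = feature_names(out),
                                        removed = rm_feat) |>
                    filter(.data$action %in% EXPLICIT_ACTIONS) |>
                    bind_rows(honored_tbl(d, "sample", kept = out$sample_id,
                                          removed = rm_samp) |>
                                filter(.data$action %in% EXPLICIT_ACTIONS)),
                  log = sprintf("explicit_rules: removed %d feature(s), %d sample(s)",
                                length(rm_feat), length(rm_samp)))
}
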
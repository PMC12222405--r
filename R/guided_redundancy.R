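#' Rule-guided redundant-feature filtering
#'
#' Features are clustered into redundant groups by single-linkage on
#' `1 - |pairwise Pearson correlation|`, cutting so that features with
#' `|r| >= r_threshold` share a group. One representative is kept per group:
#' every `exp-keep` member if any is present; otherwise the `pref-keep`
#' member ranking highest within the group (ranking = variance, the same
#' criterion the unguided filter uses); otherwise the highest-variance
#' member. `pref-remove` members are never chosen as representative unless
#' they are alone in their group. This lets a clinician keep a preferred
#' feature even when it is not the top-ranking member of its redundant group.
#'
#' @param table a feature-table tibble.
#' @param d a `rst_directives`.
#' @param r_threshold absolute-correlation cutoff in (0, 1).
#' @return A `rst_step`.
#' @export
guided_redundancy_filter <- function(table, d = empty_directives(table),
                                     r_threshold = 0.9) {
  check_feature_table(table)
  if (r_threshold <= 0 || r_threshold >= 1) abort("r_threshold must be in (0, 1)")
  feats <- feature_names(table)
  if (length(feats) < 2) {
    return(new_step_result(table, log = "redundancy_filter: <2 features, identity"))
  }
  m <- feature_matrix(table)
  cc <- suppressWarnings(abs(cor(m)))
  cc[!is.finite(cc)] <- 0 # constant features correlate with nothing
  hc <- hclust(as.dist(1 - cc), method = "single")
  grp <- cutree(hc, h = 1 - r_threshold)
  facts <- dir_action(d, "feature", feats)
  vars <- apply(m, 2, var)
  kept <- character()
  for (g in unique(grp)) {
    members <- lex_order(feats[grp == g])
    a <- facts[members]
    if (length(members) == 1) {
      kept <- c(kept, members)
      next
    }
    if (any(a == "exp_keep")) {
      kept <- c(kept, members[a == "exp_keep"])
      next
    }
    pool <- if (any(a == "pref_keep")) {
      members[a == "pref_keep"]
    } else if (all(a == "pref_remove")) {
      members
    } else {
      members[a != "pref_remove"]
    }
    kept <- c(kept, pool[which.max(vars[pool])])
  }
  kept <- feats[feats %in% kept] # original column order
  removed <- setdiff(feats, kept)
  out <- table[c(intersect(RESERVED_COLS, names(table)), kept)]
  new_step_result(out, removed_features = removed,
                  honored = honored_tbl(d, "feature", kept = kept, removed = removed),
                  log = sprintf("redundancy_filter(r=%.2f): removed %d of %d feature(s)",
                                r_threshold, length(removed), length(feats)))
}
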
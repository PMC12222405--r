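#' Rule-guided isolation-forest outlier removal
#'
#' Anomaly scores are computed by an isolation forest on the given (training)
#' rows only. The unguided removal set is the `floor(contamination * n)`
#' highest-scoring samples. Directives modulate it:
#' `exp-keep` samples are exempt regardless of score (the next-ranked
#' candidate is removed instead to meet the contamination count);
#' `pref-remove` samples are removed if they fall within the relaxed top
#' `contamination * (1 + gamma)` quantile; `pref-keep` samples are kept
#' unless they fall within the tightened top `contamination * (1 - gamma)`
#' quantile. Removal never empties a class.
#'
#' @param table a feature-table tibble (training rows).
#' @param d a `rst_directives`.
#' @param contamination expected outlier fraction, in (0, 0.5).
#' @param cfg a [preference_config()] (`outlier_slack` = gamma).
#' @param seed integer seed for the forest.
#' @param n_trees,subsample isolation-forest size (fixed defaults: 200 trees,
#'   subsample 256 or n if smaller).
#' @return A `rst_step`; `$scores` holds the per-sample anomaly scores.
#' @export
guided_outlier_removal <- function(table, d = empty_directives(table),
                                   contamination = 0.1,
                                   cfg = preference_config(), seed = 1L,
                                   n_trees = 200, subsample = 256) {
  check_feature_table(table)
  if (contamination <= 0 || contamination >= 0.5) {
    abort("contamination must be in (0, 0.5)")
  }
  gamma <- cfg$outlier_slack
  n <- nrow(table)
  scores <- iforest_score(feature_matrix(table), n_trees = n_trees,
                          subsample = subsample, seed = seed)
  names(scores) <- table$sample_id
  ## ranks: 1 = most anomalous; score ties broken lexicographically by id
  ord <- order(-scores, table$sample_id, method = "radix")
  rank <- integer(n); rank[ord] <- seq_len(n)
  names(rank) <- table$sample_id
  acts <- dir_action(d, "sample", table$sample_id)
  m <- floor(contamination * n)
  m_tight <- floor(contamination * (1 - gamma) * n)
  m_loose <- floor(contamination * (1 + gamma) * n)

  eligible <- table$sample_id[acts != "exp_keep"]
  ## base set: top-m eligible by rank (exp-keep replaced by next-ranked)
  base <- eligible[order(rank[eligible])][seq_len(min(m, length(eligible)))]
  ## pref-keep members of the base set survive unless within the tight quantile
  spared <- base[acts[base] == "pref_keep" & rank[base] > m_tight]
  removal <- setdiff(base, spared)
  ## refill slots freed by spared pref-keep samples with next-ranked eligibles
  if (length(spared)) {
    pool <- setdiff(eligible, union(removal, spared))
    pool <- pool[acts[pool] != "pref_keep" | rank[pool] <= m_tight]
    refill <- pool[order(rank[pool])]
    removal <- c(removal, head(refill, length(spared)))
  }
  ## pref-remove samples inside the relaxed quantile join the removal set
  extra <- eligible[acts[eligible] == "pref_remove" & rank[eligible] <= m_loose]
  removal <- union(removal, extra)

  ## never empty a class: retain the lowest-scoring removals of a class
  for (cl in levels(table$label)) {
    ids_cl <- table$sample_id[table$label == cl]
    if (length(ids_cl) && all(ids_cl %in% removal)) {
      keep_back <- ids_cl[which.max(rank[ids_cl])]
      removal <- setdiff(removal, keep_back)
    }
  }
  removal <- removal[order(rank[removal])]
  out <- table[!table$sample_id %in% removal, ]
  step <- new_step_result(out, removed_samples = removal,
                          honored = honored_tbl(d, "sample", kept = out$sample_id,
                                                removed = removal),
                          log = sprintf("outlier_iforest(c=%.3f): removed %d of %d sample(s)",
                                        contamination, length(removal), n))
  step$scores <- scores
  step
}
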
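#' Rule-guided random undersampling of the majority class
#'
#' Majority-class samples are removed by a weighted random draw without
#' replacement until the minority:majority ratio reaches `target_ratio`.
#' Directives set the draw weights: `exp-keep` samples get weight 0 (never
#' drawn), `pref-remove` weight `w`, `pref-keep` weight `1/w`, all others 1.
#'
#' @param table a feature-table tibble.
#' @param d a `rst_directives`.
#' @param target_ratio desired minority/majority count ratio after removal,
#'   in (0, 1].
#' @param cfg a [preference_config()] (`undersample_weight` = w).
#' @param seed integer seed.
#' @return A `rst_step`.
#' @export
guided_undersample <- function(table, d = empty_directives(table),
                               target_ratio = 1, cfg = preference_config(),
                               seed = 1L) {
  check_feature_table(table)
  if (target_ratio <= 0 || target_ratio > 1) abort("target_ratio must be in (0, 1]")
  counts <- table(table$label)
  if (counts[1] == counts[2]) {
    return(new_step_result(table, log = "undersample: classes balanced, identity"))
  }
  maj <- names(counts)[which.max(counts)]
  n_min <- min(counts); n_maj <- max(counts)
  n_keep <- round_half_up(n_min / target_ratio)
  n_remove <- n_maj - n_keep
  if (n_remove <= 0) {
    return(new_step_result(table, log = "undersample: target already met, identity"))
  }
  maj_ids <- table$sample_id[table$label == maj]
  acts <- dir_action(d, "sample", maj_ids)
  w <- cfg$undersample_weight
  wt <- setNames(rep(1, length(maj_ids)), maj_ids)
  wt[acts == "exp_keep"] <- 0
  wt[acts == "pref_remove"] <- w
  wt[acts == "pref_keep"] <- 1 / w
  removable <- sum(wt > 0)
  if (n_remove > removable) {
    abort(sprintf("infeasible target_ratio: %d removal(s) needed but only %d majority sample(s) are not exp-keep protected",
                  n_remove, removable))
  }
  removed <- with_seed(seed, {
    pool <- maj_ids[wt > 0]
    w <- wt[wt > 0]
    if (all(w == w[1])) { # uniform weights reduce to plain sampling
      sample(pool, n_remove, replace = FALSE)
    } else {
      sample(pool, n_remove, replace = FALSE, prob = w)
    }
  })
  out <- table[!table$sample_id %in% removed, ]
  new_step_result(out, removed_samples = removed,
                  honored = honored_tbl(d, "sample", kept = out$sample_id,
                                        removed = removed),
                  log = sprintf("undersample(ratio=%.2f): removed %d majority sample(s)",
                                target_ratio, n_remove))
}

#' SMOTE oversampling of the minority class
#'
#' Standard synthetic minority oversampling: each synthetic row interpolates
#' between a random minority sample and one of its `k_neighbors` nearest
#' minority neighbors (Euclidean distance on the feature columns) at a
#' uniform random fraction. Synthetic rows are flagged (`.synthetic = TRUE`)
#' with generated ids disjoint from the originals. Directives do not alter
#' the interpolation itself — only explicit removals, applied upstream,
#' affect which samples SMOTE sees.
#'
#' @param table a feature-table tibble.
#' @param d a `rst_directives` (accepted for interface uniformity; unused
#'   internally).
#' @param k_neighbors number of nearest neighbors to interpolate with.
#' @param target_ratio desired minority/majority ratio after oversampling,
#'   in (0, 1].
#' @param seed integer seed.
#' @return A `rst_step`.
#' @export
guided_smote <- function(table, d = empty_directives(table), k_neighbors = 5,
                         target_ratio = 1, seed = 1L) {
  check_feature_table(table)
  if (target_ratio <= 0 || target_ratio > 1) abort("target_ratio must be in (0, 1]")
  counts <- table(table$label)
  minc <- names(counts)[which.min(counts)]
  n_min <- min(counts); n_maj <- max(counts)
  n_new <- round_half_up(n_maj * target_ratio) - n_min
  if (counts[1] == counts[2] || n_new <= 0) {
    return(new_step_result(table, log = "smote: target already met, identity"))
  }
  if (n_min < k_neighbors + 1) {
    abort(sprintf("minority class has %d sample(s) but SMOTE needs k_neighbors + 1 = %d; lower k_neighbors",
                  n_min, k_neighbors + 1))
  }
  feats <- feature_names(table)
  minority <- table[table$label == minc, ]
  xm <- feature_matrix(minority)
  dd <- as.matrix(dist(xm))
  diag(dd) <- Inf
  nn <- t(apply(dd, 1, function(r) order(r)[seq_len(k_neighbors)]))
  synth <- with_seed(seed, {
    base_idx <- sample.int(nrow(xm), n_new, replace = TRUE)
    nb_pick <- sample.int(k_neighbors, n_new, replace = TRUE)
    nbr_idx <- nn[cbind(base_idx, nb_pick)]
    delta <- runif(n_new) # recycled down columns: one fraction per synthetic row
    xnew <- xm[base_idx, , drop = FALSE] +
      delta * (xm[nbr_idx, , drop = FALSE] - xm[base_idx, , drop = FALSE])
    list(x = xnew, base = base_idx)
  })
  new_rows <- as_tibble(as.data.frame(synth$x))
  names(new_rows) <- feats
  new_rows$sample_id <- sprintf("SMOTE_%04d", seq_len(n_new))
  new_rows$label <- factor(minc, levels = levels(table$label))
  new_rows$.synthetic <- TRUE
  if ("center" %in% names(table)) {
    new_rows$center <- minority$center[synth$base]
  }
  out <- bind_rows(table, new_rows[names(table)])
  new_step_result(out, log = sprintf("smote(k=%d): added %d synthetic minority sample(s)",
                                     k_neighbors, n_new))
}
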
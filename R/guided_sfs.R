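#' Inner-CV scorers for sequential forward selection
#'
#' A scorer is `function(x_train, y_train, x_val, y_val) -> balanced accuracy`
#' evaluated on a candidate feature subset. The default, `scorer_dlda()`,
#' fits a diagonal-covariance Gaussian discriminant (per-class means, pooled
#' per-feature variance, equal priors) — a fast, deterministic wrapper base
#' learner well suited to small-n / wide-p radiomics tables.
#'
#' @param x_train,x_val numeric matrices (rows = samples).
#' @param y_train,y_val two-level factors.
#' @return Balanced accuracy of the validation predictions.
#' @export
scorer_dlda <- function(x_train, y_train, x_val, y_val) {
  lev <- levels(y_train)
  i1 <- y_train == lev[1]
  m1 <- colMeans(x_train[i1, , drop = FALSE])
  m2 <- colMeans(x_train[!i1, , drop = FALSE])
  d1 <- sweep(x_train[i1, , drop = FALSE], 2, m1)
  d2 <- sweep(x_train[!i1, , drop = FALSE], 2, m2)
  pooled <- (colSums(d1^2) + colSums(d2^2)) / max(nrow(x_train) - 2, 1)
  pooled <- pmax(pooled, 1e-8)
  s1 <- -colSums((t(x_val) - m1)^2 / pooled)
  s2 <- -colSums((t(x_val) - m2)^2 / pooled)
  pred <- factor(ifelse(s2 > s1, lev[2], lev[1]), levels = lev)
  mean(c(mean(pred[y_val == lev[1]] == lev[1]),
         mean(pred[y_val == lev[2]] == lev[2])))
}

## stratified k-fold assignment (returns integer fold per row)
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (lev in levels(y)) {
      idx <- which(y == lev)
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    fold
  })
}

#' Rule-guided sequential forward selection
#'
#' Greedy wrapper feature selection: starting from the `exp-keep` features
#' (which are seeded into the selection before any search and count toward
#' the budget `k`), each step adds the candidate feature whose inner-CV
#' score is highest. Preferential rules bend the ranking within a relative
#' slack `epsilon = cfg$sfs_slack`: if any `pref-keep` candidate scores at
#' least `(1 - epsilon) * best`, the best such candidate is chosen instead
#' of the argmax; a `pref-remove` candidate is chosen only when its score
#' exceeds `best-other / (1 - epsilon)`. At `epsilon = 0` the preferential
#' logic is disabled entirely and the selection equals unconstrained SFS.
#' Score ties are broken lexicographically by feature name (tolerance
#' 1e-12).
#'
#' @param table a feature-table tibble (training rows; `exp-remove` features
#'   already removed upstream).
#' @param d a `rst_directives`.
#' @param k target number of selected features (must be >= the number of
#'   `exp-keep` features).
#' @param scorer inner-CV score callback, see [scorer_dlda()]. The default
#'   `NULL` uses an incremental implementation mathematically identical to
#'   `scorer_dlda` (diagonal discriminant terms are additive per feature,
#'   so all candidates of a step are scored in one matrix operation).
#' @param cfg a [preference_config()].
#' @param seed integer seed (drives the inner-CV folds).
#' @param inner_folds inner cross-validation fold count.
#' @return A `rst_step`; `$selected_features` has `min(k, available)`
#'   entries, `$step_scores` the audit trail of chosen-feature scores.
#' @export
guided_sfs <- function(table, d = empty_directives(table), k,
                       scorer = NULL, cfg = preference_config(),
                       seed = 1L, inner_folds = 3) {
  check_feature_table(table)
  feats <- setdiff(feature_names(table), dir_targets(d, "feature", "exp_remove"))
  if (k < 1) abort("k must be >= 1")
  eps <- cfg$sfs_slack
  acts <- dir_action(d, "feature", feats)
  seeded <- lex_order(feats[acts == "exp_keep"])
  if (length(seeded) > k) {
    abort(sprintf("feature budget k = %d cannot honor %d exp-keep feature(s)",
                  k, length(seeded)))
  }
  k_eff <- min(k, length(feats))
  selected <- seeded
  candidates <- setdiff(feats, selected)
  x <- feature_matrix(table, feats)
  y <- table$label
  fold <- stratified_folds(y, inner_folds, derive_seed(seed, "sfs_folds"))

  if (is.null(scorer)) {
    ## fast dlda path: per fold, the class-difference of squared
    ## standardized deviations D = (x-m1)^2/v - (x-m2)^2/v is additive over
    ## features, so a step's candidate scores are one matrix comparison
    lev <- levels(y)
    fold_dat <- lapply(seq_len(inner_folds), function(f) {
      tr <- fold != f
      xt <- x[tr, , drop = FALSE]; yt <- y[tr]
      xv <- x[!tr, , drop = FALSE]; yv <- y[!tr]
      i1 <- yt == lev[1]
      m1 <- colMeans(xt[i1, , drop = FALSE])
      m2 <- colMeans(xt[!i1, , drop = FALSE])
      d1 <- sweep(xt[i1, , drop = FALSE], 2, m1)
      d2 <- sweep(xt[!i1, , drop = FALSE], 2, m2)
      pooled <- pmax((colSums(d1^2) + colSums(d2^2)) / max(nrow(xt) - 2, 1), 1e-8)
      D <- sweep(sweep(xv, 2, m1)^2, 2, pooled, "/") -
        sweep(sweep(xv, 2, m2)^2, 2, pooled, "/")
      list(D = D, pos = yv == lev[2], neg = yv == lev[1],
           base = rowSums(D[, selected, drop = FALSE]))
    })
    score_candidates <- function(cands) {
      acc <- 0
      for (f in seq_len(inner_folds)) {
        fd <- fold_dat[[f]]
        P <- fd$D[, cands, drop = FALSE] + fd$base > 0 # predicted positive
        acc <- acc + 0.5 * (colMeans(P[fd$pos, , drop = FALSE]) +
                              colMeans(!P[fd$neg, , drop = FALSE]))
      }
      acc / inner_folds
    }
    advance <- function(pick) {
      for (f in seq_len(inner_folds)) {
        fold_dat[[f]]$base <<- fold_dat[[f]]$base + fold_dat[[f]]$D[, pick]
      }
    }
  } else {
    score_set <- function(cols) {
      mean(vapply(seq_len(inner_folds), function(f) {
        tr <- fold != f
        scorer(x[tr, cols, drop = FALSE], y[tr],
               x[!tr, cols, drop = FALSE], y[!tr])
      }, numeric(1)))
    }
    score_candidates <- function(cands) {
      vapply(cands, function(cand) score_set(c(selected, cand)), numeric(1))
    }
    advance <- function(pick) invisible(NULL)
  }

  trail <- list()
  tol <- 1e-12
  while (length(selected) < k_eff && length(candidates)) {
    sc <- score_candidates(candidates)
    names(sc) <- candidates
    pick <- argmax_lex(sc, tol)
    if (eps > 0) {
      pk <- candidates[acts[candidates] == "pref_keep"]
      pr <- candidates[acts[candidates] == "pref_remove"]
      best <- max(sc)
      if (length(pk)) {
        ok <- pk[sc[pk] >= (1 - eps) * best - tol]
        if (length(ok)) pick <- argmax_lex(sc[ok], tol)
      }
      if (pick %in% pr) {
        others <- setdiff(candidates, pr)
        if (length(others)) {
          best_other <- max(sc[others])
          if (!(sc[pick] > best_other / (1 - eps) + tol)) {
            pick <- argmax_lex(sc[others], tol)
          }
        }
      }
    }
    trail[[length(trail) + 1L]] <- tibble(
      step = length(trail) + 1L, feature = pick, score = unname(sc[pick]),
      best_score = max(sc), action = unname(acts[pick]))
    selected <- c(selected, pick)
    candidates <- setdiff(candidates, pick)
    advance(pick)
  }
  selected <- feats[feats %in% selected] # original column order
  removed <- setdiff(feats, selected)
  out <- table[c(intersect(RESERVED_COLS, names(table)), selected)]
  step <- new_step_result(out, removed_features = removed,
                          selected_features = selected,
                          honored = honored_tbl(d, "feature", kept = selected,
                                                removed = removed),
                          log = sprintf("sfs(k=%d, eps=%.3f): selected %d feature(s), %d seeded by exp-keep",
                                        k, eps, length(selected), length(seeded)))
  step$step_scores <- if (length(trail)) bind_rows(trail) else {
    tibble(step = integer(), feature = character(), score = numeric(),
           best_score = numeric(), action = character())
  }
  step
}
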
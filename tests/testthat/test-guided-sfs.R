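# a stub scorer whose value depends only on the candidate feature added,
# letting each step's candidate ranking be enumerated by hand
fixed_scorer <- function(values) {
  function(x_train, y_train, x_val, y_val) {
    cand <- colnames(x_train)[ncol(x_train)]
    values[[cand]]
  }
}

test_that("exp-keep features saturate the budget with zero search steps", {
  tbl <- tiny_table(n = 12, p = 5)
  d <- compile_rules(parse_rules("feature exp-keep name=GLCM_a,GLCM_b,GLCM_c"), tbl)
  st <- guided_sfs(tbl, d, k = 3, seed = 1)
  expect_setequal(st$selected_features, c("GLCM_a", "GLCM_b", "GLCM_c"))
  expect_equal(nrow(st$step_scores), 0)
})

test_that("budget below the exp-keep count is a hard error", {
  tbl <- tiny_table(n = 12, p = 5)
  d <- compile_rules(parse_rules("feature exp-keep name=GLCM_a,GLCM_b,GLCM_c"), tbl)
  expect_error(guided_sfs(tbl, d, k = 2, seed = 1), "cannot honor")
})

test_that("with zero slack and no rules, guided SFS equals unconstrained SFS", {
  tbl <- glioma_small()
  cfg0 <- preference_config(sfs_slack = 0)
  d <- compile_rules(parse_rules("feature pref-keep name=age"), tbl, quiet = TRUE)
  a <- guided_sfs(tbl, empty_directives(tbl), k = 6, seed = 4)
  b <- guided_sfs(tbl, d, k = 6, cfg = cfg0, seed = 4)
  expect_identical(a$selected_features, b$selected_features)
})

test_that("the fast diagonal-LDA path matches the generic scorer path", {
  for (s in 1:3) {
    tbl <- tiny_table(n = 30, p = 8, seed = s,
                      feature_names = sprintf("F%02d", 1:8))
    fast <- guided_sfs(tbl, k = 4, seed = s)
    slow <- guided_sfs(tbl, k = 4, scorer = scorer_dlda, seed = s)
    expect_identical(fast$selected_features, slow$selected_features)
  }
})

test_that("a pref-keep candidate within the slack is chosen over the argmax", {
  tbl <- tiny_table(n = 12, p = 6,
                    feature_names = c("F1", "F2", "F3", "F4", "F5", "F6"))
  # hand-enumerated ranking: F1 best (0.80), F2 second (0.79); slack 0.05
  # admits F2 because 0.79 >= 0.95 * 0.80 = 0.76
  vals <- c(F1 = 0.80, F2 = 0.79, F3 = 0.60, F4 = 0.55, F5 = 0.50, F6 = 0.45)
  d <- compile_rules(parse_rules("feature pref-keep name=F2"), tbl)
  st <- guided_sfs(tbl, d, k = 1, scorer = fixed_scorer(vals),
                   cfg = preference_config(sfs_slack = 0.05), seed = 1)
  expect_equal(st$selected_features, "F2")
  # outside the slack the suggestion is overruled
  vals2 <- c(F1 = 0.80, F2 = 0.70, F3 = 0.60, F4 = 0.55, F5 = 0.50, F6 = 0.45)
  st2 <- guided_sfs(tbl, d, k = 1, scorer = fixed_scorer(vals2),
                    cfg = preference_config(sfs_slack = 0.05), seed = 1)
  expect_equal(st2$selected_features, "F1")
  pref_row <- st2$honored_preferences[st2$honored_preferences$target == "F2", ]
  expect_false(pref_row$honored)
})

test_that("a pref-remove candidate is skipped unless it clearly dominates", {
  tbl <- tiny_table(n = 12, p = 3, feature_names = c("F1", "F2", "F3"))
  d <- compile_rules(parse_rules("feature pref-remove name=F1"), tbl)
  # F1 is argmax but 0.80 <= 0.79 / 0.95 = 0.8316: overruled in favor of F2
  st <- guided_sfs(tbl, d, k = 1, scorer = fixed_scorer(c(F1 = 0.80, F2 = 0.79, F3 = 0.5)),
                   cfg = preference_config(sfs_slack = 0.05), seed = 1)
  expect_equal(st$selected_features, "F2")
  # with a decisive margin the algorithm overrules the suggestion and keeps F1
  st2 <- guided_sfs(tbl, d, k = 1, scorer = fixed_scorer(c(F1 = 0.95, F2 = 0.60, F3 = 0.5)),
                    cfg = preference_config(sfs_slack = 0.05), seed = 1)
  expect_equal(st2$selected_features, "F1")
})

test_that("selection is deterministic and sized min(k, available)", {
  tbl <- tiny_table(n = 20, p = 5, seed = 9)
  a <- guided_sfs(tbl, k = 3, seed = 2)
  b <- guided_sfs(tbl, k = 3, seed = 2)
  expect_identical(a$selected_features, b$selected_features)
  all5 <- guided_sfs(tbl, k = 99, seed = 2)
  expect_equal(length(all5$selected_features), 5)
})
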
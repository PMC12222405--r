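test_that("MCCV splits have the stated sizes, stratification and determinism", {
  tbl <- glioma_small() # n = 69, 23 pos / 46 neg
  sp <- make_mccv_splits(tbl, folds = 100, test_fraction = 0.2, master_seed = 3)
  expect_equal(nrow(sp), 100)
  expect_true(all(lengths(sp$test_ids) == 14)) # round-half-up 0.2 * 69
  expect_true(all(lengths(sp$train_ids) == 55))
  for (i in c(1, 50, 100)) {
    expect_length(intersect(sp$train_ids[[i]], sp$test_ids[[i]]), 0)
    expect_setequal(c(sp$train_ids[[i]], sp$test_ids[[i]]), tbl$sample_id)
    y_te <- tbl$label[tbl$sample_id %in% sp$test_ids[[i]]]
    expect_equal(as.integer(table(y_te)), c(9L, 5L)) # largest remainder: 9 neg, 5 pos
  }
  expect_identical(sp, make_mccv_splits(tbl, 100, 0.2, 3))
  expect_false(identical(sp$test_ids[[1]],
                         make_mccv_splits(tbl, 100, 0.2, 4)$test_ids[[1]]))
})

test_that("single-fold splits and small-class errors behave", {
  tbl <- glioma_small()
  one <- make_mccv_splits(tbl, folds = 1, test_fraction = 0.2, master_seed = 1)
  expect_equal(nrow(one), 1)
  tiny <- tiny_table(n = 12, p = 3, pos_frac = 1 / 12)
  expect_error(make_mccv_splits(tiny, 5, 0.2, 1), "too small")
  expect_error(make_mccv_splits(tbl, 5, 0.7, 1), "test_fraction")
})

test_that("confusion metrics match hand-computed values and boundary cases", {
  # TP=3 FN=1 TN=2 FP=2
  y_true <- c(rep("pos", 4), rep("neg", 4))
  y_pred <- c("pos", "pos", "pos", "neg", "pos", "pos", "neg", "neg")
  m <- confusion_metrics(y_true, y_pred, positive = "pos")
  expect_equal(m$SENS, 0.75)
  expect_equal(m$SPEC, 0.5)
  expect_equal(m$BACC, 0.625)
  expect_equal(m$ACC, 5 / 8)

  perfect <- confusion_metrics(c("pos", "neg"), c("pos", "neg"), positive = "pos")
  expect_true(all(unlist(perfect[c("SENS", "SPEC", "PPV", "NPV", "ACC", "BACC")]) == 1))

  allpos <- confusion_metrics(c("pos", "neg", "neg"), rep("pos", 3), positive = "pos")
  expect_equal(allpos$SPEC, 0)
  expect_equal(allpos$BACC, allpos$SENS / 2)
  expect_error(confusion_metrics(character(), character()), "empty")
})

test_that("metric formulas match brute-force enumeration for all totals <= 12", {
  # independent oracle: construct label vectors for every (TP, FP, TN, FN)
  # cell combination and recompute each ratio from first principles
  for (total in 1:12) {
    parts <- expand.grid(TP = 0:total, FP = 0:total, TN = 0:total)
    parts$FN <- total - parts$TP - parts$FP - parts$TN
    parts <- parts[parts$FN >= 0, ]
    for (r in seq_len(nrow(parts))) {
      tp <- parts$TP[r]; fp <- parts$FP[r]; tn <- parts$TN[r]; fn <- parts$FN[r]
      y_true <- c(rep("pos", tp), rep("neg", fp), rep("neg", tn), rep("pos", fn))
      y_pred <- c(rep("pos", tp), rep("pos", fp), rep("neg", tn), rep("neg", fn))
      m <- confusion_metrics(y_true, y_pred, positive = "pos")
      expect_identical(c(m$TP, m$FP, m$TN, m$FN), c(tp, fp, tn, fn))
      safe <- function(num, den) if (den == 0) NA_real_ else num / den
      expect_identical(m$SENS, safe(tp, tp + fn))
      expect_identical(m$SPEC, safe(tn, tn + fp))
      expect_identical(m$PPV, safe(tp, tp + fp))
      expect_identical(m$NPV, safe(tn, tn + fn))
      expect_equal(m$ACC, (tp + tn) / total)
      expect_equal(m$BACC, (m$SENS + m$SPEC) / 2)
      expect_equal(m$ACC * total, tp + tn)
    }
  }
})

test_that("all classifiers separate linearly separable toy data perfectly", {
  x <- cbind(f1 = c(rnorm(10, -3), rnorm(10, 3)), f2 = rnorm(20))
  tbl <- table_from_matrix(x, labels = rep(c("neg", "pos"), each = 10))
  for (alg in c("xgboost", "random_forest", "svm", "dlda")) {
    clf <- train_classifier(tbl, alg, seed = 1)
    acc <- confusion_metrics(tbl$label, predict(clf, tbl), "pos")$ACC
    expect_equal(acc, 1.0, info = alg)
    # determinism: identical (data, seed) -> identical predictions
    clf2 <- train_classifier(tbl, alg, seed = 1)
    expect_identical(predict(clf2, tbl, type = "prob"),
                     predict(clf, tbl, type = "prob"), info = alg)
  }
  solo <- tbl[c(1, 11), ]
  expect_error(train_classifier(solo, "xgboost", seed = 1), "2 samples per class")
})

test_that("scenario comparison computes ANOVA p-values against the baseline", {
  tbl <- glioma_small()
  cfg <- experiment_config(folds = 4, master_seed = 7, budget = 5, classifier = "dlda")
  sp <- make_mccv_splits(tbl, 4, 0.2, 7)
  r0 <- run_experiment(tbl, "manual", "norst", config = cfg, splits = sp)
  rk <- run_experiment(tbl, "manual", "exp_keep",
                       rules = scenario_rules("exp_keep", PLANTED),
                       config = cfg, splits = sp)
  cmp <- compare_scenarios(list(r0, rk))
  expect_equal(nrow(cmp), 2)
  expect_true(is.na(cmp$p_vs_norst[cmp$rule_scenario == "norst"]))
  expect_true(cmp$p_vs_norst[cmp$rule_scenario == "exp_keep"] <= 1)

  # identical reports -> p = 1
  r0b <- r0
  r0b$rule_scenario <- "pref_keep"
  cmp2 <- compare_scenarios(list(r0, r0b))
  expect_equal(cmp2$p_vs_norst[2], 1)

  # mismatched splits are refused
  r_other <- run_experiment(tbl, "manual", "norst",
                            config = cfg, splits = make_mccv_splits(tbl, 4, 0.2, 8))
  expect_error(compare_scenarios(list(r0, r_other)), "identical splits")
})

test_that("constructed BACC vectors give the closed-form ANOVA p-value", {
  a <- rep(c(0.49, 0.51), 50) # mean 0.5, variance broken by alternation
  b <- rep(c(0.89, 0.91), 50) # mean 0.9
  # closed form one-way ANOVA: F = n * (between MS) / (within MS)
  v <- c(a, b); g <- rep(1:2, each = 100)
  ssb <- 100 * ((0.5 - mean(v))^2 + (0.9 - mean(v))^2)
  ssw <- sum((a - 0.5)^2) + sum((b - 0.9)^2)
  f_stat <- (ssb / 1) / (ssw / 198)
  p_expected <- pf(f_stat, 1, 198, lower.tail = FALSE)
  sp <- tibble::tibble(fold = 1L, train_ids = list("a"), test_ids = list("b"))
  fake_report <- function(scenario, bacc) {
    structure(list(dp_mode = "manual", rule_scenario = scenario,
                   folds = tibble::tibble(BACC = bacc, ACC = NA_real_,
                                          SENS = NA_real_, SPEC = NA_real_,
                                          error = NA_character_),
                   splits = sp), class = "rst_eval")
  }
  r1 <- fake_report("norst", a)
  r2 <- fake_report("pref_keep", b)
  cmp <- compare_scenarios(list(r1, r2))
  expect_equal(cmp$p_vs_norst[2], p_expected, tolerance = 1e-10)
  expect_lt(cmp$p_vs_norst[2], 0.001)
})

test_that("dual-center evaluation is a single train/test fold with NA p-value", {
  dl <- generate_cohort(cohort_preset("dlbcl_twin", seed = 8))
  cfg <- experiment_config(classifier = "dlda", master_seed = 3, budget = 10,
                           dual_center = TRUE)
  r0 <- run_experiment(dl, "manual", "norst", config = cfg)
  expect_equal(nrow(r0$folds), 1)
  expect_equal(r0$folds$n_train, 44)
  expect_equal(r0$folds$n_test, 41)
  rk <- run_experiment(dl, "manual", "exp_keep",
                       rules = scenario_rules("exp_keep", PLANTED), config = cfg)
  cmp <- compare_scenarios(list(r0, rk))
  expect_true(all(is.na(cmp$p_vs_norst)))
})

test_that("feature occurrence recounts selections; explicit rules pin it to 0/1", {
  tbl <- glioma_small()
  cfg <- experiment_config(folds = 3, master_seed = 5, budget = 8, classifier = "dlda")
  sp <- make_mccv_splits(tbl, 3, 0.2, 5)
  rk <- run_experiment(tbl, "manual", "exp_keep",
                       rules = scenario_rules("exp_keep", PLANTED),
                       config = cfg, splits = sp)
  occ <- feature_occurrence(rk)
  expect_true(all(occ$occurrence[match(PLANTED, occ$feature)] == 1))
  rr <- run_experiment(tbl, "manual", "exp_remove",
                       rules = scenario_rules("exp_remove", PLANTED),
                       config = cfg, splits = sp)
  occ_r <- feature_occurrence(rr)
  expect_true(all(occ_r$occurrence[match(PLANTED, occ_r$feature)] == 0))
  # hand recount on the report itself
  f1 <- occ$feature[1]
  expect_equal(occ$occurrence[1],
               mean(vapply(rk$selected, function(s) f1 %in% s, logical(1))))
})

test_that("scenario/rules consistency is validated", {
  tbl <- glioma_small()
  cfg <- experiment_config(folds = 2, master_seed = 5, budget = 5, classifier = "dlda")
  expect_error(run_experiment(tbl, "manual", "exp_keep", rules = NULL, config = cfg),
               "requires a non-empty rule set")
  expect_error(run_experiment(tbl, "manual", "norst",
                              rules = scenario_rules("exp_keep", PLANTED), config = cfg),
               "must not carry rules")
  # an empty rules object is equivalent to norst with NULL rules
  sp <- make_mccv_splits(tbl, 2, 0.2, 5)
  a <- run_experiment(tbl, "manual", "norst", rules = NULL, config = cfg, splits = sp)
  b <- run_experiment(tbl, "manual", "norst", rules = parse_rules(""),
                      config = cfg, splits = sp)
  expect_identical(a$folds, b$folds)
})
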
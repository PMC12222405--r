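test_that("undersampling hits the target ratio exactly", {
  tbl <- tiny_table(n = 60, p = 3, pos_frac = 1 / 3) # 20 pos vs 40 neg
  st <- guided_undersample(tbl, target_ratio = 1, seed = 4)
  expect_equal(as.integer(table(st$table$label)), c(20L, 20L))
  expect_equal(length(st$removed_samples), 20)
  expect_true(all(st$removed_samples %in% tbl$sample_id[tbl$label == "neg"]))
})

test_that("exp-keep protection can make the target infeasible", {
  tbl <- tiny_table(n = 60, p = 3, pos_frac = 1 / 3)
  maj <- tbl$sample_id[tbl$label == "neg"]
  d <- compile_rules(parse_rules(
    sprintf("sample exp-keep name=%s", paste(maj[1:25], collapse = ","))), tbl)
  # 20 removals needed, only 15 removable
  expect_error(guided_undersample(tbl, d, target_ratio = 1, seed = 4), "infeasible")
})

test_that("preference weights shift removal frequencies as an independent oracle predicts", {
  tbl <- tiny_table(n = 30, p = 2, pos_frac = 1 / 3) # 10 pos vs 20 neg, 10 removals
  maj <- tbl$sample_id[tbl$label == "neg"]
  w <- 4
  d <- compile_rules(parse_rules(c(
    sprintf("sample pref-remove name=%s", maj[1]),
    sprintf("sample pref-keep name=%s", maj[2]))), tbl)
  n_rep <- 600
  freq <- matrix(0, n_rep, 3, dimnames = list(NULL, c("pref_remove", "pref_keep", "plain")))
  for (r in seq_len(n_rep)) {
    st <- guided_undersample(tbl, d, target_ratio = 1,
                             cfg = preference_config(undersample_weight = w), seed = r)
    freq[r, ] <- c(maj[1] %in% st$removed_samples, maj[2] %in% st$removed_samples,
                   maj[3] %in% st$removed_samples)
  }
  emp <- colMeans(freq)
  # independent oracle: hand-rolled successive weighted sampling without
  # replacement (inverse-CDF draws), same weights, averaged over many runs
  oracle <- replicate(4000, {
    wts <- c(w, 1 / w, rep(1, 18))
    picked <- logical(20)
    for (k in 1:10) {
      p <- wts; p[picked] <- 0
      u <- runif(1) * sum(p)
      i <- which(cumsum(p) >= u)[1]
      picked[i] <- TRUE
    }
    picked[1:3]
  })
  exp_freq <- rowMeans(oracle)
  expect_true(all(abs(emp - exp_freq) < 0.07))
  # monotonicity: pref-remove > unmarked > pref-keep
  expect_gt(emp["pref_remove"], emp["plain"])
  expect_lt(emp["pref_keep"], emp["plain"])
})

test_that("SMOTE interpolates on the segment between minority neighbors", {
  x <- rbind(c(0, 0), c(1, 1), matrix(rnorm(8, 10), 4, 2))
  colnames(x) <- c("u", "v")
  tbl <- table_from_matrix(x, labels = c("pos", "pos", rep("neg", 4)))
  st <- guided_smote(tbl, k_neighbors = 1, target_ratio = 0.75, seed = 2)
  syn <- st$table[st$table$.synthetic, ]
  expect_equal(nrow(syn), 1)
  # the only two minority points are mutual 1-NNs: new point lies on their segment
  expect_equal(syn$u, syn$v, tolerance = 1e-12)
  expect_true(syn$u >= 0 && syn$u <= 1)
})

test_that("SMOTE adds the exact count of flagged synthetic minority rows", {
  tbl <- tiny_table(n = 69, p = 4, pos_frac = 1 / 3) # 23 pos vs 46 neg
  st <- guided_smote(tbl, k_neighbors = 5, target_ratio = 1, seed = 3)
  expect_equal(nrow(st$table), 92)
  syn <- st$table[st$table$.synthetic, ]
  expect_equal(nrow(syn), 23)
  expect_true(all(syn$label == "pos"))
  expect_false(any(syn$sample_id %in% tbl$sample_id))
})

test_that("SMOTE is the identity on balanced tables and validates k", {
  tbl <- tiny_table(n = 20, p = 3, pos_frac = 0.5)
  st <- guided_smote(tbl, seed = 1)
  expect_identical(st$table, tbl)
  small <- tiny_table(n = 20, p = 3, pos_frac = 0.2) # 4 minority samples
  expect_error(guided_smote(small, k_neighbors = 5, seed = 1), "lower k")
})

test_that("resampling operators are seed-deterministic", {
  tbl <- tiny_table(n = 45, p = 3, pos_frac = 1 / 3)
  expect_identical(guided_undersample(tbl, seed = 7)$removed_samples,
                   guided_undersample(tbl, seed = 7)$removed_samples)
  expect_identical(guided_smote(tbl, seed = 7)$table, guided_smote(tbl, seed = 7)$table)
})
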
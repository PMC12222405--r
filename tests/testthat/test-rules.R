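test_that("parsing covers the grammar and records line numbers", {
  rs <- parse_rules(c("# header comment", "",
                      "feature exp-keep name=TLG_g_Total",
                      "sample pref-remove where=age>80",
                      "feature pref-keep pattern=GLCM_*"))
  expect_s3_class(rs, "rst_ruleset")
  expect_equal(nrow(rs), 3)
  expect_equal(rs$line_no, c(3L, 4L, 5L))
  expect_equal(rs$scope, c("feature", "sample", "feature"))
  expect_equal(rs$action, c("exp_keep", "pref_remove", "pref_keep"))
  expect_equal(rs$names[[1]], "TLG_g_Total")
  expect_equal(rs$attribute[2], "age")
  expect_equal(rs$comparator[2], ">")
  expect_equal(rs$value[2], "80")
  expect_equal(rs$pattern[3], "GLCM_*")
})

test_that("an empty file parses to zero rules and compiles to all-none", {
  rs <- parse_rules("")
  expect_equal(nrow(rs), 0)
  d <- compile_rules(rs, tiny_table(), quiet = TRUE)
  expect_true(all(d$feature == "none"))
  expect_true(all(d$sample == "none"))
})

test_that("serialization round-trips to canonical form", {
  txt <- c("sample pref-remove where=age>80", "feature   pref-keep    pattern=GLCM_*",
           "feature exp-keep name=F1, F2")
  rs <- parse_rules(txt)
  canon <- format(rs)
  expect_equal(canon, c("sample pref-remove where=age>80",
                        "feature pref-keep pattern=GLCM_*",
                        "feature exp-keep name=F1,F2"))
  # idempotence after one canonicalization pass
  expect_equal(format(parse_rules(canon)), canon)
})

test_that("syntax errors are rejected with line number and token", {
  expect_error(parse_rules("feature keepit name=F1"), "line 1.*keepit")
  expect_error(parse_rules(c("feature exp-keep name=F1", "banana exp-keep name=F1")),
               "line 2.*banana")
  expect_error(parse_rules("feature exp-keep"), "syntax error at line 1")
  expect_error(parse_rules("feature exp-keep foo=F1"), "selector")
  expect_error(parse_rules("feature exp-keep where=age>80"), "scope=sample only")
  expect_error(parse_rules("sample exp-keep where=age>>80"), "cannot parse condition")
})

test_that("validate_rules classifies contradictions, overrides and duplicates", {
  fatal <- validate_rules(parse_rules(c("feature exp-keep name=F1",
                                        "feature exp-remove name=F1")))
  expect_equal(fatal$severity, "fatal")
  expect_equal(fatal$type, "contradiction")

  soft <- validate_rules(parse_rules(c("feature exp-keep name=F1",
                                       "feature pref-remove name=F1")))
  expect_equal(soft$severity, "note")
  expect_equal(soft$resolution, "exp_keep")

  dup <- validate_rules(parse_rules(c("feature pref-keep name=F1",
                                      "feature pref-keep name=F1")))
  expect_equal(dup$type, "duplicate_rule")

  expect_equal(nrow(validate_rules(parse_rules("feature exp-keep name=F1"))), 0)
})

test_that("compile resolves names, globs and conditions against the table", {
  tbl <- tiny_table(n = 10, p = 6) # GLCM_a GLCM_b GLCM_c NGTDM_a NGTDM_b NGTDM_c
  d <- compile_rules(parse_rules(c("feature exp-keep name=GLCM_a,GLCM_b",
                                   "feature pref-keep pattern=NGTDM_*")), tbl)
  expect_equal(unname(d$feature[c("GLCM_a", "GLCM_b")]), rep("exp_keep", 2))
  expect_equal(unname(d$feature[c("NGTDM_a", "NGTDM_b", "NGTDM_c")]), rep("pref_keep", 3))
  expect_equal(unname(d$feature["GLCM_c"]), "none")

  # glob expansion matches an independently computed match set
  feats <- feature_names(tbl)
  expect_setequal(names(d$feature)[d$feature == "pref_keep"],
                  feats[startsWith(feats, "NGTDM_")])
})

test_that("sample conditions evaluate on current values; no match is unresolved", {
  tbl <- tiny_table(n = 10, p = 3)
  tbl$age <- c(85, 70, 90, rep(60, 7))
  d <- compile_rules(parse_rules("sample pref-remove where=age>80"), tbl)
  expect_setequal(names(d$sample)[d$sample == "pref_remove"],
                  tbl$sample_id[tbl$age > 80])

  # max age 79 -> nothing matches, warning + unresolved record
  tbl$age <- rep(60, 10)
  expect_warning(d2 <- compile_rules(parse_rules("sample pref-remove where=age>80"), tbl),
                 "no effect")
  expect_true(all(d2$sample == "none"))
  expect_equal(d2$unresolved$reason, "no match")
})

test_that("explicit rules naming absent targets are hard errors; preferential warn", {
  tbl <- tiny_table(n = 10, p = 3)
  expect_error(compile_rules(parse_rules("feature exp-keep name=NOPE"), tbl),
               "unknown feature")
  expect_error(compile_rules(parse_rules("sample exp-remove name=ZZZ"), tbl),
               "unknown sample")
  expect_warning(d <- compile_rules(parse_rules("feature pref-keep name=NOPE"), tbl),
                 "unknown feature")
  expect_true(all(d$feature == "none"))
})

test_that("fatal conflicts block compilation, including cross-selector ones", {
  tbl <- tiny_table(n = 10, p = 6)
  expect_error(compile_rules(parse_rules(c("feature exp-keep name=GLCM_a",
                                           "feature exp-remove name=GLCM_a")), tbl),
               "fatal")
  # contradiction only visible after glob expansion
  expect_error(compile_rules(parse_rules(c("feature exp-remove pattern=GLCM_*",
                                           "feature exp-keep name=GLCM_a")), tbl),
               "both exp-keep and exp-remove")
})

test_that("precedence: explicit beats preferential; later line wins within a level", {
  tbl <- tiny_table(n = 10, p = 6)
  # enumerated 2-rule combinations across precedence levels
  combos <- list(
    c("feature pref-remove name=GLCM_a", "feature exp-keep name=GLCM_a"),
    c("feature exp-keep name=GLCM_a", "feature pref-remove name=GLCM_a"))
  for (cmb in combos) {
    d <- compile_rules(parse_rules(cmb), tbl, quiet = TRUE)
    expect_equal(unname(d$feature["GLCM_a"]), "exp_keep")
  }
  # same level: last wins
  d <- compile_rules(parse_rules(c("feature pref-keep name=GLCM_a",
                                   "feature pref-remove name=GLCM_a")), tbl, quiet = TRUE)
  expect_equal(unname(d$feature["GLCM_a"]), "pref_remove")
  # 3-rule combination: reordering across levels leaves the resolution fixed
  rules3 <- c("feature pref-keep name=GLCM_a", "feature exp-remove name=GLCM_a",
              "feature pref-remove name=GLCM_a")
  for (perm in list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    d <- compile_rules(parse_rules(rules3[perm]), tbl, quiet = TRUE)
    expect_equal(unname(d$feature["GLCM_a"]), "exp_remove")
  }
})

test_that("tidy() and JSON export expose the compiled map", {
  tbl <- tiny_table(n = 10, p = 6)
  d <- compile_rules(parse_rules("feature exp-keep name=GLCM_a"), tbl)
  td <- tidy(d)
  expect_equal(td$target, "GLCM_a")
  expect_equal(td$action, "exp_keep")
  path <- withr::local_tempfile(fileext = ".json")
  write_directives_json(d, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$feature$GLCM_a, "exp_keep")
})
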
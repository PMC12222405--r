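#' Parse a rule-set table (RST) file
#'
#' Clinicians write one rule per line in a plain-text file:
#'
#' ```
#' # comment lines and blank lines are ignored
#' feature exp-keep   name=TLG_g_Total,Coarseness
#' feature pref-keep  pattern=GLCM_*
#' sample  pref-remove where=age>80
#' ```
#'
#' A rule is `<scope> <action> <selector>` with scope `feature` or `sample`,
#' action one of `exp-keep`, `exp-remove`, `pref-keep`, `pref-remove`
#' (explicit actions are hard constraints; preferential actions are
#' suggestions the algorithms may overrule), and selector one of
#' `name=<comma-list>`, `pattern=<glob>` or `where=<attr><cmp><value>` with
#' comparator `<`, `<=`, `==`, `>=`, `>` or `!=`. Feature-scope conditions are
#' restricted to name selectors and patterns; `where=` conditions address
#' sample-level columns (features or metadata such as `center`).
#'
#' @param text rule file content (single string or character vector of
#'   lines), or a file path if `file = TRUE`.
#' @param file interpret `text` as a path.
#' @return A `rst_ruleset`: a tibble with one row per rule (columns
#'   `line_no`, `scope`, `action`, `selector`, `names`, `pattern`,
#'   `attribute`, `comparator`, `value`).
#' @export
parse_rules <- function(text, file = FALSE) {
  if (file) {
    lines <- readLines(text, warn = FALSE)
    src <- text
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
    src <- NA_character_
  }
  rules <- list()
  for (i in seq_along(lines)) {
    raw <- trimws(lines[i])
    if (raw == "" || startsWith(raw, "#")) next
    rules[[length(rules) + 1L]] <- parse_rule_line(raw, i)
  }
  rs <- if (length(rules)) bind_rows(rules) else empty_ruleset_tbl()
  structure(rs, class = c("rst_ruleset", class(tibble())), source_path = src)
}

empty_ruleset_tbl <- function() {
  tibble(line_no = integer(), scope = character(), action = character(),
         selector = character(), names = list(), pattern = character(),
         attribute = character(), comparator = character(), value = character())
}

parse_rule_line <- function(raw, line_no) {
  toks <- strsplit(raw, "[[:space:]]+")[[1]]
  if (length(toks) > 3) {
    # tolerate spaces after commas in name lists: rejoin the selector tokens
    tail_toks <- toks[3:length(toks)]
    joined <- paste(tail_toks, collapse = "")
    if (grepl(",", joined, fixed = TRUE)) toks <- c(toks[1:2], joined)
  }
  if (length(toks) != 3) {
    abort(sprintf("rule syntax error at line %d: expected '<scope> <action> <selector>', got '%s'",
                  line_no, raw))
  }
  scope <- toks[1]
  if (!scope %in% RULE_SCOPES) {
    abort(sprintf("line %d: unknown scope '%s' (expected feature|sample)", line_no, scope))
  }
  action <- gsub("-", "_", toks[2], fixed = TRUE)
  if (!action %in% RULE_ACTIONS) {
    abort(sprintf("line %d: unknown action keyword '%s' (expected exp-keep|exp-remove|pref-keep|pref-remove)",
                  line_no, toks[2]))
  }
  sel <- toks[3]
  out <- tibble(line_no = as.integer(line_no), scope = scope, action = action,
                selector = NA_character_, names = list(character()),
                pattern = NA_character_, attribute = NA_character_,
                comparator = NA_character_, value = NA_character_)
  if (startsWith(sel, "name=")) {
    nm <- strsplit(substring(sel, 6), ",", fixed = TRUE)[[1]]
    nm <- trimws(nm[nzchar(trimws(nm))])
    if (!length(nm)) abort(sprintf("line %d: empty name list", line_no))
    out$selector <- "name"
    out$names <- list(nm)
  } else if (startsWith(sel, "pattern=")) {
    pat <- substring(sel, 9)
    if (!nzchar(pat)) abort(sprintf("line %d: empty pattern", line_no))
    out$selector <- "pattern"
    out$pattern <- pat
  } else if (startsWith(sel, "where=")) {
    if (scope == "feature") {
      abort(sprintf("line %d: 'where=' conditions are supported for scope=sample only; use name= or pattern= for features",
                    line_no))
    }
    cond <- substring(sel, 7)
    m <- regexec("^([A-Za-z0-9_.]+)(<=|>=|==|!=|<|>)(.+)$", cond)[[1]]
    if (m[1] == -1) {
      abort(sprintf("line %d: cannot parse condition '%s' (expected <attr><cmp><value>)",
                    line_no, cond))
    }
    parts <- regmatches(cond, regexec("^([A-Za-z0-9_.]+)(<=|>=|==|!=|<|>)(.+)$", cond))[[1]]
    if (grepl("^[<>=!]", parts[4])) {
      abort(sprintf("line %d: cannot parse condition '%s' (expected <attr><cmp><value>)",
                    line_no, cond))
    }
    out$selector <- "condition"
    out$attribute <- parts[2]
    out$comparator <- parts[3]
    out$value <- parts[4]
  } else {
    abort(sprintf("line %d: unknown selector token '%s' (expected name=|pattern=|where=)",
                  line_no, sel))
  }
  out
}

#' Serialize a rule set back to canonical rule-file text
#' @param x a `rst_ruleset`.
#' @param ... unused.
#' @return Character vector, one canonical rule line per rule.
#' @export
format.rst_ruleset <- function(x, ...) {
  if (!nrow(x)) return(character())
  vapply(seq_len(nrow(x)), function(i) {
    sel <- switch(x$selector[i],
      name = paste0("name=", paste(x$names[[i]], collapse = ",")),
      pattern = paste0("pattern=", x$pattern[i]),
      condition = paste0("where=", x$attribute[i], x$comparator[i], x$value[i]))
    paste(x$scope[i], gsub("_", "-", x$action[i], fixed = TRUE), sel)
  }, character(1))
}

#' @export
print.rst_ruleset <- function(x, ...) {
  cat(sprintf("<rst_ruleset: %d rule(s)>\n", nrow(x)))
  if (nrow(x)) cat(paste0("  ", format(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Report conflicts within a rule set
#'
#' Conflicts are detected over named targets: the same target under both
#' `exp-keep` and `exp-remove` is fatal; the same target under an explicit
#' and a preferential action is non-fatal (the explicit action wins);
#' duplicated identical rules are warnings.
#'
#' @param rs a `rst_ruleset`.
#' @return A tibble of conflict records (`scope`, `target`, `lines`, `type`,
#'   `severity`, `resolution`); zero rows when the rule set is clean.
#' @export
validate_rules <- function(rs) {
  stopifnot(inherits(rs, "rst_ruleset"))
  out <- list()
  if (nrow(rs)) {
    canon <- format(rs)
    dup <- which(duplicated(canon))
    for (i in dup) {
      out[[length(out) + 1L]] <- tibble(
        scope = rs$scope[i], target = canon[i],
        lines = list(rs$line_no[canon == canon[i]]),
        type = "duplicate_rule", severity = "warning", resolution = NA_character_)
    }
    named <- rs[rs$selector == "name", ]
    if (nrow(named)) {
      flat <- tidyr::unnest(
        tibble(scope = named$scope, action = named$action,
               line_no = named$line_no, target = named$names),
        "target")
      for (key in unique(paste(flat$scope, flat$target))) {
        sub <- flat[paste(flat$scope, flat$target) == key, ]
        acts <- unique(sub$action)
        if (all(c("exp_keep", "exp_remove") %in% acts)) {
          out[[length(out) + 1L]] <- tibble(
            scope = sub$scope[1], target = sub$target[1],
            lines = list(sub$line_no), type = "contradiction",
            severity = "fatal", resolution = NA_character_)
        } else if (any(acts %in% EXPLICIT_ACTIONS) && any(acts %in% PREF_ACTIONS)) {
          out[[length(out) + 1L]] <- tibble(
            scope = sub$scope[1], target = sub$target[1],
            lines = list(sub$line_no), type = "explicit_overrides_preference",
            severity = "note", resolution = intersect(acts, EXPLICIT_ACTIONS)[1])
        }
      }
    }
  }
  if (length(out)) bind_rows(out) else {
    tibble(scope = character(), target = character(), lines = list(),
           type = character(), severity = character(), resolution = character())
  }
}

## which targets (among 'universe') a single rule row matches; for sample
## scope, 'tbl' supplies the columns conditions are evaluated on
match_rule <- function(rule, universe, tbl = NULL, scope = rule$scope) {
  switch(rule$selector,
    name = intersect(rule$names[[1]], universe),
    pattern = universe[grepl(glob_to_regex(rule$pattern), universe)],
    condition = {
      attr_col <- rule$attribute
      if (is.null(tbl) || !attr_col %in% names(tbl)) return(character())
      v <- tbl[[attr_col]]
      rhs <- rule$value
      if (is.numeric(v)) {
        rhs_n <- suppressWarnings(as.numeric(rhs))
        if (is.na(rhs_n)) {
          abort(sprintf("line %d: non-numeric value '%s' compared against numeric column '%s'",
                        rule$line_no, rhs, attr_col))
        }
        hit <- switch(rule$comparator,
          "<" = v < rhs_n, "<=" = v <= rhs_n, "==" = v == rhs_n,
          ">=" = v >= rhs_n, ">" = v > rhs_n, "!=" = v != rhs_n)
      } else {
        if (!rule$comparator %in% c("==", "!=")) {
          abort(sprintf("line %d: comparator '%s' not valid for non-numeric column '%s'",
                        rule$line_no, rule$comparator, attr_col))
        }
        hit <- if (rule$comparator == "==") as.character(v) == rhs else as.character(v) != rhs
      }
      tbl$sample_id[which(hit)]
    })
}

#' Compile a rule set against a concrete feature table
#'
#' Selectors are resolved against the table's actual feature names and sample
#' ids: name lists are checked, glob patterns expanded, `where=` conditions
#' evaluated on current values. Precedence is explicit > preferential; within
#' a level the later rule line wins. An explicit rule *naming* a feature or
#' sample absent from the table is a hard error (a clinician hard requirement
#' must not be silently dropped); a preferential rule matching nothing is
#' recorded as unresolved with a warning.
#'
#' @param rs a `rst_ruleset` with no fatal conflicts.
#' @param table a feature-table tibble.
#' @param quiet suppress the no-match warning.
#' @return A `rst_directives` object: list with named character vectors
#'   `feature` and `sample` (values in `exp_keep`, `exp_remove`, `pref_keep`,
#'   `pref_remove`, `none`) and an `unresolved` tibble.
#' @export
compile_rules <- function(rs, table, quiet = FALSE) {
  stopifnot(inherits(rs, "rst_ruleset"))
  check_feature_table(table)
  confl <- validate_rules(rs)
  if (any(confl$severity == "fatal")) {
    bad <- confl[confl$severity == "fatal", ]
    abort(paste0("fatal rule conflicts: ",
                 paste(sprintf("%s '%s' under both exp-keep and exp-remove (lines %s)",
                               bad$scope, bad$target,
                               vapply(bad$lines, function(l) paste(l, collapse = ","), "")),
                       collapse = "; ")))
  }
  feats <- feature_names(table)
  samps <- table$sample_id
  unresolved <- list()
  ## per-target matched rules, file order preserved
  hits <- list(feature = list(), sample = list())
  for (i in seq_len(nrow(rs))) {
    rule <- rs[i, ]
    universe <- if (rule$scope == "feature") feats else samps
    matched <- match_rule(rule, universe, tbl = table)
    if (rule$selector == "name") {
      missing <- setdiff(rule$names[[1]], universe)
      if (length(missing)) {
        if (rule$action %in% EXPLICIT_ACTIONS) {
          abort(sprintf("line %d: explicit rule names unknown %s(s): %s",
                        rule$line_no, rule$scope, paste(missing, collapse = ", ")))
        }
        why <- paste0("unknown ", rule$scope, "(s): ", paste(missing, collapse = ", "))
        unresolved[[length(unresolved) + 1L]] <- tibble(
          line_no = rule$line_no, rule = format(rs)[i], reason = why)
      }
    }
    if (!length(matched)) {
      unresolved[[length(unresolved) + 1L]] <- tibble(
        line_no = rule$line_no, rule = format(rs)[i], reason = "no match")
      next
    }
    for (t in matched) {
      hits[[rule$scope]][[t]] <- rbind(
        hits[[rule$scope]][[t]],
        data.frame(action = rule$action, line_no = rule$line_no))
    }
  }
  resolve <- function(h) {
    expl <- h[h$action %in% EXPLICIT_ACTIONS, ]
    if (nrow(expl)) {
      if (length(unique(expl$action)) > 1) {
        abort(paste0("target resolved to both exp-keep and exp-remove (lines ",
                     paste(expl$line_no, collapse = ","), ")"))
      }
      return(expl$action[which.max(expl$line_no)])
    }
    h$action[which.max(h$line_no)]
  }
  feature_action <- setNames(rep("none", length(feats)), feats)
  for (t in names(hits$feature)) feature_action[[t]] <- resolve(hits$feature[[t]])
  sample_action <- setNames(rep("none", length(samps)), samps)
  for (t in names(hits$sample)) sample_action[[t]] <- resolve(hits$sample[[t]])
  unresolved <- if (length(unresolved)) bind_rows(unresolved) else {
    tibble(line_no = integer(), rule = character(), reason = character())
  }
  if (!quiet && nrow(unresolved)) {
    warn(paste0("rules with no effect: ",
                paste(sprintf("line %d (%s)", unresolved$line_no, unresolved$reason),
                      collapse = "; ")))
  }
  structure(list(feature = feature_action, sample = sample_action,
                 unresolved = unresolved),
            class = "rst_directives")
}

#' An empty directive map for a table (the "no rules" scenario)
#' @param table a feature-table tibble.
#' @return A `rst_directives` with every action `none`.
#' @export
empty_directives <- function(table) {
  compile_rules(parse_rules(character()), table, quiet = TRUE)
}

## targets under a given action (helper used by every guided operator)
dir_targets <- function(d, scope, action) {
  v <- d[[scope]]
  names(v)[v == action]
}

## look up actions for ids/names possibly absent from the map -> "none"
dir_action <- function(d, scope, targets) {
  v <- d[[scope]]
  out <- setNames(rep("none", length(targets)), targets)
  known <- intersect(targets, names(v))
  out[known] <- v[known]
  out
}

#' @export
print.rst_directives <- function(x, ...) {
  ftab <- table(factor(x$feature, levels = c(RULE_ACTIONS, "none")))
  stab <- table(factor(x$sample, levels = c(RULE_ACTIONS, "none")))
  cat("<rst_directives>\n  features:",
      paste(sprintf("%s=%d", names(ftab), ftab), collapse = " "),
      "\n  samples: ",
      paste(sprintf("%s=%d", names(stab), stab), collapse = " "), "\n")
  if (nrow(x$unresolved)) {
    cat(sprintf("  unresolved: %d rule(s) with no effect\n", nrow(x$unresolved)))
  }
  invisible(x)
}

#' Tidy a directive map into a long tibble
#' @param x a `rst_directives`.
#' @param ... unused.
#' @return Tibble with columns `scope`, `target`, `action` (resolved actions
#'   only, `none` rows dropped).
#' @export
tidy.rst_directives <- function(x, ...) {
  bind_rows(
    tibble(scope = "feature", target = names(x$feature), action = unname(x$feature)),
    tibble(scope = "sample", target = names(x$sample), action = unname(x$sample))
  ) |> filter(.data$action != "none")
}

#' Export a compiled directive map as JSON for audit logging
#' @param d a `rst_directives`.
#' @param path output file.
#' @export
write_directives_json <- function(d, path) {
  jsonlite::write_json(
    list(feature = as.list(d$feature[d$feature != "none"]),
         sample = as.list(d$sample[d$sample != "none"]),
         unresolved = d$unresolved),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
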
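#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed through this
#' function, so that e.g. cross-validation splits are reused bit-identically
#' across experiments while each component still gets an independent stream.
#'
#' @param master integer master seed.
#' @param ... tags (strings or integers) naming the component and repetition.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (tag in list(...)) {
    for (ch in utf8ToInt(paste0(as.character(tag), "|"))) {
      h <- (h * 131 + ch) %% m
    }
  }
  as.integer(max(1, h %% (m - 1)))
}

## round-half-up (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

## evaluate a local RNG stream without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## deterministic ordering of names used for all tie-breaks
lex_order <- function(x) x[order(x, method = "radix")]

## argmax with ties (at tol) broken lexicographically by name
argmax_lex <- function(scores, tol = 1e-12) {
  best <- max(scores)
  cand <- names(scores)[scores >= best - tol]
  lex_order(cand)[1]
}

## glob -> regex (anchored)
glob_to_regex <- function(glob) {
  utils::glob2rx(glob)
}
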
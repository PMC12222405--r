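#' Scale features with parameters fitted on training rows only
#'
#' `zscore` centers/scales to mean 0, SD 1; `minmax` maps the training range
#' to `[0, 1]`. Constant features map to 0 under both methods (no division
#' by zero). The fitted parameters are stored on the step (`$params`) so the
#' identical transform can be replayed on validation rows — validation
#' statistics never influence the fit.
#'
#' @param table a feature-table tibble (the training rows).
#' @param method `"zscore"` or `"minmax"`.
#' @param params optional previously fitted parameters (replay mode).
#' @return A `rst_step`; `$params` holds the fitted transform.
#' @export
scale_features <- function(table, method = c("zscore", "minmax"), params = NULL) {
  method <- match.arg(method)
  check_feature_table(table)
  feats <- feature_names(table)
  m <- feature_matrix(table)
  if (is.null(params)) {
    params <- if (method == "zscore") {
      list(method = "zscore", center = colMeans(m), scale = apply(m, 2, sd))
    } else {
      list(method = "minmax", min = apply(m, 2, min),
           range = apply(m, 2, max) - apply(m, 2, min))
    }
  }
  out <- table
  out[feats] <- as.data.frame(apply_scale_params(m, params, feats))
  step <- new_step_result(out, log = sprintf("scale_%s: %d feature(s)", method, length(feats)))
  step$params <- params
  step
}

apply_scale_params <- function(m, params, feats) {
  if (params$method == "zscore") {
    ctr <- params$center[feats]; scl <- params$scale[feats]
    scl[!is.finite(scl) | scl < 1e-12] <- Inf # constant -> 0
    sweep(sweep(m, 2, ctr, "-"), 2, scl, "/")
  } else {
    mn <- params$min[feats]; rg <- params$range[feats]
    rg[!is.finite(rg) | rg < 1e-12] <- Inf
    sweep(sweep(m, 2, mn, "-"), 2, rg, "/")
  }
}
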
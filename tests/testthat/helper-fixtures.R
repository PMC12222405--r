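# fixtures are generated in code; nothing is read from disk

PLANTED <- c("TLG_g_Total", "Coarseness", "Busyness",
             "HardArea_Volume", "Max_Diameter_mm_VOI")

# a small deterministic feature table with named feature families
tiny_table <- function(n = 20, p = 6, seed = 1, pos_frac = 0.5,
                       feature_names = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  feature_names <- feature_names %||%
    c(paste0("GLCM_", letters[seq_len(min(p, 3))]),
      paste0("NGTDM_", letters[seq_len(max(p - 3, 0))]))[seq_len(p)]
  colnames(x) <- feature_names
  df <- tibble::as_tibble(as.data.frame(x))
  df$sample_id <- sprintf("S%03d", seq_len(n))
  npos <- round(n * pos_frac)
  df$label <- rep(c("pos", "neg"), c(npos, n - npos))
  as_feature_table(df, positive = "pos")
}

# build a table from an explicit matrix (rows x named columns)
table_from_matrix <- function(x, labels, ids = NULL, center = NULL) {
  df <- tibble::as_tibble(as.data.frame(x))
  df$sample_id <- ids %||% sprintf("S%03d", seq_len(nrow(x)))
  df$label <- labels
  if (!is.null(center)) df$center <- center
  as_feature_table(df, positive = "pos")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

glioma_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(cohort_preset("glioma_twin", seed = 5))
    cache
  }
})
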
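#' Recipe for a synthetic radiomics-style cohort
#'
#' Defines the statistical structure of a generated feature table: planted
#' label-associated ("informative") features, groups of redundant correlated
#' features, injected extreme outliers, a multi-center batch effect and label
#' noise. Demographic-like columns (`age`, `weight_kg`, `height_cm`) are
#' always included among the `n_features` columns so that sample-level
#' `where=` rules are exercisable.
#'
#' @param n_samples integer vector of per-center sample counts (length 1 for
#'   a single-center cohort).
#' @param n_features total feature-column count (informative + redundant
#'   members + 3 demographic columns + noise).
#' @param positive_fraction positive-class fraction, one value per center.
#' @param n_informative number of label-associated features.
#' @param effect_size standardized mean shift of informative features in the
#'   positive class (Cohen's d scale).
#' @param redundancy list of `c(size, rho)` pairs: each group is one parent
#'   noise feature plus `size - 1` children mixed to intra-group correlation
#'   `rho`.
#' @param outlier_fraction fraction of samples replanted at ±(6–10) SD.
#' @param center_shift additive batch shift applied to every radiomics
#'   feature of centers after the first.
#' @param label_noise fraction of labels flipped after generation.
#' @param seed integer seed; the table is a pure function of the recipe.
#' @return A `cohort_recipe` list.
#' @export
cohort_recipe <- function(n_samples, n_features, positive_fraction,
                          n_informative = 5, effect_size = 0.8,
                          redundancy = list(), outlier_fraction = 0,
                          center_shift = 0, label_noise = 0, seed = 1L) {
  r <- list(n_samples = as.integer(n_samples), n_features = as.integer(n_features),
            positive_fraction = positive_fraction, n_informative = as.integer(n_informative),
            effect_size = effect_size, redundancy = redundancy,
            outlier_fraction = outlier_fraction, center_shift = center_shift,
            label_noise = label_noise, seed = as.integer(seed))
  if (length(r$positive_fraction) == 1) {
    r$positive_fraction <- rep(r$positive_fraction, length(r$n_samples))
  }
  if (length(r$positive_fraction) != length(r$n_samples)) {
    abort("positive_fraction must have one value per center")
  }
  fracs <- c(r$positive_fraction, r$outlier_fraction, r$label_noise)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (r$effect_size < 0) abort("effect_size must be >= 0")
  grp_cols <- sum(vapply(r$redundancy, function(g) as.integer(g[1]), 1L))
  need <- r$n_informative + grp_cols + 3L # groups (parent + children) + demographics
  if (need > r$n_features) {
    abort(sprintf("infeasible recipe: n_informative + redundant group members + 3 demographics = %d exceeds n_features = %d",
                  need, r$n_features))
  }
  structure(r, class = "cohort_recipe")
}

## reference prominent-feature names used for all planted features
PLANTED_NAMES <- c("TLG_g_Total", "Coarseness", "Busyness",
                   "HardArea_Volume", "Max_Diameter_mm_VOI")
DEMOGRAPHIC_NAMES <- c("age", "weight_kg", "height_cm")

#' Preset recipes mirroring the shapes of the three study cohorts
#'
#' `glioma_twin`: 69 samples x 160 features, 33% positive;
#' `prostate_twin`: 57 x 306, 48% positive;
#' `dlbcl_twin`: two centers (44 and 41 samples) x 57 features, 32%/39%
#' positive with a nonzero center batch shift. All presets plant 5 named
#' informative features.
#'
#' @param name one of `"glioma_twin"`, `"prostate_twin"`, `"dlbcl_twin"`.
#' @param seed recipe seed.
#' @return A [cohort_recipe()].
#' @export
cohort_preset <- function(name, seed = 101L) {
  presets <- list(
    glioma_twin = function() cohort_recipe(
      n_samples = 69L, n_features = 160L, positive_fraction = 0.33,
      n_informative = 5L, effect_size = 0.8,
      redundancy = list(c(4, 0.90), c(3, 0.85)),
      outlier_fraction = 0.03, seed = seed),
    prostate_twin = function() cohort_recipe(
      n_samples = 57L, n_features = 306L, positive_fraction = 0.48,
      n_informative = 5L, effect_size = 0.8,
      redundancy = list(c(4, 0.90), c(3, 0.85)),
      outlier_fraction = 0.03, seed = seed),
    dlbcl_twin = function() cohort_recipe(
      n_samples = c(44L, 41L), n_features = 57L,
      positive_fraction = c(0.32, 0.39), n_informative = 5L, effect_size = 0.8,
      redundancy = list(c(3, 0.90)), outlier_fraction = 0.03,
      center_shift = 0.6, seed = seed)
  )
  if (!name %in% names(presets)) {
    abort(paste0("unknown preset '", name, "'; available: ",
                 paste(names(presets), collapse = ", ")))
  }
  presets[[name]]()
}

#' Generate a synthetic cohort feature table from a recipe
#'
#' Noise features are standard normal; informative features get an additive
#' `effect_size` shift in the positive class; redundant children are
#' `rho * parent + sqrt(1 - rho^2) * noise`; outlier samples have their
#' radiomics features replanted at a common random sign times U(6, 10) SD;
#' rows of centers after the first are shifted by `center_shift` on all
#' radiomics features; class counts are exact (`round_half_up(n * fraction)`
#' positives per center); fully deterministic in `recipe$seed`.
#'
#' @param recipe a [cohort_recipe()].
#' @return A feature-table tibble (with a `center` column when the recipe
#'   has more than one center).
#' @export
generate_cohort <- function(recipe) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  r <- recipe
  n_centers <- length(r$n_samples)
  n <- sum(r$n_samples)
  n_inf <- r$n_informative
  red_sizes <- vapply(r$redundancy, function(g) as.integer(g[1]), 1L)
  red_rhos <- vapply(r$redundancy, function(g) as.numeric(g[2]), 1.0)
  n_noise <- r$n_features - n_inf - sum(red_sizes) - 3L

  inf_names <- if (n_inf <= length(PLANTED_NAMES)) PLANTED_NAMES[seq_len(n_inf)] else {
    c(PLANTED_NAMES, sprintf("Planted_%02d", seq_len(n_inf - length(PLANTED_NAMES))))
  }
  prefixes <- c("GLCM", "GLRLM", "NGTDM", "Shape", "Intensity")
  noise_names <- sprintf("%s_f%03d", prefixes[(seq_len(n_noise) - 1) %% length(prefixes) + 1],
                         seq_len(n_noise))

  with_seed(r$seed, {
    center_ids <- rep(sprintf("C%d", seq_len(n_centers)), r$n_samples)
    label <- unlist(lapply(seq_len(n_centers), function(ci) {
      nc <- r$n_samples[ci]
      npos <- round_half_up(nc * r$positive_fraction[ci])
      sample(rep(c("pos", "neg"), c(npos, nc - npos)))
    }))
    pos <- label == "pos"

    X_inf <- matrix(rnorm(n * n_inf), n, n_inf)
    X_inf[pos, ] <- X_inf[pos, , drop = FALSE] + r$effect_size
    colnames(X_inf) <- inf_names

    red_cols <- list()
    for (g in seq_along(red_sizes)) {
      parent <- rnorm(n)
      grp <- matrix(NA_real_, n, red_sizes[g])
      grp[, 1] <- parent
      if (red_sizes[g] > 1) {
        for (j in 2:red_sizes[g]) {
          grp[, j] <- red_rhos[g] * parent + sqrt(1 - red_rhos[g]^2) * rnorm(n)
        }
      }
      colnames(grp) <- c(sprintf("Redund_g%d", g),
                         if (red_sizes[g] > 1) sprintf("Redund_g%d_r%d", g, seq_len(red_sizes[g] - 1L)))
      red_cols[[g]] <- grp
    }
    X_red <- if (length(red_cols)) do.call(cbind, red_cols) else matrix(nrow = n, ncol = 0)

    X_noise <- matrix(rnorm(n * n_noise), n, n_noise)
    colnames(X_noise) <- noise_names

    radiomics <- cbind(X_inf, X_red, X_noise)

    ## extreme outliers: whole radiomics profile at a common sign * U(6,10) SD
    n_out <- round_half_up(r$outlier_fraction * n)
    if (n_out > 0) {
      idx <- sample(n, n_out)
      for (i in idx) {
        s <- sample(c(-1, 1), 1)
        radiomics[i, ] <- rnorm(ncol(radiomics)) + s * runif(ncol(radiomics), 6, 10)
      }
    }

    ## center batch effect on radiomics features only
    if (n_centers > 1 && r$center_shift != 0) {
      shift_rows <- center_ids != "C1"
      radiomics[shift_rows, ] <- radiomics[shift_rows, , drop = FALSE] + r$center_shift
    }

    demo <- cbind(age = round(rnorm(n, 62, 10)),
                  weight_kg = round(rnorm(n, 78, 12), 1),
                  height_cm = round(rnorm(n, 170, 9), 1))

    if (r$label_noise > 0) {
      nflip <- round_half_up(r$label_noise * n)
      flip <- sample(n, nflip)
      label[flip] <- ifelse(label[flip] == "pos", "neg", "pos")
    }

    out <- as_tibble(cbind(as.data.frame(radiomics), as.data.frame(demo)))
    out$sample_id <- sprintf("%s_%03d", center_ids, unlist(lapply(r$n_samples, seq_len)))
    out$label <- label
    if (n_centers > 1) out$center <- center_ids
    as_feature_table(out, positive = "pos")
  })
}
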
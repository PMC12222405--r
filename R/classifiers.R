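#' Train a classifier on a preprocessed feature table
#'
#' Fixed, logged hyperparameters (no per-fold tuning): XGBoost with 300
#' boosting rounds, depth 4, eta 0.1; random forest with 500 trees; RBF SVM
#' with scaled gamma (`1 / (p * var(x))`) on internally z-scored features;
#' plus the lightweight `"dlda"` diagonal Gaussian discriminant used as a
#' fast baseline. Prediction threshold is 0.5 on the positive-class score.
#'
#' @param table a feature-table tibble (training rows).
#' @param algorithm `"xgboost"`, `"random_forest"`, `"svm"` or `"dlda"`.
#' @param seed integer seed.
#' @return A `rst_classifier` with a [predict][predict.rst_classifier]
#'   method.
#' @export
train_classifier <- function(table, algorithm = c("xgboost", "random_forest",
                                                  "svm", "dlda"), seed = 1L) {
  algorithm <- match.arg(algorithm)
  check_feature_table(table)
  if (any(table(table$label) < 2)) {
    abort("need at least 2 samples per class to train")
  }
  feats <- feature_names(table)
  x <- feature_matrix(table)
  if (any(!is.finite(x))) abort("features must be finite")
  y <- table$label
  pos <- positive_class(table)
  fit <- with_seed(seed, switch(algorithm,
    xgboost = {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 4, eta = 0.1,
                      nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(x, label = as.integer(y == pos)),
        nrounds = 300, verbose = 0)
    },
    random_forest = randomForest::randomForest(x, y, ntree = 500),
    svm = {
      mu <- colMeans(x); sdev <- apply(x, 2, sd); sdev[sdev < 1e-12] <- 1
      xs <- sweep(sweep(x, 2, mu), 2, sdev, "/")
      gamma <- 1 / (ncol(xs) * max(var(as.vector(xs)), 1e-12))
      list(model = e1071::svm(xs, y, kernel = "radial", gamma = gamma,
                              probability = TRUE),
           center = mu, scale = sdev)
    },
    dlda = {
      i2 <- y == pos
      m1 <- colMeans(x[!i2, , drop = FALSE]); m2 <- colMeans(x[i2, , drop = FALSE])
      d1 <- sweep(x[!i2, , drop = FALSE], 2, m1); d2 <- sweep(x[i2, , drop = FALSE], 2, m2)
      pooled <- pmax((colSums(d1^2) + colSums(d2^2)) / max(nrow(x) - 2, 1), 1e-8)
      list(m1 = m1, m2 = m2, pooled = pooled)
    }))
  structure(list(algorithm = algorithm, fit = fit, features = feats,
                 levels = levels(y), positive = pos, seed = seed,
                 hyperparameters = switch(algorithm,
                   xgboost = list(nrounds = 300, max_depth = 4, eta = 0.1),
                   random_forest = list(ntree = 500),
                   svm = list(kernel = "radial", gamma = "scale"),
                   dlda = list())),
            class = "rst_classifier")
}

#' Predict with a trained classifier
#'
#' @param object a `rst_classifier`.
#' @param newdata a feature-table tibble (or data frame) containing the
#'   training feature columns.
#' @param type `"class"` for thresholded labels, `"prob"` for the
#'   positive-class score.
#' @param ... unused.
#' @return Factor of predicted labels, or numeric positive-class scores.
#' @export
predict.rst_classifier <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    abort(paste0("newdata lacks feature(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  x <- as.matrix(as.data.frame(newdata)[object$features])
  storage.mode(x) <- "double"
  p <- switch(object$algorithm,
    xgboost = predict(object$fit, xgboost::xgb.DMatrix(x)),
    random_forest = predict(object$fit, x, type = "prob")[, object$positive],
    svm = {
      xs <- sweep(sweep(x, 2, object$fit$center), 2, object$fit$scale, "/")
      pr <- attr(predict(object$fit$model, xs, probability = TRUE), "probabilities")
      pr[, object$positive]
    },
    dlda = {
      s1 <- -colSums((t(x) - object$fit$m1)^2 / object$fit$pooled)
      s2 <- -colSums((t(x) - object$fit$m2)^2 / object$fit$pooled)
      1 / (1 + exp(pmin(pmax(s1 - s2, -50), 50)))
    })
  if (type == "prob") return(unname(p))
  factor(ifelse(p > 0.5, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' Confusion-matrix metrics for binary predictions
#'
#' Computes TP/FP/TN/FN and SENS, SPEC, PPV, NPV, ACC, BACC. Ratios with a
#' zero denominator are reported as `NA`, never silently 0.
#'
#' @param y_true,y_pred equal-length factors (or vectors) of binary labels.
#' @param positive the positive-class label; defaults to the second level of
#'   `y_true`.
#' @return A one-row tibble (a `MetricRecord`).
#' @export
confusion_metrics <- function(y_true, y_pred, positive = NULL) {
  if (!length(y_true)) abort("empty input")
  if (length(y_true) != length(y_pred)) abort("length mismatch")
  y_true <- as.factor(y_true)
  positive <- positive %||% levels(y_true)[nlevels(y_true)]
  t_pos <- as.character(y_true) == positive
  p_pos <- as.character(y_pred) == positive
  TP <- sum(t_pos & p_pos); FN <- sum(t_pos & !p_pos)
  FP <- sum(!t_pos & p_pos); TN <- sum(!t_pos & !p_pos)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  SENS <- ratio(TP, TP + FN); SPEC <- ratio(TN, TN + FP)
  tibble(TP = TP, FP = FP, TN = TN, FN = FN,
         SENS = SENS, SPEC = SPEC,
         PPV = ratio(TP, TP + FP), NPV = ratio(TN, TN + FN),
         ACC = (TP + TN) / length(y_true),
         BACC = (SENS + SPEC) / 2)
}
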
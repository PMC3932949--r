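#' Fit a [-1, 1] rescaling of a feature matrix
#'
#' Per-feature linear map x' = -1 + 2 (x - min) / (max - min) from the
#' training data; constant features map to 0. Values outside the training
#' range extrapolate beyond [-1, 1] (no clipping).
#'
#' @param features Feature tibble (non-numeric columns `id`/`label` ignored).
#' @return An object of class `srna_scaler` (tibble of per-feature min/max).
#' @export
fit_scaler <- function(features) {
  x <- dplyr::select(tibble::as_tibble(features),
                     -dplyr::any_of(c("id", "label")))
  stopifnot(nrow(x) >= 1L)
  out <- tibble::tibble(
    feature = names(x),
    min = unname(vapply(x, min, numeric(1))),
    max = unname(vapply(x, max, numeric(1)))
  )
  class(out) <- c("srna_scaler", class(out))
  out
}

#' @rdname fit_scaler
#' @param scaler An `srna_scaler`.
#' @return `apply_scaler()`: the rescaled feature tibble (id/label preserved).
#' @export
apply_scaler <- function(scaler, features) {
  x <- tibble::as_tibble(features)
  miss <- setdiff(scaler$feature, names(x))
  if (length(miss)) stop("features missing from matrix: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  for (i in seq_len(nrow(scaler))) {
    f <- scaler$feature[i]
    rng <- scaler$max[i] - scaler$min[i]
    x[[f]] <- if (rng == 0) {
      rep(0, nrow(x))
    } else {
      -1 + 2 * (x[[f]] - scaler$min[i]) / rng
    }
  }
  x
}

platt_fit <- function(decision, y) {
  # sigmoid calibration of decision values with Platt target smoothing;
  # smoothed targets keep the MLE finite on separable data
  np <- sum(y == 1); nn <- sum(y == -1)
  t <- ifelse(y == 1, (np + 1) / (np + 2), 1 / (nn + 2))
  fit <- suppressWarnings(
    stats::glm(t ~ decision, family = stats::quasibinomial())
  )
  stats::coef(fit)
}

platt_apply <- function(coefs, decision) {
  as.numeric(stats::plogis(coefs[1] + coefs[2] * decision))
}

#' Train the hairpin SVM classifier
#'
#' Radial-basis-function SVM (penalty C = 8.0, kernel width gamma = 1/32 by
#' default) on features rescaled to [-1, 1], with a seeded sigmoid
#' calibration of decision values so that scores are positive-class
#' probabilities in [0, 1].
#'
#' @param features Feature tibble (`id` optional; feature columns numeric).
#' @param label Class labels (+1 = real hairpin), one per row; both classes
#'   must be present.
#' @param cost SVM penalty parameter C (default 8.0).
#' @param gamma RBF kernel width (default 0.03125).
#' @param seed Integer seed (stored; training itself is deterministic).
#' @return An object of class `hairpin_model` bundling the fitted SVM, the
#'   scaler, feature order, calibration coefficients and training metadata.
#' @export
train_hairpin_svm <- function(features, label, cost = 8.0, gamma = 0.03125,
                              seed = 1L) {
  stopifnot(cost > 0, gamma > 0)
  y <- as_pm1(label)
  if (length(unique(y)) < 2L) stop("training needs both classes present")
  x <- dplyr::select(tibble::as_tibble(features),
                     -dplyr::any_of(c("id", "label")))
  stopifnot(nrow(x) == length(y))
  scaler <- fit_scaler(x)
  xs <- as.matrix(apply_scaler(scaler, x))
  set.seed(seed)
  fit <- e1071::svm(xs, factor(y, levels = c(-1, 1)),
                    type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  dec <- orient_decision(fit, xs)
  cal <- platt_fit(dec, y)
  structure(
    list(
      svm = fit, scaler = scaler, feature_order = names(x),
      calibration = cal, cost = cost, gamma = gamma, seed = seed,
      n_pos = sum(y == 1), n_neg = sum(y == -1),
      trained = format(Sys.time(), "%Y-%m-%d"),
      format = "hairpin_model/1"
    ),
    class = "hairpin_model"
  )
}

orient_decision <- function(fit, xs) {
  # decision values oriented so larger = more positive-class (+1)
  pr <- stats::predict(fit, xs, decision.values = TRUE)
  dec <- as.numeric(attr(pr, "decision.values"))
  flip <- identical(colnames(attr(pr, "decision.values"))[1], "-1/1")
  if (flip) -dec else dec
}

#' @export
print.hairpin_model <- function(x, ...) {
  cat("<hairpin_model> RBF SVM: C=", x$cost, " gamma=", x$gamma,
      "; trained on ", x$n_pos, "+ / ", x$n_neg, "- samples, ",
      length(x$feature_order), " features\n", sep = "")
  invisible(x)
}

#' Score candidate hairpins with a trained model
#'
#' @param model A `hairpin_model`.
#' @param features Feature tibble whose feature columns must match the
#'   model's training features exactly.
#' @return Numeric vector of calibrated positive-class scores in [0, 1].
#' @export
predict_score <- function(model, features) {
  stopifnot(inherits(model, "hairpin_model"))
  x <- dplyr::select(tibble::as_tibble(features),
                     -dplyr::any_of(c("id", "label")))
  extra <- setdiff(names(x), model$feature_order)
  miss <- setdiff(model$feature_order, names(x))
  if (length(miss) || length(extra)) {
    stop("feature mismatch with model; missing: [",
         paste(miss, collapse = ", "), "] extra: [",
         paste(extra, collapse = ", "), "]")
  }
  xs <- as.matrix(apply_scaler(model$scaler, x[model$feature_order]))
  dec <- orient_decision(model$svm, xs)
  platt_apply(model$calibration, dec)
}

#' Confusion counts to performance metrics
#'
#' Sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP), accuracy
#' Ac = (TP+TN)/total (all in percent) and the Matthews correlation
#' coefficient MCC = (TP TN - FN FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)),
#' with MCC = 0 when its denominator vanishes.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts (total > 0).
#' @return A one-row tibble of class `srna_metrics`: `tp`, `fp`, `tn`, `fn`,
#'   `sn`, `sp`, `ac` (percent) and `mcc`.
#' @examples
#' confusion_metrics(tp = 329, fp = 4, tn = 340, fn = 15)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  den <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fn * fp) / sqrt(den)
  out <- tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sn = if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_,
    sp = if (tn + fp > 0) tn / (tn + fp) * 100 else NA_real_,
    ac = (tp + tn) / (tp + fp + tn + fn) * 100,
    mcc = mcc
  )
  class(out) <- c("srna_metrics", class(out))
  out
}

make_folds <- function(y, folds, seed) {
  n <- length(y)
  if (folds == n) return(seq_len(n))  # leave-one-out: one sample per fold
  if (folds < 2L) stop("folds must be >= 2")
  if (folds > min(table(y))) {
    stop("fold count (", folds, ") exceeds smallest class size (",
         min(table(y)), ")")
  }
  fold <- integer(n)
  set.seed(seed)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validate the hairpin SVM
#'
#' Stratified k-fold (or leave-one-out with `folds = "loo"` or `folds = n`)
#' cross-validation. The scaler and calibration are fitted inside each
#' training fold only; confusion counts are pooled over held-out folds and
#' the ROC curve is computed from the pooled scores.
#'
#' @param features Feature tibble.
#' @param label Class labels (+1/-1 coercible).
#' @param folds Number of folds (>= 2), or `"loo"`.
#' @param cost,gamma,seed As in [train_hairpin_svm()].
#' @param cutoff Score threshold calling a prediction positive (default 0.5).
#' @return An object of class `hairpin_cv`: list with `metrics`
#'   (an `srna_metrics` row), `roc` (tibble of FPR/TPR points), `auc`,
#'   `scores` (per-sample tibble with fold, label, score) and the settings.
#' @export
cross_validate <- function(features, label, folds = 10, cost = 8.0,
                           gamma = 0.03125, seed = 1L, cutoff = 0.5) {
  y <- as_pm1(label)
  x <- dplyr::select(tibble::as_tibble(features),
                     -dplyr::any_of(c("id", "label")))
  n <- length(y)
  if (identical(folds, "loo")) folds <- n
  folds <- as.integer(folds)
  fold <- make_folds(y, folds, seed)
  score <- numeric(n)
  for (k in seq_len(folds)) {
    tr <- fold != k
    if (length(unique(y[tr])) < 2L) stop("training fold lost a class")
    m <- train_hairpin_svm(x[tr, , drop = FALSE], y[tr],
                           cost = cost, gamma = gamma, seed = seed)
    score[!tr] <- predict_score(m, x[!tr, , drop = FALSE])
  }
  pred <- ifelse(score >= cutoff, 1L, -1L)
  metrics <- confusion_metrics(
    tp = sum(pred == 1 & y == 1), fp = sum(pred == 1 & y == -1),
    tn = sum(pred == -1 & y == -1), fn = sum(pred == -1 & y == 1)
  )
  r <- pROC::roc(response = y, predictor = score, levels = c(-1, 1),
                 direction = "<", quiet = TRUE)
  roc_tbl <- tibble::tibble(fpr = rev(1 - r$specificities),
                            tpr = rev(r$sensitivities))
  structure(
    list(
      metrics = metrics, roc = roc_tbl, auc = as.numeric(pROC::auc(r)),
      scores = tibble::tibble(fold = fold, label = y, score = score),
      folds = folds, cost = cost, gamma = gamma, seed = seed, cutoff = cutoff
    ),
    class = "hairpin_cv"
  )
}

#' @export
print.hairpin_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<hairpin_cv> %d-fold: Ac=%.2f%% Sn=%.2f%% Sp=%.2f%% MCC=%.4f AUC=%.4f\n",
    x$folds, m$ac, m$sn, m$sp, m$mcc, x$auc))
  invisible(x)
}

#' Save / load a trained hairpin model
#'
#' The archive bundles the SVM, scaler, feature order, calibration and
#' training metadata under a versioned format tag.
#'
#' @param model A `hairpin_model`.
#' @param path File path for the model archive.
#' @return `path` (writer); a `hairpin_model` (reader).
#' @export
write_hairpin_model <- function(model, path) {
  stopifnot(inherits(model, "hairpin_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_hairpin_model
#' @export
read_hairpin_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "hairpin_model") ||
      !identical(model$format, "hairpin_model/1")) {
    stop("not a recognised hairpin model archive: ", path)
  }
  model
}

# ---- broom-style methods ----------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.srna_metrics <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @export
tidy.hairpin_cv <- function(x, ...) tidy.srna_metrics(x$metrics)

#' @export
glance.hairpin_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::as_tibble(x$metrics),
    tibble::tibble(auc = x$auc, folds = x$folds, n = nrow(x$scores),
                   cost = x$cost, gamma = x$gamma)
  )
}

#' @export
glance.hairpin_model <- function(x, ...) {
  tibble::tibble(
    n_pos = x$n_pos, n_neg = x$n_neg,
    n_features = length(x$feature_order),
    n_support_vectors = nrow(x$svm$SV),
    cost = x$cost, gamma = x$gamma, seed = x$seed
  )
}

#' @export
tidy.hairpin_model <- function(x, ...) {
  tibble::as_tibble(x$scaler)
}
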
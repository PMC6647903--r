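#' Outcome-derived training labels
#'
#' Supervision for the risk classifier is derived from follow-up alone:
#' a patient is `high` risk if they died of breast cancer strictly
#' before `horizon_years` (10 years by default) after diagnosis, and
#' `low` risk if they never died of breast cancer during follow-up
#' (alive at last contact or death from another cause). A breast-cancer
#' death at or beyond the horizon satisfies neither rule and is labelled
#' `indeterminate`; such records are excluded from supervision and their
#' count is reported by the training pipeline.
#'
#' @param cause character vector: `"breast_cancer_death"`,
#'   `"other_death"` or `"alive"`.
#' @param followup_years positive follow-up times.
#' @param horizon_years label horizon.
#' @return factor with levels `low`, `high`, `indeterminate`.
#' @export
assign_training_labels <- function(cause, followup_years,
                                   horizon_years = 10) {
  stopifnot(length(cause) == length(followup_years),
            all(followup_years > 0),
            all(cause %in% c("breast_cancer_death", "other_death", "alive")))
  lab <- ifelse(cause != "breast_cancer_death", "low",
                ifelse(followup_years < horizon_years, "high",
                       "indeterminate"))
  factor(lab, levels = c("low", "high", "indeterminate"))
}

#' @rdname assign_training_labels
#' @param record list or one-row data.frame with fields `cause` and
#'   `followup_years`.
#' @export
assign_training_label <- function(record, horizon_years = 10) {
  as.character(assign_training_labels(record$cause, record$followup_years,
                                      horizon_years))
}

#' Train the digital risk score classifier
#'
#' Linear soft-margin support-vector machine (hinge loss, L2
#' regularisation) on the encoded spot features, with `high` coded +1
#' and `low` -1. Indeterminate labels must be removed beforehand. The
#' stored model is the hyperplane `(w, b)` oriented so that positive
#' scores mean high risk.
#'
#' @param features `n x p` numeric matrix.
#' @param labels `"low"`/`"high"` per row; both classes required.
#' @param margin_parameter SVM cost parameter (default 1).
#' @param seed RNG seed (used only when `cross_validate = TRUE`).
#' @param cross_validate select `margin_parameter` by stratified 5-fold
#'   cross-validated AUC over `10^(-2:2)`.
#' @return object of class `drs_model` (fields `weights`, `bias`,
#'   `margin_parameter`).
#' @export
train_drs <- function(features, labels, margin_parameter = 1, seed = 1L,
                      cross_validate = FALSE) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (any(!labels %in% c("low", "high")))
    stop("labels must be 'low'/'high'; remove indeterminate records first")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to train the classifier")
  stopifnot(nrow(features) == length(labels))
  if (cross_validate) {
    grid <- 10^(-2:2)
    cv_auc <- vapply(grid, function(cost)
      cv_margin_auc(features, labels, cost, seed), numeric(1))
    margin_parameter <- grid[which.max(cv_auc)]
  }
  y <- factor(labels, levels = c("high", "low"))
  fit <- e1071::svm(features, y, kernel = "linear", cost = margin_parameter,
                    scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # e1071 orients decision values toward its first factor level ("high");
  # verify and flip if the solver returned the opposite orientation.
  score <- features %*% w + b
  pred <- predict(fit, features)
  agree <- mean((score > 0) == (pred == "high"))
  if (agree < 0.5) {
    w <- -w
    b <- -b
  }
  structure(list(weights = w, bias = b,
                 margin_parameter = margin_parameter),
            class = "drs_model")
}

# stratified 5-fold CV AUC for one cost value
cv_margin_auc <- function(features, labels, cost, seed, folds = 5L) {
  idx <- with_seed(derive_seed(seed, round(1e3 * log10(cost) + 5e3), 7L), {
    f <- integer(length(labels))
    for (cls in unique(labels)) {
      rows <- which(labels == cls)
      f[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
    f
  })
  aucs <- vapply(seq_len(folds), function(k) {
    tr <- idx != k
    if (length(unique(labels[tr])) < 2L || length(unique(labels[!tr])) < 2L)
      return(NA_real_)
    m <- train_drs(features[tr, , drop = FALSE], labels[tr],
                   margin_parameter = cost)
    s <- predict_drs(features[!tr, , drop = FALSE], m)$drs_score
    evaluate_auc(s, labels[!tr] == "high")
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Apply a fitted DRS model
#'
#' The digital risk score is the signed distance to the hyperplane,
#' `w . x + b`; the binary DRS group is `high` iff the score is strictly
#' positive (scores of exactly zero go to `low`, the favourable group).
#'
#' @param features `n x p` matrix.
#' @param model a [train_drs()] model.
#' @return data.frame with columns `drs_score` and `drs_group`.
#' @export
predict_drs <- function(features, model) {
  stopifnot(inherits(model, "drs_model"))
  features <- if (is.matrix(features)) features
              else matrix(features, nrow = 1L)
  if (ncol(features) != length(model$weights))
    stop("feature dimension does not match the fitted model")
  score <- as.numeric(features %*% model$weights + model$bias)
  data.frame(drs_score = score,
             drs_group = factor(ifelse(score > 0, "high", "low"),
                                levels = c("low", "high")))
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a uniformly drawn positive
#' outscores a uniformly drawn negative, with score ties counted 1/2.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or 0/1 vector; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
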
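# Logistic diagnosis classifier trained on discovery scores and evaluated
# out-of-distribution on a replication sample scored with the
# discovery-fitted transforms.

#' Fit a logistic diagnosis classifier on scores
#'
#' Single-predictor logistic regression (maximum likelihood via iteratively
#' reweighted least squares) of class membership on the score. Perfect
#' separation is reported with a warning but the fit is returned.
#'
#' @param scores numeric vector or an `mrs_result`.
#' @param labels two-level factor (or coercible); the second level is the
#'   positive class. At least 10 subjects per class.
#' @return list of class `mrs_classifier`: `coefficients` (intercept,
#'   slope), `classes`, `separation` flag and the `glm` fit.
#' @export
fit_logistic <- function(scores, labels) {
  x <- if (inherits(scores, "mrs_result")) scores$phi else as.numeric(scores)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("need exactly two classes")
  if (any(table(labels) < 2L)) stop("need >= 2 subjects per class")
  if (any(table(labels) < 10L))
    warning("fewer than 10 subjects in a class; fit will be unstable")
  y <- as.integer(labels == levels(labels)[2L])
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated) warning("perfect or quasi-perfect separation detected")
  structure(list(coefficients = stats::coef(fit),
                 classes = levels(labels), separation = separated,
                 fit = fit),
            class = "mrs_classifier")
}

#' Out-of-distribution accuracy with exact binomial CI
#'
#' Applies a discovery-fitted classifier, unchanged, to replication scores
#' (which must have been produced with the discovery-fitted deconfounding /
#' scaling / weight transforms) and reports accuracy at the probability
#' threshold with a Clopper-Pearson 95% interval.
#'
#' @param model an `mrs_classifier`.
#' @param scores replication scores (numeric or `mrs_result`).
#' @param labels true two-level labels, levels matching the training
#'   classes.
#' @param threshold posterior-probability cutoff for the positive class.
#' @param conf_level CI level.
#' @return list with `accuracy`, `ci` (length 2), `n_correct`, `n`,
#'   `predicted`.
#' @export
evaluate_ood <- function(model, scores, labels, threshold = 0.5,
                         conf_level = 0.95) {
  x <- if (inherits(scores, "mrs_result")) scores$phi else as.numeric(scores)
  if (length(x) == 0L) stop("empty replication set")
  labels <- factor(labels, levels = model$classes)
  if (anyNA(labels)) stop("labels outside the training classes")
  co <- model$coefficients
  co[is.na(co)] <- 0   # rank-deficient (constant-score) fits predict flat
  eta <- co[1L] + co[2L] * x
  prob <- 1 / (1 + exp(-eta))
  pred <- model$classes[1L + as.integer(prob > threshold)]
  k <- sum(pred == as.character(labels))
  n <- length(x)
  alpha <- 1 - conf_level
  ci <- c(if (k == 0L) 0 else stats::qbeta(alpha / 2, k, n - k + 1),
          if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k))
  list(accuracy = k / n, ci = ci, n_correct = k, n = n, predicted = pred)
}
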
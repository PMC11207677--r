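# Group-level inference: IQR outlier labeling, covariate-adjusted group
# models (site as random intercept, fixed dummies, or omitted),
# standardized mean differences, FDR correction, post-hoc diagnosis
# contrasts, dependent-correlation comparison, the composite-vs-regional
# effect-size Z comparison, analytic power, and effect-profile correlation.

.default_covariates <- c("age", "sex", "iq", "icv", "mean_thickness",
                         "mean_area")

#' IQR outlier labeling
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, quartiles by the
#' linear-interpolation convention (`stats::quantile` type 7). Applied once,
#' non-iteratively.
#'
#' @param values numeric vector, length >= 4.
#' @return list with `values` (kept), `flags` (logical, `TRUE` = outlier)
#'   and `fences` (the two cutoffs).
#' @examples
#' iqr_outlier_filter(c(1:9, 100))$flags
#' @export
iqr_outlier_filter <- function(values) {
  if (sum(!is.na(values)) < 4L) stop("need at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2L] - q[1L]
  fences <- c(lower = q[1L] - 1.5 * iqr, upper = q[2L] + 1.5 * iqr)
  flags <- !is.na(values) & (values < fences[1L] | values > fences[2L])
  list(values = values[!flags], flags = flags, fences = fences)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return step-up adjusted p-values (monotone).
#' @export
fdr_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

.align_outcome <- function(outcome, table) {
  if (inherits(outcome, "mrs_result")) {
    idx <- match(table$subject_id, outcome$subject_id)
    if (any(is.na(idx))) stop("subjects missing from scores")
    outcome$phi[idx]
  } else {
    stopifnot(length(outcome) == nrow(table))
    as.numeric(outcome)
  }
}

#' Covariate-adjusted group difference for one outcome
#'
#' Regresses a (z-rescaled) outcome on diagnostic status with fixed
#' covariates, after one pass of IQR outlier labeling on the outcome. Site
#' enters as a random intercept (REML, Satterthwaite degrees of freedom), as
#' fixed dummies, or not at all. Cohen's d is derived from the adjusted
#' contrast as \eqn{d = 2t/\sqrt{df}}.
#'
#' @param outcome numeric vector aligned with `table`, or an `mrs_result`.
#' @param table a `roi_table` supplying diagnosis, site and covariates.
#' @param covariates fixed-effect covariate column names (default age, sex,
#'   IQ, ICV, mean thickness, mean area).
#' @param site `"random"`, `"fixed"` or `"none"`; a singular random-effect
#'   fit falls back to fixed dummies, then to none, with a warning.
#' @param contrast `"case_control"` pools every non-control diagnosis into
#'   one case group; `"diagnosis"` keeps the full factor (first level
#'   `control`), reporting the slope of the last level.
#' @param outlier_filter apply [iqr_outlier_filter()] to the outcome first.
#' @param z_scale z-rescale the outcome over the analyzed subjects so the
#'   slope is in outcome-SD units.
#' @return object of class `group_stats`: `beta`, `se`, `df`, `t`, `p_raw`,
#'   `cohens_d`, `n_used`, `n_input`, model descriptor, and the underlying
#'   fit (element `fit`).
#' @export
group_model <- function(outcome, table,
                        covariates = .default_covariates,
                        site = c("random", "fixed", "none"),
                        contrast = c("case_control", "diagnosis"),
                        outlier_filter = TRUE, z_scale = TRUE) {
  site <- match.arg(site)
  contrast <- match.arg(contrast)
  y <- .align_outcome(outcome, table)
  dat <- as.data.frame(table)[, c("diagnosis", "site", covariates),
                              drop = FALSE]
  dat$.y <- y
  keep <- stats::complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]
  n_input <- nrow(dat)
  if (outlier_filter) {
    fl <- iqr_outlier_filter(dat$.y)$flags
    dat <- dat[!fl, , drop = FALSE]
  }
  if (z_scale) dat$.y <- as.numeric(scale(dat$.y))
  for (cv in covariates)   # unit-variance covariates keep the fit well-scaled
    if (stats::sd(dat[[cv]]) > 0) dat[[cv]] <- as.numeric(scale(dat[[cv]]))
  dat$dx <- if (contrast == "case_control") {
    factor(ifelse(dat$diagnosis == "control", "control", "case"),
           levels = c("control", "case"))
  } else {
    stats::relevel(factor(dat$diagnosis), ref = "control")
  }
  if (any(table(dat$dx) < 2L)) stop("a diagnosis level has < 2 subjects")
  rhs <- paste(c("dx", covariates), collapse = " + ")
  if (site == "fixed" && length(unique(dat$site)) > 1L)
    rhs <- paste(rhs, "+ factor(site)")
  fit <- NULL
  if (site == "random" && length(unique(dat$site)) > 1L) {
    fit <- tryCatch(
      lmerTest::lmer(stats::as.formula(paste(".y ~", rhs, "+ (1 | site)")),
                     data = dat, REML = TRUE),
      error = function(e) NULL)
    if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-5)) {
      warning("singular random-intercept fit; falling back to fixed site")
      fit <- NULL
      rhs <- paste(rhs, "+ factor(site)")
    }
  }
  if (is.null(fit))
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
  co <- if (inherits(fit, "lmerModLmerTest"))
    stats::coef(summary(fit)) else summary(fit)$coefficients
  dx_rows <- grep("^dx", rownames(co), value = TRUE)
  row <- co[dx_rows[length(dx_rows)], , drop = TRUE]
  df <- if (inherits(fit, "lmerModLmerTest")) row[["df"]] else
    fit$df.residual
  tval <- row[["t value"]]
  structure(list(
    outcome = if (inherits(outcome, "mrs_result"))
      attr(outcome, "provenance") else "outcome",
    beta = row[["Estimate"]], se = row[["Std. Error"]], df = df, t = tval,
    p_raw = 2 * stats::pt(-abs(tval), df),
    cohens_d = 2 * tval / sqrt(df),
    n_used = nrow(dat), n_input = n_input,
    site = site, covariates = covariates, contrast = contrast,
    fit = fit, data = dat), class = "group_stats")
}

#' @method print group_stats
#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf(
    "<group_stats> %s: beta = %.3f (SE %.3f), df = %.1f, p = %.4g, d = %.3f, n = %d/%d\n",
    x$outcome, x$beta, x$se, x$df, x$p_raw, x$cohens_d, x$n_used,
    x$n_input))
  invisible(x)
}

#' Post-hoc pairwise diagnosis contrasts
#'
#' Refits the group model with the full diagnosis factor and extracts all
#' pairwise adjusted contrasts (estimated marginal means), with FDR
#' adjustment across the contrasts.
#'
#' @inheritParams group_model
#' @return data.frame with `contrast`, `beta`, `se`, `df`, `p_raw`,
#'   `p_adjusted`, one row per unordered diagnosis pair.
#' @export
posthoc_contrasts <- function(outcome, table,
                              covariates = .default_covariates,
                              site = "random", outlier_filter = TRUE) {
  gs <- group_model(outcome, table, covariates = covariates, site = site,
                    contrast = "diagnosis",
                    outlier_filter = outlier_filter)
  em <- emmeans::emmeans(gs$fit, "dx",
                         lmer.df = "satterthwaite", data = gs$data)
  pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "none"))
  data.frame(contrast = as.character(pr$contrast), beta = pr$estimate,
             se = pr$SE, df = pr$df, p_raw = pr$p.value,
             p_adjusted = fdr_adjust(pr$p.value),
             stringsAsFactors = FALSE)
}

#' Per-region covariate-adjusted group-difference profile
#'
#' Vectorized per-region group models (one QR factorization, all regions at
#' once) returning slope, t, and Cohen's d (\eqn{2t/\sqrt{df}}) for each of
#' the 75 regions. Site enters as fixed dummies (or is omitted); region
#' values are z-rescaled columnwise so slopes are in SD units.
#'
#' @param values a `residual_table` or `roi_table` carrying the 75 region
#'   columns plus `diagnosis` and `site`.
#' @param table optional `roi_table` supplying the covariates when `values`
#'   is a residual table (rows must align).
#' @inheritParams group_model
#' @return data.frame with `region`, `beta`, `se`, `t`, `df`, `p_raw`,
#'   `p_fdr`, `cohens_d`.
#' @export
roi_smd_profile <- function(values, table = NULL,
                            covariates = .default_covariates,
                            site = c("fixed", "none"),
                            contrast = "case_control") {
  site <- match.arg(site)
  src <- if (is.null(table)) as.data.frame(values) else as.data.frame(table)
  if (!is.null(table) &&
      !identical(as.character(values$subject_id),
                 as.character(table$subject_id)))
    stop("values and table rows do not align")
  Y <- scale(region_matrix(values))
  dx <- as.integer(src$diagnosis != "control")
  X <- cbind(intercept = 1, dx = dx)
  for (cv in covariates) X <- cbind(X, src[[cv]])
  if (site == "fixed" && length(unique(src$site)) > 1L)
    X <- cbind(X, stats::model.matrix(~ factor(src$site))[, -1, drop = FALSE])
  fs <- .fast_group_stats(Y, X, 2L)
  data.frame(region = colnames(Y), beta = fs$beta, se = fs$se, t = fs$t,
             df = fs$df, p_raw = fs$p, p_fdr = fdr_adjust(fs$p),
             cohens_d = 2 * fs$t / sqrt(fs$df), stringsAsFactors = FALSE)
}

# one QR, many outcomes: slope stats for column coef_idx of X
.fast_group_stats <- function(Y, X, coef_idx) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("singular design")
  B <- qr.coef(qx, Y)
  res <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtxi <- chol2inv(qr.R(qx))[coef_idx, coef_idx]
  se <- sqrt(sigma2 * xtxi)
  tval <- B[coef_idx, ] / se
  list(beta = B[coef_idx, ], se = se, t = tval, df = df,
       p = 2 * stats::pt(-abs(tval), df))
}

#' Test of difference between two dependent, overlapping correlations
#'
#' Hotelling-Williams/Steiger t for \eqn{H_0: \rho(y, a) = \rho(y, b)} given
#' the overlap \eqn{\rho(a, b)}, with `n - 3` degrees of freedom. Used to
#' compare how strongly two competing scores relate to the same outcome.
#'
#' @param outcome,score_a,score_b aligned numeric vectors, n >= 10.
#' @param alternative `"two.sided"`, or `"greater"` / `"less"` for a
#'   prespecified direction (`"greater"`: `score_a` more strongly related).
#' @return list with `t`, `df`, `p` and the three correlations.
#' @export
dependent_correlation_test <- function(outcome, score_a, score_b,
                                       alternative = c("two.sided",
                                                       "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(outcome)
  stopifnot(length(score_a) == n, length(score_b) == n, n >= 10L)
  if (stats::sd(outcome) == 0 || stats::sd(score_a) == 0 ||
      stats::sd(score_b) == 0) stop("zero variance in an input vector")
  r13 <- stats::cor(outcome, score_a)
  r23 <- stats::cor(outcome, score_b)
  r12 <- stats::cor(score_a, score_b)
  if (abs(r12) >= 1 - 1e-12) {
    # the two scores are (anti)identical: equal correlations give t = 0,
    # anything else is outside the test's domain
    if (abs(r13 - r23) < 1e-12) {
      tval <- 0
    } else {
      stop("degenerate |r| = 1 input")
    }
  } else {
    detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
    rbar <- (r13 + r23) / 2
    tval <- (r13 - r23) * sqrt(((n - 1) * (1 + r12)) /
      (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r12)^3))
  }
  df <- n - 3
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(tval), df),
              greater = stats::pt(tval, df, lower.tail = FALSE),
              less = stats::pt(tval, df))
  list(t = tval, df = df, p = p, r_outcome_a = r13, r_outcome_b = r23,
       r_ab = r12, alternative = alternative)
}

#' Compare a composite SMD with the distribution of regional SMDs
#'
#' Standardizes the composite score's absolute SMD against the mean and SD
#' of the 75 absolute regional SMDs, \eqn{z = (|d_{MRS}| - \mathrm{mean}
#' |d_{ROI}|) / \mathrm{sd} |d_{ROI}|}, with a normal p-value. Absolute
#' values are used so that reductions and enlargements are compared on one
#' scale.
#'
#' @param mrs_smd the composite score's SMD.
#' @param roi_smds the 75 regional SMDs.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return list with `z` and `p`.
#' @export
smd_vs_roi_distribution <- function(mrs_smd, roi_smds,
                                    alternative = c("two.sided",
                                                    "greater")) {
  alternative <- match.arg(alternative)
  if (any(!is.finite(roi_smds))) stop("non-finite regional SMD")
  a <- abs(roi_smds)
  s <- stats::sd(a)
  if (s == 0) stop("zero spread in regional SMDs")
  z <- (abs(mrs_smd) - mean(a)) / s
  p <- if (alternative == "two.sided") 2 * stats::pnorm(-abs(z)) else
    stats::pnorm(z, lower.tail = FALSE)
  list(z = z, p = p)
}

#' Power of the two-sample t test
#'
#' Analytic power via the noncentral t distribution with noncentrality
#' \eqn{d \sqrt{n_1 n_2 / (n_1 + n_2)}} and \eqn{n_1 + n_2 - 2} degrees of
#' freedom.
#'
#' @param d true standardized mean difference (>= 0).
#' @param n1,n2 group sizes (>= 2).
#' @param alpha significance level in (0, 1).
#' @param sides 2 (default) or 1.
#' @return power, a number in (0, 1).
#' @examples
#' power_two_sample_t(0.61, 47, 77)  # > 0.90
#' @export
power_two_sample_t <- function(d, n1, n2, alpha = 0.05, sides = 2) {
  stopifnot(d >= 0, n1 >= 2, n2 >= 2, alpha > 0, alpha < 1,
            sides %in% c(1, 2))
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (sides == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
  } else {
    stats::pt(stats::qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  }
}

#' Correlation between a sample effect-size profile and a weight profile
#'
#' Pearson correlation across the 75 regions between estimated per-region
#' SMDs and a weight set. With `stratify_by_metric = TRUE` both profiles
#' are centered within metric class before pooling (absorbing class-level
#' mean differences, the fixed-effect analogue of a class grouping factor);
#' per-class correlations are always reported alongside.
#'
#' @param sample_smds named numeric vector of per-region SMDs (canonical
#'   region names) or the data.frame from [roi_smd_profile()].
#' @param weights a `weight_set`.
#' @param stratify_by_metric center within metric class before pooling.
#' @return list with `r` (pooled), `by_class` (named per-class r) and `n`.
#' @export
effect_profile_correlation <- function(sample_smds, weights,
                                       stratify_by_metric = FALSE) {
  if (is.data.frame(sample_smds)) {
    v <- stats::setNames(sample_smds$cohens_d, sample_smds$region)
  } else v <- sample_smds
  v <- v[weights$region]
  if (any(is.na(v))) stop("sample SMDs do not cover the weight regions")
  cls <- weights$metric_class
  by_class <- vapply(unique(cls), function(k) {
    sel <- cls == k
    if (sum(sel) < 3L) stop("fewer than 3 regions in a stratum")
    stats::cor(v[sel], weights$theta[sel])
  }, numeric(1))
  if (stratify_by_metric) {
    vc <- stats::ave(v, cls, FUN = function(z) z - mean(z))
    wc <- stats::ave(weights$theta, cls, FUN = function(z) z - mean(z))
    r <- stats::cor(vc, wc)
  } else {
    r <- stats::cor(v, weights$theta)
  }
  list(r = r, by_class = by_class, n = length(v))
}

#' Two-group Cohen's d (pooled SD)
#'
#' @param x numeric values.
#' @param case logical (or 0/1) case indicator.
#' @return cases-minus-controls mean difference over the pooled SD.
#' @export
cohens_d <- function(x, case) {
  case <- as.logical(case)
  n1 <- sum(!case); n2 <- sum(case)
  sp <- sqrt(((n1 - 1) * stats::var(x[!case]) +
              (n2 - 1) * stats::var(x[case])) / (n1 + n2 - 2))
  (mean(x[case]) - mean(x[!case])) / sp
}
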
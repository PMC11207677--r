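# Deconfounding (age, sex, metric-matched global measure), z-rescaling and
# empirical-Bayes location/scale site harmonization. The ComBat step is
# implemented in-package because downstream use needs the fitted model
# (standardization constants, shrunken per-site effects, hyperparameters)
# for exact reapplication to replication data, not just the adjusted matrix.

.global_for_class <- c(thickness = "mean_thickness", area = "mean_area",
                       volume = "icv")

# value columns of a table: everything beyond the identifier/covariate set
.value_matrix <- function(tab) {
  drop_cols <- c(.covariate_cols, "cpz_equivalent")
  cols <- setdiff(names(tab), drop_cols)
  cols <- cols[vapply(as.data.frame(tab)[cols], is.numeric, logical(1))]
  m <- as.matrix(as.data.frame(tab)[, cols, drop = FALSE])
  rownames(m) <- tab$subject_id
  m
}

.residual_table <- function(table, resid_mat, model) {
  out <- data.frame(subject_id = table$subject_id,
                    diagnosis = table$diagnosis, site = table$site,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(resid_mat, check.names = FALSE))
  structure(out, deconfound_model = model,
            class = c("residual_table", "data.frame"))
}

#' Deconfound region values and z-rescale
#'
#' Per region, residualizes the measurement on `[1, age, sex, global]` by
#' ordinary least squares, where the global regressor is matched to the
#' metric class (mean cortical thickness for thickness, total surface area
#' for area, ICV for subcortical volume), then rescales the residuals to
#' mean 0 / SD 1 using the fitting population's statistics. Coefficients and
#' scaling constants are retained so the identical transform can be applied
#' to a replication table with [apply_deconfound()].
#'
#' @param table a `roi_table`.
#' @param fit_population `"all"` fits and scales on every subject (deviation
#'   from the sample norm); `"controls"` uses the control group only.
#' @return A `residual_table`: `subject_id`, `diagnosis`, `site` plus 75
#'   unitless residual columns; attribute `deconfound_model` holds the
#'   per-region coefficients and scaling constants.
#' @export
deconfound <- function(table, fit_population = c("all", "controls")) {
  fit_population <- match.arg(fit_population)
  canon <- attr(table, "region_info")
  if (is.null(canon)) canon <- canonical_regions()
  fit_rows <- if (fit_population == "all") rep(TRUE, nrow(table)) else
    table$diagnosis == "control"
  if (sum(fit_rows) < 5L)
    stop("fewer fitting subjects than parameters")
  Y <- region_matrix(table)
  res <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  coefs <- matrix(NA_real_, 4L, 75L,
                  dimnames = list(c("intercept", "age", "sex", "global"),
                                  canon$region))
  for (cl in unique(canon$metric_class)) {
    cols <- canon$region[canon$metric_class == cl]
    X <- cbind(1, table$age, table$sex, table[[.global_for_class[[cl]]]])
    Xf <- X[fit_rows, , drop = FALSE]
    qx <- qr(Xf)
    if (qx$rank < ncol(Xf))
      stop("singular deconfounding design (constant covariate?)")
    B <- qr.coef(qx, Y[fit_rows, cols, drop = FALSE])
    res[, cols] <- Y[, cols, drop = FALSE] - X %*% B
    coefs[, cols] <- B
  }
  ctr <- colMeans(res[fit_rows, , drop = FALSE])
  scl <- apply(res[fit_rows, , drop = FALSE], 2L, stats::sd)
  if (any(scl == 0)) stop("zero residual variance in a region")
  res <- sweep(sweep(res, 2L, ctr, "-"), 2L, scl, "/")
  model <- list(coefficients = coefs, center = ctr, scale = scl,
                fit_population = fit_population)
  .residual_table(table, res, model)
}

#' Apply a fitted deconfounding transform to new data
#'
#' Uses the coefficients and scaling constants fitted on a discovery table
#' (no refitting), the out-of-distribution contract for replication scoring.
#'
#' @param model the `deconfound_model` attribute of a [deconfound()] result
#'   (or that result itself).
#' @param table a `roi_table` of new subjects.
#' @return A `residual_table` on the discovery scale.
#' @export
apply_deconfound <- function(model, table) {
  if (inherits(model, "residual_table")) model <- attr(model, "deconfound_model")
  canon <- canonical_regions()
  Y <- region_matrix(table)
  res <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  for (cl in unique(canon$metric_class)) {
    cols <- canon$region[canon$metric_class == cl]
    X <- cbind(1, table$age, table$sex, table[[.global_for_class[[cl]]]])
    res[, cols] <- Y[, cols, drop = FALSE] - X %*% model$coefficients[, cols]
  }
  res <- sweep(sweep(res, 2L, model$center, "-"), 2L, model$scale, "/")
  .residual_table(table, res, model)
}

#' Empirical-Bayes site harmonization (ComBat)
#'
#' Removes additive and multiplicative site (batch) effects from a residual
#' table: per region the data are standardized against the size-weighted
#' grand mean and pooled variance, per-site location/scale effects are
#' estimated and shrunk toward their across-region priors (Gaussian prior on
#' locations, inverse-gamma on scales, moment-matched hyperparameters,
#' iterative conditional estimation), and the batch effects are then removed
#' and the scale restored. Deterministic for fixed input.
#'
#' @param residuals a `residual_table` (or `roi_table`; any table carrying a
#'   `site` column plus the 75 region columns).
#' @param mode `"parametric"` (location and scale) or `"mean_only"`
#'   (shrunken locations only, scales untouched).
#' @param tol,max_iter convergence control for the EB conditional updates.
#' @return list with `residuals` (harmonized table, same class as input) and
#'   `model` (a `combat_model`: per-site gamma*/delta*², standardization
#'   constants and prior hyperparameters). A single-site input is returned
#'   unchanged with a warning and an identity model.
#' @export
combat_adjust <- function(residuals, mode = c("parametric", "mean_only"),
                          tol = 1e-6, max_iter = 1000L) {
  mode <- match.arg(mode)
  site <- factor(residuals$site)
  Y <- .value_matrix(residuals)
  n <- nrow(Y); R <- ncol(Y)
  if (nlevels(site) < 2L) {
    warning("single site: harmonization is the identity")
    model <- structure(list(sites = levels(site), mode = "identity"),
                       class = "combat_model")
    return(list(residuals = residuals, model = model))
  }
  ns <- tabulate(site)
  if (any(ns < 2L))
    stop("a site has fewer than 2 subjects")
  X <- stats::model.matrix(~ 0 + site)
  B <- solve(crossprod(X), crossprod(X, Y))          # per-site means, S x R
  grand <- drop((ns / n) %*% B)
  var_pooled <- colSums((Y - X %*% B)^2) / n
  if (any(var_pooled == 0)) stop("zero within-site variance in a region")
  Z <- sweep(sweep(Y, 2L, grand, "-"), 2L, sqrt(var_pooled), "/")
  S <- nlevels(site)
  gamma_hat <- B * 0
  delta_hat <- B * 0
  for (s in seq_len(S)) {
    sel <- as.integer(site) == s
    gamma_hat[s, ] <- colMeans(Z[sel, , drop = FALSE])
    delta_hat[s, ] <- apply(Z[sel, , drop = FALSE], 2L, stats::var)
  }
  if (mode == "parametric" && any(delta_hat == 0))
    stop("zero within-site variance in a region")
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1L, stats::var)
  m_d <- rowMeans(delta_hat)
  s2_d <- apply(delta_hat, 1L, stats::var)
  aprior <- (2 * s2_d + m_d^2) / s2_d
  bprior <- (m_d * s2_d + m_d^3) / s2_d
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (s in seq_len(S)) {
    sel <- as.integer(site) == s
    Zs <- Z[sel, , drop = FALSE]
    if (mode == "mean_only") {
      gamma_star[s, ] <- if (t2[s] == 0) gamma_bar[s] else
        (ns[s] * t2[s] * gamma_hat[s, ] + gamma_bar[s]) /
          (ns[s] * t2[s] + 1)
      delta_star[s, ] <- 1
      next
    }
    if (s2_d[s] == 0 || t2[s] == 0) {
      # degenerate priors (no spread across regions): complete shrinkage
      gamma_star[s, ] <- if (t2[s] == 0) gamma_bar[s] else gamma_hat[s, ]
      delta_star[s, ] <- if (s2_d[s] == 0) m_d[s] else delta_hat[s, ]
      next
    }
    g_old <- gamma_hat[s, ]
    d_old <- delta_hat[s, ]
    for (it in seq_len(max_iter)) {
      g_new <- (ns[s] * t2[s] * gamma_hat[s, ] + d_old * gamma_bar[s]) /
        (ns[s] * t2[s] + d_old)
      sum2 <- colSums(sweep(Zs, 2L, g_new, "-")^2)
      d_new <- (0.5 * sum2 + bprior[s]) / (ns[s] / 2 + aprior[s] - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
      if (change < tol) break
    }
    gamma_star[s, ] <- g_old
    delta_star[s, ] <- d_old
  }
  adj <- Z
  for (s in seq_len(S)) {
    sel <- as.integer(site) == s
    adj[sel, ] <- sweep(sweep(Z[sel, , drop = FALSE], 2L, gamma_star[s, ],
                              "-"), 2L, sqrt(delta_star[s, ]), "/")
  }
  adj <- sweep(sweep(adj, 2L, sqrt(var_pooled), "*"), 2L, grand, "+")
  out <- residuals
  out[, colnames(Y)] <- adj
  model <- structure(
    list(sites = levels(site), gamma_star = gamma_star,
         delta_star = delta_star, grand_mean = grand,
         var_pooled = var_pooled,
         prior = list(gamma_bar = gamma_bar, t2 = t2, aprior = aprior,
                      bprior = bprior),
         mode = mode),
    class = "combat_model")
  list(residuals = out, model = model)
}

#' Apply a fitted ComBat model to new data
#'
#' @param model a `combat_model` from [combat_adjust()].
#' @param residuals table of new subjects whose `site` labels were all seen
#'   at fitting time (an identity model passes data through).
#' @return harmonized table, same class as the input.
#' @export
apply_combat <- function(model, residuals) {
  if (identical(model$mode, "identity")) return(residuals)
  site <- as.character(residuals$site)
  unknown <- setdiff(unique(site), model$sites)
  if (length(unknown) > 0L)
    stop("site not seen at fitting time: ", paste(unknown, collapse = ", "))
  Y <- .value_matrix(residuals)
  Z <- sweep(sweep(Y, 2L, model$grand_mean, "-"), 2L,
             sqrt(model$var_pooled), "/")
  for (s in seq_along(model$sites)) {
    sel <- site == model$sites[s]
    if (!any(sel)) next
    Z[sel, ] <- sweep(sweep(Z[sel, , drop = FALSE], 2L,
                            model$gamma_star[s, ], "-"), 2L,
                      sqrt(model$delta_star[s, ]), "/")
  }
  Z <- sweep(sweep(Z, 2L, sqrt(model$var_pooled), "*"), 2L,
             model$grand_mean, "+")
  out <- residuals
  out[, colnames(Y)] <- Z
  out
}

#' Deconfound, rescale and harmonize in one call
#'
#' Convenience wrapper running the full normalization chain in the default
#' order (deconfound then ComBat); `order = "combat_first"` harmonizes the
#' raw measurements before deconfounding, for sensitivity analysis.
#'
#' @inheritParams deconfound
#' @inheritParams combat_adjust
#' @param order stage order, `"deconfound_first"` (default) or
#'   `"combat_first"`.
#' @return list with `residuals`, `deconfound_model`, `combat_model`.
#' @export
harmonize <- function(table, fit_population = "all",
                      mode = "parametric",
                      order = c("deconfound_first", "combat_first")) {
  order <- match.arg(order)
  single_site <- length(unique(table$site)) < 2L
  if (order == "deconfound_first") {
    rt <- deconfound(table, fit_population)
    cb <- if (single_site)
      list(residuals = rt,
           model = structure(list(sites = unique(table$site),
                                  mode = "identity"),
                             class = "combat_model"))
    else combat_adjust(rt, mode)
    res <- cb$residuals
    dm <- attr(rt, "deconfound_model")
  } else {
    tab2 <- table
    if (!single_site) {
      cb <- combat_adjust(table, mode)
      tab2 <- cb$residuals
    } else {
      cb <- list(model = structure(list(sites = unique(table$site),
                                        mode = "identity"),
                 class = "combat_model"))
    }
    res <- deconfound(tab2, fit_population)
    dm <- attr(res, "deconfound_model")
  }
  list(residuals = res, deconfound_model = dm, combat_model = cb$model)
}
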
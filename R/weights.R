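# Construction of the experimental weight sets from two raw meta-analytic
# effect-size vectors: the shared first principal component, the two
# unique-variance residual vectors, and the unit-weight negative control.

#' Shared first principal component of two weight vectors
#'
#' Operationalizes "shared variance" as the first principal component of the
#' 75 x 2 matrix of the two centered effect-size vectors (eigendecomposition
#' of their 2 x 2 covariance). The component sign is fixed so PC1 scores
#' correlate positively with the first input, making higher scores "more
#' like" the first disorder's profile.
#'
#' @param scz,bd `weight_set` objects on the same 75 regions.
#' @return A `weight_set` of per-region PC1 scores, provenance
#'   `"pc1_shared"`; attribute `explained` gives the fraction of variance
#'   the component carries.
#' @export
pc1_shared <- function(scz, bd) {
  stopifnot(identical(scz$region, bd$region))
  M <- cbind(scz = scz$theta, bd = bd$theta)
  if (any(apply(M, 2L, stats::sd) == 0)) stop("zero-variance input vector")
  Mc <- scale(M, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(Mc), symmetric = TRUE)
  v1 <- ev$vectors[, 1L]
  scores <- drop(Mc %*% v1)
  if (stats::cor(scores, scz$theta) < 0) scores <- -scores
  out <- weight_set(scz$region, scores, provenance = "pc1_shared",
                    note = "PC1 of centered [scz, bd] effect-size vectors")
  attr(out, "explained") <- ev$values[1L] / sum(ev$values)
  out
}

#' Unique-variance weights
#'
#' Residualizes one effect-size vector on the other across regions (simple
#' OLS with intercept by default), isolating the variation in the target
#' profile not shared with the other disorder.
#'
#' @param target,other `weight_set` objects on the same 75 regions.
#' @param provenance tag for the result (`"scz_unique"` or `"bd_unique"`).
#' @param intercept logical; include the intercept in the residualizing
#'   regression (default) or force it through the origin.
#' @return A `weight_set` of residuals.
#' @export
unique_weights <- function(target, other,
                           provenance = c("scz_unique", "bd_unique"),
                           intercept = TRUE) {
  provenance <- match.arg(provenance)
  stopifnot(identical(target$region, other$region))
  if (stats::sd(other$theta) == 0) stop("zero-variance regressor")
  X <- if (intercept) cbind(1, other$theta) else cbind(other$theta)
  beta <- qr.coef(qr(X), target$theta)
  resid <- target$theta - drop(X %*% beta)
  weight_set(target$region, resid, provenance = provenance,
             note = sprintf("residual of %s on %s (intercept = %s)",
                            attr(target, "provenance"),
                            attr(other, "provenance"), intercept))
}

#' Unit-weight negative control
#'
#' The null weight set: \eqn{\theta = 1} for every region, so the score
#' carries no meta-analytic information and is expected to show no group
#' difference.
#'
#' @param regions character vector of region names (defaults to the
#'   canonical 75).
#' @return A `weight_set` with provenance `"h0"`.
#' @export
h0_weights <- function(regions = canonical_regions()$region) {
  if (length(regions) == 0L) stop("empty region list")
  weight_set(regions, rep(1, length(regions)), provenance = "h0",
             note = "unit weights (negative control)")
}
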
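# The scoring engine: per-subject morphometric risk score phi aggregating
# weighted deviations under the sign-congruency rule.

#' Morphometric risk score
#'
#' For each subject, forms the per-region products \eqn{p_r = \theta_r
#' \chi_r} of the effect-size weight with the subject's normalized deviation
#' and aggregates over the congruent set \eqn{C = \{r : p_r > 0\}} (regions
#' where the subject deviates in the direction of the established group
#' effect; ties \eqn{p_r = 0} are excluded):
#'
#' * `mean_congruent` (default): \eqn{\phi = |\,\mathrm{mean}_{r \in C}\,
#'   p_r\,|}, the absolute mean congruent product (\eqn{\phi = 0} when `C`
#'   is empty);
#' * `sum_over_N`: \eqn{\phi = \sum_{r \in C} p_r / N}, the congruent sum
#'   scaled by the number of scoreable regions;
#' * `raw_sum`: \eqn{\phi = \sum_{r \in C} p_r}.
#'
#' Missing deviations drop their region from both `C` and `N` for that
#' subject; subjects missing more than 20% of regions are flagged.
#'
#' @param residuals a `residual_table` (subjects x 75 unitless deviations).
#' @param weights a `weight_set`.
#' @param mode aggregation rule, see above.
#' @return data.frame of class `mrs_result`: `subject_id`, `diagnosis`,
#'   `site`, `phi`, `n_congruent`, `n_regions` (scoreable regions),
#'   `flagged_missing`, plus attributes `provenance` and `mode`.
#' @examples
#' coh <- simulate_cohort(emulate_table1("replication", seed = 1))
#' rt <- deconfound(coh$table)
#' head(mrs_score(rt, h0_weights()))
#' @export
mrs_score <- function(residuals, weights,
                      mode = c("mean_congruent", "sum_over_N", "raw_sum")) {
  mode <- match.arg(mode)
  X <- region_matrix(residuals)
  if (!identical(colnames(X), weights$region))
    stop("region mismatch between residuals and weights")
  if (any(rowSums(!is.na(X)) == 0L)) stop("all-missing subject")
  P <- sweep(X, 2L, weights$theta, "*")
  congr <- !is.na(P) & P > 0
  n_avail <- rowSums(!is.na(P))
  n_congr <- rowSums(congr)
  Ppos <- ifelse(congr, P, 0)
  s <- rowSums(Ppos, na.rm = TRUE)
  phi <- switch(mode,
    mean_congruent = abs(ifelse(n_congr > 0, s / n_congr, 0)),
    sum_over_N = s / n_avail,
    raw_sum = s)
  structure(
    data.frame(subject_id = residuals$subject_id,
               diagnosis = residuals$diagnosis, site = residuals$site,
               phi = phi, n_congruent = n_congr, n_regions = n_avail,
               flagged_missing = n_avail < 0.8 * ncol(X),
               stringsAsFactors = FALSE),
    provenance = attr(weights, "provenance"), mode = mode,
    class = c("mrs_result", "data.frame"))
}

#' Write scores to CSV
#' @param scores an `mrs_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mrs <- function(scores, path) {
  out <- data.frame(subject_id = scores$subject_id,
                    provenance = attr(scores, "provenance"),
                    phi = scores$phi, n_congruent = scores$n_congruent,
                    mode = attr(scores, "mode"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
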
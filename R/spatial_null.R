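# Spatial-autocorrelation-preserving significance tests for parcellated
# effect-size maps: rotation ("spin") permutations on the sphere for the 34
# cortical parcels, exhaustive or sampled label shuffles for the 7
# subcortical regions.

.null_distribution <- function(observed, null, method, n, seed,
                               exact = FALSE) {
  p <- if (exact) sum(abs(null) >= abs(observed) - 1e-15) / length(null)
  else (1 + sum(abs(null) >= abs(observed) - 1e-15)) / (1 + length(null))
  structure(list(observed = observed, null = null, p = p, method = method,
                 n_permutations = n, seed = seed),
            class = "null_distribution")
}

#' @method print null_distribution
#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s: r_obs = %.3f, p = %.4g (%d perms)\n",
              x$method, x$observed, x$p, x$n_permutations))
  invisible(x)
}

# uniform random rotation matrix (Shoemake quaternion method)
.random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# greedy one-to-one nearest-centroid assignment (ties broken by index):
# perm[i] = source parcel whose rotated centroid is claimed by target i
.greedy_assign <- function(D) {
  greedy_assign_cpp(order(D), nrow(D))
}

#' Spin permutation test for cortical effect-size maps
#'
#' Correlates two 34-parcel cortical maps and assesses significance against
#' rotation nulls: each permutation draws a uniform random 3-D rotation of
#' the spherical parcel centroids, reassigns `map_a` by greedy one-to-one
#' nearest-centroid matching, and recomputes the Pearson correlation with
#' the fixed `map_b`. This preserves the spatial autocorrelation of the map
#' that plain label shuffling would destroy.
#'
#' @param map_a,map_b numeric vectors of 34 cortical values, either named by
#'   parcel or aligned with `geometry$parcel`.
#' @param geometry a [parcel_geometry()] data.frame.
#' @param n number of rotations (>= 100).
#' @param seed RNG seed; results are reproducible given `(seed, n)`.
#' @return A `null_distribution` with the two-sided permutation p-value
#'   (`(1 + #{|r_null| >= |r_obs|}) / (1 + n)`).
#' @export
spin_test <- function(map_a, map_b, geometry = parcel_geometry(),
                      n = 10000L, seed = 1L) {
  stopifnot(n >= 100L)
  C <- as.matrix(geometry[, c("x", "y", "z")])
  k <- nrow(C)
  if (anyDuplicated(round(C, 8L)) > 0L) stop("degenerate geometry")
  a <- if (!is.null(names(map_a))) map_a[geometry$parcel] else map_a
  b <- if (!is.null(names(map_b))) map_b[geometry$parcel] else map_b
  stopifnot(length(a) == k, length(b) == k, !anyNA(a), !anyNA(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero-variance map")
  obs <- stats::cor(a, b)
  null <- .with_seed(seed, {
    vapply(seq_len(n), function(i) {
      Rm <- .random_rotation()
      rot <- C %*% t(Rm)
      D <- -2 * (C %*% t(rot))  # monotone in squared distance (unit norms)
      stats::cor(a[.greedy_assign(D)], b)
    }, numeric(1))
  })
  .null_distribution(obs, null, "spin", n, seed)
}

# all permutations of 1..k, one per row
.all_perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  row <- 1L
  for (pos in seq_len(k)) {
    for (r in seq_len(nrow(sub))) {
      rest <- seq_len(k)[-pos]
      out[row, ] <- c(pos, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Label-shuffle permutation test for subcortical maps
#'
#' The plain-permutation analogue of [spin_test()] for the 7 subcortical
#' regions, where no spherical geometry exists. Exhaustive mode enumerates
#' all 5040 label permutations and returns the exact two-sided p; sampled
#' mode draws `n` random permutations with the +1 correction.
#'
#' @param map_a,map_b aligned numeric vectors of 7 values.
#' @param n `"exhaustive"` (default) or a number of random draws.
#' @param seed RNG seed (sampled mode).
#' @return A `null_distribution`.
#' @export
shuffle_test <- function(map_a, map_b, n = "exhaustive", seed = 1L) {
  k <- length(map_a)
  stopifnot(length(map_b) == k)
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0)
    stop("zero-variance map")
  obs <- stats::cor(map_a, map_b)
  if (identical(n, "exhaustive")) {
    P <- .all_perms(k)
    null <- vapply(seq_len(nrow(P)),
                   function(i) stats::cor(map_a[P[i, ]], map_b), numeric(1))
    .null_distribution(obs, null, "shuffle-exhaustive", nrow(P), NA_integer_,
                       exact = TRUE)
  } else {
    null <- .with_seed(seed, {
      vapply(seq_len(n), function(i) stats::cor(sample(map_a), map_b),
             numeric(1))
    })
    .null_distribution(obs, null, "shuffle-sampled", n, seed)
  }
}

#' Spatially informed profile correlation test for one metric class
#'
#' Dispatches to [spin_test()] for thickness and surface-area maps (34
#' cortical parcels) and to [shuffle_test()] for subcortical volume (7
#' regions), taking per-region profiles named in the canonical layout.
#'
#' @param sample_smds named per-region SMD vector or [roi_smd_profile()]
#'   output.
#' @param weights a `weight_set`.
#' @param metric_class `"thickness"`, `"area"` or `"volume"`.
#' @param n permutations for spin (or shuffle sampling).
#' @param seed RNG seed.
#' @return A `null_distribution`.
#' @export
metric_profile_test <- function(sample_smds, weights,
                                metric_class = c("thickness", "area",
                                                 "volume"),
                                n = 10000L, seed = 1L) {
  metric_class <- match.arg(metric_class)
  if (is.data.frame(sample_smds))
    sample_smds <- stats::setNames(sample_smds$cohens_d, sample_smds$region)
  sel <- weights$metric_class == metric_class
  a <- sample_smds[weights$region[sel]]
  b <- weights$theta[sel]
  if (metric_class == "volume") return(shuffle_test(a, b, seed = seed))
  parcel <- sub(paste0("_", metric_class, "$"), "", weights$region[sel])
  names(a) <- parcel
  names(b) <- parcel
  spin_test(a, b, n = n, seed = seed)
}
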
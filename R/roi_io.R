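# Reading, writing and validating subject-by-region tables and per-region
# effect-size weight tables.

.covariate_cols <- c("subject_id", "diagnosis", "site", "age", "sex", "iq",
                     "icv", "mean_thickness", "mean_area")

#' Construct a weight set
#'
#' A weight set maps each of the canonical 75 regions to a signed effect
#' size \eqn{\theta} (Cohen's d scale) with a provenance tag recording how
#' the weights were built.
#'
#' @param region character vector of region names (canonicalized against the
#'   75-region layout, order-independent).
#' @param theta numeric effect sizes, same length.
#' @param provenance one of `"scz_raw"`, `"bd_raw"`, `"pc1_shared"`,
#'   `"scz_unique"`, `"bd_unique"`, `"h0"`.
#' @param note free-text source note.
#' @return data.frame of class `weight_set` with columns `region`, `theta`,
#'   `metric_class`, ordered as [canonical_regions()]; attributes
#'   `provenance` and `note`.
#' @export
weight_set <- function(region, theta,
                       provenance = c("scz_raw", "bd_raw", "pc1_shared",
                                      "scz_unique", "bd_unique", "h0"),
                       note = "") {
  provenance <- match.arg(provenance)
  if (length(region) != length(theta))
    stop("region and theta lengths differ")
  if (length(region) == 0L) stop("empty region list")
  canon <- canonical_regions()
  key <- canonicalize_region(region)
  ckey <- canonicalize_region(canon$region)
  if (anyDuplicated(key) > 0L)
    stop("duplicate region: ", region[duplicated(key)][1L])
  unknown <- setdiff(key, ckey)
  if (length(unknown) > 0L)
    stop("unknown region name: ", paste(unknown, collapse = ", "))
  if (length(key) != 75L)
    stop("expected 75 regions, got ", length(key))
  if (any(!is.finite(theta))) stop("non-finite theta")
  idx <- match(ckey, key)
  ws <- data.frame(region = canon$region, theta = as.numeric(theta)[idx],
                   metric_class = canon$metric_class,
                   stringsAsFactors = FALSE)
  if (provenance == "h0" && any(ws$theta != 1))
    stop("h0 provenance requires all theta = 1")
  structure(ws, provenance = provenance, note = note,
            class = c("weight_set", "data.frame"))
}

#' @method print weight_set
#' @export
print.weight_set <- function(x, ...) {
  cat("<weight_set> provenance:", attr(x, "provenance"),
      "| 75 regions | theta range [",
      sprintf("%.3f", min(x$theta)), ",", sprintf("%.3f", max(x$theta)), "]\n")
  invisible(x)
}

#' Read a per-region weight table
#'
#' Expects a delimited table with columns `region` and `effect_size` (or
#' `theta`); rows may be in any order and are aligned to the canonical
#' 75-region layout.
#'
#' @param path file path (CSV/TSV; delimiter auto-detected unless given).
#' @param provenance provenance tag for the resulting [weight_set()].
#' @param delimiter optional explicit field delimiter.
#' @return A `weight_set`.
#' @export
read_weight_table <- function(path, provenance = "scz_raw",
                              delimiter = NULL) {
  tab <- .read_delim(path, delimiter)
  val_col <- intersect(c("effect_size", "theta"), names(tab))
  if (!"region" %in% names(tab) || length(val_col) == 0L)
    stop("weight table needs columns 'region' and 'effect_size' (or 'theta')")
  weight_set(tab$region, tab[[val_col[1L]]], provenance = provenance,
             note = paste("read from", basename(path)))
}

#' Write a weight set to CSV
#' @param ws a `weight_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(ws, path) {
  out <- data.frame(region = ws$region, theta = ws$theta,
                    provenance = attr(ws, "provenance"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_delim <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    first <- readLines(path, n = 1L)
    delimiter <- if (lengths(regmatches(first, gregexpr("\t", first))) >
                     lengths(regmatches(first, gregexpr(",", first))))
      "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = delimiter,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Bilaterally average two hemisphere values
#'
#' @param left,right numeric vectors of per-hemisphere measurements; `NA`
#'   marks a missing hemisphere.
#' @param policy `"both"` requires both hemispheres; `"available"` lets a
#'   single present hemisphere pass through unchanged.
#' @return numeric vector of bilateral means.
#' @examples
#' bilateral_average(2.8, 3.0)              # 2.9
#' bilateral_average(2.8, NA, "available")  # 2.8
#' @export
bilateral_average <- function(left, right, policy = c("both", "available")) {
  policy <- match.arg(policy)
  if (length(left) != length(right)) stop("hemisphere lengths differ")
  both_na <- is.na(left) & is.na(right)
  if (any(both_na)) stop("both hemispheres missing")
  if (policy == "both") {
    if (any(is.na(left) | is.na(right)))
      stop("missing hemisphere under policy 'both'")
    (left + right) / 2
  } else {
    rowMeans(cbind(left, right), na.rm = TRUE)
  }
}

#' Validate a subject-by-region table
#'
#' Checks the covariate columns, the 75-region layout and value sanity, and
#' attaches the region/metric-class map. Called by [read_roi_table()] and
#' [simulate_cohort()]; exported so externally assembled data.frames can be
#' validated the same way.
#'
#' @param df data.frame with the covariate columns (`subject_id`,
#'   `diagnosis`, `site`, `age`, `sex`, `iq`, `icv`, `mean_thickness`,
#'   `mean_area`, optionally `cpz_equivalent`) and 75 region columns named
#'   `<parcel>_<metric_class>`.
#' @return the validated data.frame, class `roi_table`, with attribute
#'   `region_info` (the [canonical_regions()] map).
#' @export
as_roi_table <- function(df) {
  missing_cov <- setdiff(.covariate_cols, names(df))
  if (length(missing_cov) > 0L)
    stop("missing mandatory column: ", paste(missing_cov, collapse = ", "))
  canon <- canonical_regions()
  key <- canonicalize_region(names(df))
  idx <- match(canonicalize_region(canon$region), key)
  n_found <- sum(!is.na(idx))
  if (n_found != 75L)
    stop("expected 75 regions, found ", n_found)
  region_cols <- names(df)[idx]
  for (rc in region_cols) {
    if (!is.numeric(df[[rc]]))
      stop("non-numeric region column: ", rc)
    if (any(is.infinite(df[[rc]])))
      stop("non-finite value in region column: ", rc)
  }
  if (anyDuplicated(df$subject_id) > 0L) stop("duplicated subject_id")
  if (any(is.na(df$site)) || any(is.na(df$diagnosis)))
    stop("every subject needs site and diagnosis")
  sex <- df$sex
  if (is.character(sex) || is.factor(sex)) {
    sex <- toupper(as.character(sex))
    if (!all(sex %in% c("F", "M", "0", "1")))
      stop("sex must be coded F/M or 0/1")
    df$sex <- ifelse(sex %in% c("M", "1"), 1L, 0L)
  }
  # reorder region columns to canonical order, covariates first
  extra <- setdiff(names(df), c(.covariate_cols, "cpz_equivalent",
                                region_cols))
  keep <- c(.covariate_cols,
            intersect("cpz_equivalent", names(df)), region_cols, extra)
  out <- df[, keep, drop = FALSE]
  names(out)[match(region_cols, names(out))] <- canon$region
  structure(out, region_info = canon,
            class = c("roi_table", "data.frame"))
}

#' Read a subject-by-region measurement table
#'
#' Reads a wide CSV/TSV (one row per subject; covariate columns plus 75
#' bilaterally averaged region columns) and validates it against the
#' canonical layout. Missing region values are preserved as `NA`.
#'
#' @inheritParams read_weight_table
#' @return A validated `roi_table`.
#' @export
read_roi_table <- function(path, delimiter = NULL) {
  as_roi_table(.read_delim(path, delimiter))
}

#' Write a subject-by-region table to CSV
#' @param table a `roi_table` (or compatible data.frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Extract the region-value matrix from a table
#' @param table a `roi_table` or `residual_table`.
#' @return numeric matrix, subjects x 75 regions (canonical order).
#' @export
region_matrix <- function(table) {
  canon <- canonical_regions()
  m <- as.matrix(as.data.frame(table)[, canon$region, drop = FALSE])
  rownames(m) <- table$subject_id
  m
}
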
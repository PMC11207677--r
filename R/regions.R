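#' @keywords internal
#' @useDynLib mrscore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Desikan-Killiany cortical parcels (34, bilaterally averaged) and the
# ENIGMA-standard subcortical set (7). Region columns are <name>_<class>.
.dk_cortical <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula"
)

.subcortical <- c(
  "thalamus", "caudate", "putamen", "pallidum", "hippocampus", "amygdala",
  "accumbens"
)

#' Canonical 75-region layout
#'
#' The package works on 75 bilaterally averaged regions of interest:
#' cortical thickness (mm) and cortical surface area (mm\eqn{^2}) for the 34
#' Desikan-Killiany parcels, plus 7 subcortical volumes (mm\eqn{^3}).
#'
#' @return A data.frame with columns `region` (canonical column name,
#'   `<parcel>_<metric_class>`), `parcel` and `metric_class` (one of
#'   `"thickness"`, `"area"`, `"volume"`), 75 rows.
#' @examples
#' table(canonical_regions()$metric_class)
#' @export
canonical_regions <- function() {
  data.frame(
    region = c(
      paste0(.dk_cortical, "_thickness"),
      paste0(.dk_cortical, "_area"),
      paste0(.subcortical, "_volume")
    ),
    parcel = c(.dk_cortical, .dk_cortical, .subcortical),
    metric_class = rep(c("thickness", "area", "volume"), c(34L, 34L, 7L)),
    stringsAsFactors = FALSE
  )
}

#' Canonicalize region names
#'
#' Lower-cases, strips non-alphanumeric separators and common hemisphere
#' prefixes so that e.g. `"Left-Hippocampus"` and `"hippocampus"` fold to the
#' same key. Idempotent.
#'
#' @param x character vector of region labels.
#' @return character vector of canonical keys.
#' @export
canonicalize_region <- function(x) {
  y <- tolower(x)
  y <- gsub("[^a-z0-9]+", "", y)
  y <- sub("^(lh|rh|left|right)", "", y)
  y
}

#' Spherical centroids for the 34 cortical parcels
#'
#' Approximate hemisphere-averaged centroid directions for the
#' Desikan-Killiany parcels, projected onto the unit sphere. These are
#' synthetic coordinates authored from standard anatomical locations (lateral
#' / anterior / superior axes), not FreeSurfer sphere registrations; they
#' provide the spatial embedding the spin test needs and can be overridden
#' with a user file of the same layout.
#'
#' @param path optional CSV (columns `parcel`, `x`, `y`, `z`) replacing the
#'   bundled fixture.
#' @return data.frame with columns `parcel`, `x`, `y`, `z`; 34 rows, each
#'   coordinate row of unit norm.
#' @export
parcel_geometry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dk34_sphere_centroids_approx.csv",
                        package = "mrscore")
  }
  geo <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("parcel", "x", "y", "z") %in% names(geo)))
  if (anyDuplicated(geo$parcel) > 0L)
    stop("duplicate parcel in geometry file")
  xyz <- as.matrix(geo[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(xyz^2))
  if (any(nrm == 0)) stop("zero-length centroid in geometry file")
  geo[, c("x", "y", "z")] <- xyz / nrm
  geo
}

# Synthetic ENIGMA-like per-region Cohen's d profiles. These are NOT the
# published meta-analytic tables (which users must supply themselves); they
# are hand-authored values with the field-typical shape: diffuse cortical
# thinning strongest in temporal cortex, small surface-area effects, mixed
# subcortical effects with hippocampal/amygdala reduction and pallidal
# enlargement. The bipolar profile is an attenuated, partly decoupled
# variant of the schizophrenia profile.
.synthetic_scz_d <- c(
  bankssts_thickness = -0.32, caudalanteriorcingulate_thickness = -0.12,
  caudalmiddlefrontal_thickness = -0.22, cuneus_thickness = -0.11,
  entorhinal_thickness = -0.18, fusiform_thickness = -0.53,
  inferiorparietal_thickness = -0.29, inferiortemporal_thickness = -0.46,
  isthmuscingulate_thickness = -0.17, lateraloccipital_thickness = -0.21,
  lateralorbitofrontal_thickness = -0.35, lingual_thickness = -0.20,
  medialorbitofrontal_thickness = -0.33, middletemporal_thickness = -0.49,
  parahippocampal_thickness = -0.25, paracentral_thickness = -0.14,
  parsopercularis_thickness = -0.35, parsorbitalis_thickness = -0.30,
  parstriangularis_thickness = -0.32, pericalcarine_thickness = -0.06,
  postcentral_thickness = -0.18, posteriorcingulate_thickness = -0.20,
  precentral_thickness = -0.21, precuneus_thickness = -0.24,
  rostralanteriorcingulate_thickness = -0.26,
  rostralmiddlefrontal_thickness = -0.31, superiorfrontal_thickness = -0.34,
  superiorparietal_thickness = -0.16, superiortemporal_thickness = -0.45,
  supramarginal_thickness = -0.30, frontalpole_thickness = -0.22,
  temporalpole_thickness = -0.28, transversetemporal_thickness = -0.27,
  insula_thickness = -0.38,
  bankssts_area = -0.09, caudalanteriorcingulate_area = -0.05,
  caudalmiddlefrontal_area = -0.10, cuneus_area = -0.06,
  entorhinal_area = -0.04, fusiform_area = -0.14,
  inferiorparietal_area = -0.12, inferiortemporal_area = -0.11,
  isthmuscingulate_area = -0.07, lateraloccipital_area = -0.10,
  lateralorbitofrontal_area = -0.11, lingual_area = -0.09,
  medialorbitofrontal_area = -0.12, middletemporal_area = -0.10,
  parahippocampal_area = -0.05, paracentral_area = -0.06,
  parsopercularis_area = -0.10, parsorbitalis_area = -0.08,
  parstriangularis_area = -0.09, pericalcarine_area = -0.04,
  postcentral_area = -0.11, posteriorcingulate_area = -0.08,
  precentral_area = -0.12, precuneus_area = -0.10,
  rostralanteriorcingulate_area = -0.07, rostralmiddlefrontal_area = -0.13,
  superiorfrontal_area = -0.14, superiorparietal_area = -0.10,
  superiortemporal_area = -0.12, supramarginal_area = -0.11,
  frontalpole_area = -0.03, temporalpole_area = -0.05,
  transversetemporal_area = -0.07, insula_area = -0.09,
  thalamus_volume = -0.31, caudate_volume = -0.05, putamen_volume = 0.07,
  pallidum_volume = 0.21, hippocampus_volume = -0.46,
  amygdala_volume = -0.31, accumbens_volume = -0.25
)

.synthetic_bd_d <- c(
  bankssts_thickness = -0.19, caudalanteriorcingulate_thickness = -0.10,
  caudalmiddlefrontal_thickness = -0.14, cuneus_thickness = -0.04,
  entorhinal_thickness = -0.06, fusiform_thickness = -0.32,
  inferiorparietal_thickness = -0.18, inferiortemporal_thickness = -0.29,
  isthmuscingulate_thickness = -0.12, lateraloccipital_thickness = -0.10,
  lateralorbitofrontal_thickness = -0.23, lingual_thickness = -0.11,
  medialorbitofrontal_thickness = -0.19, middletemporal_thickness = -0.26,
  parahippocampal_thickness = -0.10, paracentral_thickness = -0.11,
  parsopercularis_thickness = -0.22, parsorbitalis_thickness = -0.16,
  parstriangularis_thickness = -0.20, pericalcarine_thickness = -0.02,
  postcentral_thickness = -0.13, posteriorcingulate_thickness = -0.15,
  precentral_thickness = -0.14, precuneus_thickness = -0.17,
  rostralanteriorcingulate_thickness = -0.21,
  rostralmiddlefrontal_thickness = -0.24, superiorfrontal_thickness = -0.23,
  superiorparietal_thickness = -0.08, superiortemporal_thickness = -0.24,
  supramarginal_thickness = -0.18, frontalpole_thickness = -0.20,
  temporalpole_thickness = -0.13, transversetemporal_thickness = -0.14,
  insula_thickness = -0.26,
  bankssts_area = -0.03, caudalanteriorcingulate_area = -0.02,
  caudalmiddlefrontal_area = -0.04, cuneus_area = -0.01,
  entorhinal_area = 0.01, fusiform_area = -0.05,
  inferiorparietal_area = -0.04, inferiortemporal_area = -0.04,
  isthmuscingulate_area = -0.03, lateraloccipital_area = -0.02,
  lateralorbitofrontal_area = -0.04, lingual_area = -0.03,
  medialorbitofrontal_area = -0.05, middletemporal_area = -0.03,
  parahippocampal_area = 0.00, paracentral_area = -0.02,
  parsopercularis_area = -0.04, parsorbitalis_area = -0.02,
  parstriangularis_area = -0.03, pericalcarine_area = -0.01,
  postcentral_area = -0.04, posteriorcingulate_area = -0.03,
  precentral_area = -0.05, precuneus_area = -0.03,
  rostralanteriorcingulate_area = -0.02, rostralmiddlefrontal_area = -0.05,
  superiorfrontal_area = -0.06, superiorparietal_area = -0.03,
  superiortemporal_area = -0.04, supramarginal_area = -0.04,
  frontalpole_area = 0.00, temporalpole_area = -0.01,
  transversetemporal_area = -0.02, insula_area = -0.03,
  thalamus_volume = -0.15, caudate_volume = -0.04, putamen_volume = 0.00,
  pallidum_volume = 0.11, hippocampus_volume = -0.23,
  amygdala_volume = -0.11, accumbens_volume = -0.18
)

#' Bundled synthetic effect-size weight sets
#'
#' Returns a [weight_set()] of synthetic, hand-authored per-region Cohen's d
#' values shaped like published case-control meta-analytic profiles
#' (diffuse cortical thinning, small area effects, mixed subcortical
#' effects). They exist so that every stage of the pipeline can be exercised
#' without the restricted meta-analytic tables, which users supply
#' themselves via [read_weight_table()].
#'
#' @param disorder `"scz"` or `"bd"`.
#' @return A `weight_set` (provenance `scz_raw` / `bd_raw`).
#' @examples
#' w <- synthetic_weights("scz")
#' range(w$theta)
#' @export
synthetic_weights <- function(disorder = c("scz", "bd")) {
  disorder <- match.arg(disorder)
  th <- if (disorder == "scz") .synthetic_scz_d else .synthetic_bd_d
  weight_set(names(th), unname(th),
             provenance = paste0(disorder, "_raw"),
             note = "synthetic profile bundled with mrscore; not ENIGMA data")
}
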
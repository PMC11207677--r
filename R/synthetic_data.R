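# Synthetic case-control cohort generator. Every downstream stage of the
# pipeline (deconfounding, harmonization, scoring, inference) can be
# exercised and validated against known ground truth without access to the
# restricted clinical datasets the method is normally applied to.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

.default_region_specs <- function() {
  canon <- canonical_regions()
  baseline <- numeric(75L)
  sd <- numeric(75L)
  th <- canon$metric_class == "thickness"
  ar <- canon$metric_class == "area"
  vo <- canon$metric_class == "volume"
  # plausible FreeSurfer-scale values; Table-1-style data report only global
  # means, so per-region baselines are free defaults (see vignette)
  baseline[th] <- 2.25 + 0.018 * seq_len(34L)   # 2.27 .. 2.86 mm
  sd[th] <- 0.12
  baseline[ar] <- 1500 + 62 * seq_len(34L)      # 1562 .. 3608 mm^2
  sd[ar] <- 0.08 * baseline[ar]
  baseline[vo] <- c(thalamus = 7500, caudate = 3600, putamen = 5000,
                    pallidum = 1800, hippocampus = 4000, amygdala = 1600,
                    accumbens = 600)
  sd[vo] <- 0.09 * baseline[vo]
  data.frame(region = canon$region, metric_class = canon$metric_class,
             baseline = baseline, sd = sd, stringsAsFactors = FALSE)
}

.sim_group <- function(label, n, case, age_mean, age_sd, prop_male,
                       iq_mean, iq_sd, thickness_mean, thickness_sd,
                       area_mean, area_sd, icv_mean, icv_sd) {
  list(label = label, n = as.integer(n), case = case, age_mean = age_mean,
       age_sd = age_sd, prop_male = prop_male, iq_mean = iq_mean,
       iq_sd = iq_sd, thickness_mean = thickness_mean,
       thickness_sd = thickness_sd, area_mean = area_mean,
       area_sd = area_sd, icv_mean = icv_mean, icv_sd = icv_sd)
}

#' Build a simulation configuration
#'
#' Defines the generative model for a synthetic case-control morphometry
#' cohort: group structure and covariate distributions, per-region baseline
#' scale and residual noise, a signed per-region true effect profile (in
#' residual-SD units, so realized population SMDs equal the profile
#' exactly), multiplicative/additive site effects, and linear
#' covariate/global-size coupling.
#'
#' @param groups list of group definitions (see [emulate_table1()] for the
#'   bundled scenarios); each a list with `label`, `n`, `case` (logical),
#'   `age_mean`, `age_sd`, `prop_male`, `iq_mean`, `iq_sd`,
#'   `thickness_mean`, `thickness_sd`, `area_mean`, `area_sd`, `icv_mean`,
#'   `icv_sd`.
#' @param regions data.frame with columns `region`, `metric_class`,
#'   `baseline`, `sd` (75 rows; defaults to plausible FreeSurfer-scale
#'   values).
#' @param effect_profile named numeric vector of true per-region SMDs
#'   (cases minus controls, residual scale); default all zero.
#' @param sites list of site definitions: each a list with `label`, `prob`
#'   (sampling weight), `shift` (additive, scalar or per-region) and
#'   `scale` (multiplicative, positive).
#' @param covariate_slopes per-metric-class linear slopes: a list with
#'   elements `thickness`, `area`, `volume`, each `c(age = , sex = )` in
#'   measurement units (sex coded 0 = F, 1 = M).
#' @param global_coupling per-region loading on the metric-matched global
#'   measure (mean thickness / mean area / ICV); default proportional
#'   (`baseline / reference global mean`).
#' @param seed integer RNG seed; identical configs generate byte-identical
#'   cohorts.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(groups,
                       regions = NULL,
                       effect_profile = NULL,
                       sites = list(list(label = "site1", prob = 1,
                                         shift = 0, scale = 1)),
                       covariate_slopes = NULL,
                       global_coupling = NULL,
                       seed = 1L) {
  if (is.null(regions)) regions <- .default_region_specs()
  if (anyDuplicated(regions$region) > 0L)
    stop("duplicated region names in region specs")
  if (any(regions$sd <= 0)) stop("non-positive region sd")
  if (length(sites) == 0L) stop("empty site list")
  if (is.null(effect_profile)) {
    effect_profile <- stats::setNames(numeric(nrow(regions)),
                                      regions$region)
  }
  if (length(effect_profile) != nrow(regions))
    stop("effect_profile length must equal number of regions")
  if (is.null(names(effect_profile)))
    names(effect_profile) <- regions$region
  effect_profile <- effect_profile[regions$region]
  if (any(is.na(effect_profile))) stop("effect_profile names do not match regions")
  if (is.null(covariate_slopes)) {
    covariate_slopes <- list(
      thickness = c(age = -0.006, sex = -0.012),
      area = c(age = -4, sex = 160),
      volume = c(age = -12, sex = 220))
  }
  for (s in sites) {
    if (any(s$scale <= 0)) stop("non-positive site scale")
  }
  ns <- vapply(groups, function(g) g$n, numeric(1))
  if (any(ns < 0)) stop("negative group count")
  structure(list(groups = groups, regions = regions,
                 effect_profile = effect_profile, sites = sites,
                 covariate_slopes = covariate_slopes,
                 global_coupling = global_coupling, seed = as.integer(seed)),
            class = "sim_config")
}

#' Configurations matching the published descriptive tables
#'
#' Returns a [sim_config()] whose group sizes, age means/SDs, sex
#' proportions, IQ and global-measure distributions match the descriptive
#' statistics of the two study samples: a four-site early-psychosis
#' discovery cohort (23 bipolar / 47 control / 54 schizophrenia) and a
#' single-site replication cohort (24 control / 45 schizophrenia).
#'
#' @param scenario `"discovery"` or `"replication"`.
#' @param effect_profile optional named true-SMD vector passed through to
#'   [sim_config()].
#' @param seed RNG seed.
#' @return a `sim_config`.
#' @export
emulate_table1 <- function(scenario = c("discovery", "replication"),
                           effect_profile = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  if (scenario == "discovery") {
    groups <- list(
      .sim_group("control", 47L, FALSE, 25.2, 4.14, 1 - 0.340, 116, 10.8,
                 2.89, 0.0918, 2580, 188, 1640000, 148000),
      .sim_group("schizophrenia", 54L, TRUE, 22.1, 2.74, 1 - 0.204, 96.4,
                 16.2, 2.79, 0.117, 2540, 253, 1620000, 163000),
      .sim_group("bipolar", 23L, TRUE, 24.4, 3.78, 1 - 0.652, 108, 16.6,
                 2.86, 0.106, 2510, 265, 1580000, 187000))
    # four acquisition sites with the published relative sizes and mild
    # scanner effects for the harmonization stage to remove
    sites <- list(
      list(label = "IU",  prob = 60 / 124, shift = 0.00, scale = 1.00),
      list(label = "BWH", prob = 17 / 124, shift = 0.15, scale = 1.04),
      list(label = "McL", prob = 33 / 124, shift = -0.10, scale = 0.97),
      list(label = "MGH", prob = 14 / 124, shift = 0.08, scale = 1.02))
  } else {
    groups <- list(
      .sim_group("control", 24L, FALSE, 40.2, 14.3, 1 - 0.292, 101, 9.91,
                 2.52, 0.105, 2540, 244, 1130000, 102000),
      .sim_group("schizophrenia", 45L, TRUE, 42.5, 10.8, 1 - 0.222, 99.8,
                 9.27, 2.44, 0.0897, 2400, 221, 1100000, 99200))
    sites <- list(list(label = "FIDMAG", prob = 1, shift = 0, scale = 1))
  }
  sim_config(groups = groups, sites = sites,
             effect_profile = effect_profile, seed = seed)
}

#' Simulate a case-control morphometry cohort
#'
#' Draws covariates and global measures per group, builds each region as
#' baseline + global coupling + covariate effects + Gaussian residual, adds
#' the diagnosis effect on the residual scale (so true per-region SMDs equal
#' `config$effect_profile` exactly), then applies per-site multiplicative
#' and additive contamination (`value <- scale * value + shift`).
#'
#' @param config a [sim_config()].
#' @return list with elements `table` (a validated `roi_table`) and `truth`
#'   (ground truth: true SMD profile, site shifts/scales, per-subject case
#'   indicator and site assignment, seed).
#' @examples
#' cohort <- simulate_cohort(emulate_table1("replication", seed = 42))
#' nrow(cohort$table)  # 69 subjects
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    regions <- config$regions
    R <- nrow(regions)
    cls <- regions$metric_class
    # reference globals = first control group's means
    ctrl <- Filter(function(g) !g$case, config$groups)[[1]]
    gref <- c(thickness = ctrl$thickness_mean, area = ctrl$area_mean,
              volume = ctrl$icv_mean)
    coupling <- config$global_coupling
    if (is.null(coupling)) coupling <- regions$baseline / gref[cls]
    rows <- list()
    for (g in config$groups) {
      if (g$n == 0L) next
      n <- g$n
      age <- stats::rnorm(n, g$age_mean, g$age_sd)
      sex <- stats::rbinom(n, 1L, g$prop_male)
      iq <- stats::rnorm(n, g$iq_mean, g$iq_sd)
      mth <- stats::rnorm(n, g$thickness_mean, g$thickness_sd)
      mar <- stats::rnorm(n, g$area_mean, g$area_sd)
      icv <- stats::rnorm(n, g$icv_mean, g$icv_sd)
      glob <- cbind(thickness = mth, area = mar, volume = icv)
      eps <- matrix(stats::rnorm(n * R), n, R)
      if (g$case) eps <- eps + matrix(config$effect_profile, n, R,
                                      byrow = TRUE)
      sl <- config$covariate_slopes
      age_sl <- vapply(cls, function(k) sl[[k]]["age"], numeric(1))
      sex_sl <- vapply(cls, function(k) sl[[k]]["sex"], numeric(1))
      vals <- matrix(regions$baseline, n, R, byrow = TRUE) +
        (glob[, cls, drop = FALSE] -
           matrix(gref[cls], n, R, byrow = TRUE)) *
          matrix(coupling, n, R, byrow = TRUE) +
        outer(age - 30, age_sl) + outer(sex, sex_sl) +
        eps * matrix(regions$sd, n, R, byrow = TRUE)
      colnames(vals) <- regions$region
      rows[[g$label]] <- data.frame(
        subject_id = paste0(g$label, "_", seq_len(n)),
        diagnosis = g$label, site = NA_character_, age = age, sex = sex,
        iq = iq, icv = icv, mean_thickness = mth, mean_area = mar,
        vals, check.names = FALSE, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    n_all <- nrow(tab)
    probs <- vapply(config$sites, function(s) s$prob, numeric(1))
    labels <- vapply(config$sites, function(s) s$label, character(1))
    site_idx <- sample.int(length(labels), n_all, replace = TRUE,
                           prob = probs)
    tab$site <- labels[site_idx]
    shifts <- lapply(config$sites, function(s) rep_len(s$shift, R))
    scales <- lapply(config$sites, function(s) rep_len(s$scale, R))
    m <- as.matrix(tab[, regions$region, drop = FALSE])
    for (si in seq_along(labels)) {
      sel <- site_idx == si
      if (!any(sel)) next
      m[sel, ] <- sweep(sweep(m[sel, , drop = FALSE], 2L, scales[[si]],
                              "*"), 2L, shifts[[si]], "+")
    }
    tab[, regions$region] <- m
    truth <- list(
      effect_profile = config$effect_profile,
      site_shift = stats::setNames(shifts, labels),
      site_scale = stats::setNames(scales, labels),
      case = vapply(config$groups[match(tab$diagnosis,
               vapply(config$groups, `[[`, character(1), "label"))],
               `[[`, logical(1), "case"),
      site = tab$site, seed = config$seed)
    list(table = as_roi_table(tab), truth = truth)
  })
}

#' Write a simulated cohort to disk
#'
#' The measurement table goes to `<stem>.csv` (tidy wide CSV) and the
#' ground truth to a `<stem>_truth.json` sidecar.
#'
#' @param cohort result of [simulate_cohort()].
#' @param stem output path stem.
#' @return character vector of the two paths, invisibly.
#' @export
write_cohort <- function(cohort, stem) {
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, "_truth.json")
  write_roi_table(cohort$table, csv)
  jsonlite::write_json(cohort$truth, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
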
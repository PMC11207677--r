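# End-to-end orchestration: simulate or ingest a cohort, harmonize, build
# weight sets, score, run the inferential battery and spatial nulls, and
# evaluate the out-of-distribution classifier, from a single config with
# one top-level seed.

.pipeline_defaults <- function() {
  list(seed = 1L, scenario = "discovery", replication = TRUE,
       weights = "synthetic", effect = NULL, mode = "mean_congruent",
       site = "random", fit_population = "all", combat = "parametric",
       permutations = 1000L)
}

.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  # fail fast on referenced files before any compute
  if (is.list(cfg$weights)) {
    for (w in c("scz", "bd")) {
      if (is.null(cfg$weights[[w]]))
        stop("stage weights: config must name both 'scz' and 'bd' tables")
      if (!file.exists(cfg$weights[[w]]))
        stop("stage weights: file not found: ", cfg$weights[[w]])
    }
  }
  if (is.list(cfg$input) && !is.null(cfg$input$table) &&
      !file.exists(cfg$input$table))
    stop("stage ingest: file not found: ", cfg$input$table)
  cfg
}

#' Run the full scoring-and-inference pipeline
#'
#' Orchestrates simulate/ingest, deconfound + ComBat, weight-set
#' construction (raw, shared PC1, unique, null), scoring, group inference
#' (coefficient table and post-hoc contrasts), effect-size comparisons with
#' spatial permutation nulls, and — when a replication cohort is configured
#' — out-of-distribution scoring and classification with the
#' discovery-fitted transforms. Every artifact is written under `out_dir`
#' and all randomness flows from the single `seed`.
#'
#' @param config a YAML file path or a list. Recognized fields: `seed`;
#'   `scenario` (`"discovery"`) or `input: {table: path}`; `replication`
#'   (logical or `{table: path}`); `weights` (`"synthetic"` or
#'   `{scz: path, bd: path}`); `effect` (`NULL` for a null cohort, or
#'   `{source: "scz_unique", target_smd: 0.6}` for a calibrated diffuse
#'   profile); `mode` (scoring), `site` (group-model site handling),
#'   `fit_population`, `combat`, `permutations`.
#' @param out_dir artifact directory (created; default a fresh tempdir
#'   subdirectory).
#' @return invisibly, a list with the artifact paths and the in-memory
#'   results (`scores`, `table2`, `table3`, `comparisons`, `classifier`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- .load_config(config)
  if (is.null(out_dir))
    out_dir <- file.path(tempdir(), paste0("mrs_run_", cfg$seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  ## weight sets
  if (identical(cfg$weights, "synthetic")) {
    w_scz <- synthetic_weights("scz"); w_bd <- synthetic_weights("bd")
  } else {
    w_scz <- read_weight_table(cfg$weights$scz, provenance = "scz_raw")
    w_bd <- read_weight_table(cfg$weights$bd, provenance = "bd_raw")
  }
  wsets <- list(pc1 = pc1_shared(w_scz, w_bd),
                scz_unique = unique_weights(w_scz, w_bd, "scz_unique"),
                bd_unique = unique_weights(w_bd, w_scz, "bd_unique"),
                h0 = h0_weights())
  for (nm in names(wsets))
    write_weight_table(wsets[[nm]], file.path(out_dir,
                                              paste0("weights_", nm, ".csv")))

  ## effect profile (study condition)
  profile <- NULL
  if (!is.null(cfg$effect)) {
    src <- cfg$effect$source %||% "scz_unique"
    target <- cfg$effect$target_smd %||% 0.6
    cal <- calibrate_effect_profile(wsets[[src]], target_smd = target,
                                    mode = cfg$mode, seed = seed)
    profile <- cal$profile
  }

  ## discovery cohort
  if (is.list(cfg$input) && !is.null(cfg$input$table)) {
    table <- read_roi_table(cfg$input$table)
  } else {
    table <- simulate_cohort(emulate_table1(cfg$scenario,
                                            effect_profile = profile,
                                            seed = seed))$table
  }
  write_roi_table(table, file.path(out_dir, "cohort_discovery.csv"))

  ## harmonize
  h <- harmonize(table, fit_population = cfg$fit_population,
                 mode = cfg$combat)
  write_roi_table(h$residuals, file.path(out_dir, "residuals_discovery.csv"))

  ## score
  scores <- lapply(wsets, function(w) mrs_score(h$residuals, w,
                                                mode = cfg$mode))
  for (nm in names(scores))
    write_mrs(scores[[nm]], file.path(out_dir,
                                      paste0("scores_", nm, ".csv")))

  ## coefficient table (Table-2-shaped) across the four scores
  gs <- lapply(scores, group_model, table = table, site = cfg$site)
  table2 <- data.frame(
    MRS = names(gs),
    BETA = vapply(gs, `[[`, numeric(1), "beta"),
    SE = vapply(gs, `[[`, numeric(1), "se"),
    DF = vapply(gs, `[[`, numeric(1), "df"),
    P = vapply(gs, `[[`, numeric(1), "p_raw"),
    D = vapply(gs, `[[`, numeric(1), "cohens_d"))
  table2$P_CORR <- fdr_adjust(table2$P)
  utils::write.csv(table2, file.path(out_dir, "table2_coefficients.csv"),
                   row.names = FALSE)

  ## post-hoc contrasts (Table-3-shaped) when > 2 diagnosis levels
  table3 <- NULL
  if (length(unique(table$diagnosis)) > 2L) {
    t3 <- lapply(names(scores)[1:3], function(nm) {
      pc <- posthoc_contrasts(scores[[nm]], table, site = cfg$site)
      cbind(MRS = nm, pc)
    })
    table3 <- do.call(rbind, t3)
    utils::write.csv(table3, file.path(out_dir, "table3_posthoc.csv"),
                     row.names = FALSE)
  }

  ## effect-size comparisons and spatial nulls
  prof <- roi_smd_profile(h$residuals, table, site = "fixed")
  comparisons <- list(
    profile_r_pc1 = effect_profile_correlation(prof, wsets$pc1,
                                               stratify_by_metric = TRUE),
    profile_r_scz_unique = effect_profile_correlation(
      prof, wsets$scz_unique, stratify_by_metric = TRUE),
    z_pc1 = smd_vs_roi_distribution(gs$pc1$cohens_d, prof$cohens_d),
    z_scz_unique = smd_vs_roi_distribution(gs$scz_unique$cohens_d,
                                           prof$cohens_d),
    spin_thickness = metric_profile_test(prof, w_scz, "thickness",
                                         n = cfg$permutations,
                                         seed = seed + 11L),
    spin_area = metric_profile_test(prof, w_scz, "area",
                                    n = cfg$permutations, seed = seed + 12L),
    shuffle_volume = metric_profile_test(prof, w_scz, "volume",
                                         seed = seed + 13L))
  jsonlite::write_json(
    list(profile_r_pc1 = comparisons$profile_r_pc1$r,
         profile_r_scz_unique = comparisons$profile_r_scz_unique$r,
         z_pc1 = comparisons$z_pc1, z_scz_unique = comparisons$z_scz_unique,
         p_spin_thickness = comparisons$spin_thickness$p,
         p_spin_area = comparisons$spin_area$p,
         p_shuffle_volume = comparisons$shuffle_volume$p,
         seed = seed),
    file.path(out_dir, "effect_size_comparisons.json"),
    auto_unbox = TRUE, digits = NA)

  ## replication / out-of-distribution stage
  classifier <- NULL
  if (!isFALSE(cfg$replication)) {
    rep_table <- if (is.list(cfg$replication) &&
                     !is.null(cfg$replication$table)) {
      read_roi_table(cfg$replication$table)
    } else {
      simulate_cohort(emulate_table1("replication",
                                     effect_profile = profile,
                                     seed = seed + 1L))$table
    }
    write_roi_table(rep_table, file.path(out_dir, "cohort_replication.csv"))
    rep_res <- apply_deconfound(h$deconfound_model, rep_table)
    # single-site replication: site adjustment is the identity; a multi-site
    # replication acquired at discovery sites reuses the fitted model
    if (length(unique(rep_table$site)) > 1L &&
        all(unique(rep_table$site) %in% h$combat_model$sites))
      rep_res <- apply_combat(h$combat_model, rep_res)
    rep_scores <- mrs_score(rep_res, wsets$scz_unique, mode = cfg$mode)
    write_mrs(rep_scores, file.path(out_dir, "scores_replication.csv"))
    rep_gs <- group_model(rep_scores, rep_table, site = "none")
    clf <- fit_logistic(scores$scz_unique$phi,
                        factor(ifelse(table$diagnosis == "control",
                                      "control", "case"),
                               levels = c("control", "case")))
    ev <- evaluate_ood(clf, rep_scores$phi,
                       factor(ifelse(rep_table$diagnosis == "control",
                                     "control", "case"),
                              levels = c("control", "case")))
    classifier <- list(coefficients = as.list(clf$coefficients),
                       separation = clf$separation,
                       replication_beta = rep_gs$beta,
                       replication_p = rep_gs$p_raw,
                       replication_d = rep_gs$cohens_d,
                       accuracy = ev$accuracy, ci = ev$ci, n = ev$n)
    jsonlite::write_json(classifier,
                         file.path(out_dir, "classifier_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## run log: every flag in effect
  jsonlite::write_json(
    cfg[setdiff(names(cfg), c("input"))],
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(out_dir = out_dir, table = table, residuals = h$residuals,
                 weights = wsets, scores = scores, table2 = table2,
                 table3 = table3, comparisons = comparisons,
                 classifier = classifier))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
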
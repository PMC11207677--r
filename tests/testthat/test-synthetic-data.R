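test_that("identical config and seed give byte-identical cohorts", {
  cfg <- emulate_table1("discovery", seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$truth, b$truth)
  # and the global RNG stream is left untouched
  withr::with_seed(7, x1 <- rnorm(1))
  withr::with_seed(7, {
    invisible(simulate_cohort(cfg))
    x2 <- rnorm(1)
  })
  expect_identical(x1, x2)
})

test_that("table-1 scenarios reproduce the published group structure", {
  coh <- simulate_cohort(emulate_table1("discovery", seed = 1))
  expect_equal(nrow(coh$table), 124L)
  expect_equal(as.vector(table(coh$table$diagnosis)[c("bipolar", "control",
                                                      "schizophrenia")]),
               c(23L, 47L, 54L))
  rep_cfg <- emulate_table1("replication")
  expect_equal(vapply(rep_cfg$groups, `[[`, integer(1), "n"), c(24L, 45L))
  ctrl <- rep_cfg$groups[[1]]
  expect_equal(c(ctrl$age_mean, ctrl$age_sd), c(40.2, 14.3))
  expect_equal(length(rep_cfg$sites), 1L)
  expect_error(emulate_table1("validation"), "arg")
})

test_that("a null generative model yields uniform region-wise p-values", {
  coh <- simulate_cohort(null_sim_config(100L, 100L, seed = 7))
  Y <- region_matrix(coh$table)
  case <- coh$table$diagnosis != "control"
  pvals <- apply(Y, 2L, function(v) stats::t.test(v[case], v[!case])$p.value)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("an injected effect is recovered as the sample SMD", {
  profile <- c(1, rep(0, 74))
  cfg <- null_sim_config(10000L, 10000L, seed = 11)
  cfg$effect_profile[] <- profile
  coh <- simulate_cohort(cfg)
  Y <- region_matrix(coh$table)
  case <- coh$table$diagnosis != "control"
  expect_lt(abs(cohens_d(Y[, 1L], case) - 1), 0.05)
  expect_lt(max(abs(vapply(2:10, function(r) cohens_d(Y[, r], case),
                           numeric(1)))), 0.05)
})

test_that("realized SMD profiles track the generating profile", {
  theta <- synthetic_weights("scz")$theta
  cfg <- null_sim_config(2000L, 2000L, seed = 5)
  cfg$effect_profile[] <- 0.5 * theta
  coh <- simulate_cohort(cfg)
  Y <- region_matrix(coh$table)
  case <- coh$table$diagnosis != "control"
  smds <- apply(Y, 2L, cohens_d, case = case)
  expect_gt(stats::cor(smds, theta), 0.9)
})

test_that("site contamination is applied as scale * value + shift", {
  sites <- list(list(label = "a", prob = 0.5, shift = 0, scale = 1),
                list(label = "b", prob = 0.5, shift = 2, scale = 1.5))
  cfg <- null_sim_config(400L, 0L, seed = 3, sites = sites)
  cfg$regions$sd[] <- 1e-6   # nearly deterministic region values
  coh <- simulate_cohort(cfg)
  Y <- region_matrix(coh$table)
  at_b <- coh$table$site == "b"
  base <- cfg$regions$baseline
  expect_equal(colMeans(Y[!at_b, , drop = FALSE]), setNames(base, colnames(Y)),
               tolerance = 1e-4)
  expect_equal(colMeans(Y[at_b, , drop = FALSE]),
               setNames(1.5 * base + 2, colnames(Y)), tolerance = 1e-4)
})

test_that("config validation rejects degenerate inputs", {
  g <- null_sim_config()$groups
  expect_error(sim_config(groups = g, sites = list()), "empty site list")
  bad <- mrscore:::.default_region_specs()
  bad$sd[1] <- 0
  expect_error(sim_config(groups = g, regions = bad), "non-positive")
  bad2 <- mrscore:::.default_region_specs()
  bad2$region[2] <- bad2$region[1]
  expect_error(sim_config(groups = g, regions = bad2), "duplicated")
  expect_error(sim_config(groups = g, effect_profile = numeric(3)), "length")
})

test_that("cohorts round-trip through the CSV + JSON sidecar", {
  coh <- simulate_cohort(emulate_table1("replication", seed = 2))
  stem <- file.path(tempdir(), "toy_cohort")
  write_cohort(coh, stem)
  back <- read_roi_table(paste0(stem, ".csv"))
  expect_equal(region_matrix(back), region_matrix(coh$table),
               tolerance = 1e-12)
  truth <- jsonlite::read_json(paste0(stem, "_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(unname(unlist(truth$effect_profile)),
               unname(coh$truth$effect_profile))
})
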
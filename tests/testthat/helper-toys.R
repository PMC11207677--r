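# Small programmatic fixtures shared across the suite.

# a valid 75-region table with n subjects and plain Gaussian values
make_toy_roi_table <- function(n = 6L, seed = 1L, sites = "siteA") {
  canon <- canonical_regions()
  withr::with_seed(seed, {
    vals <- matrix(rnorm(n * 75L, mean = 10), n, 75L,
                   dimnames = list(NULL, canon$region))
    df <- data.frame(subject_id = paste0("s", seq_len(n)),
                     diagnosis = rep_len(c("control", "schizophrenia"), n),
                     site = rep_len(sites, n),
                     age = runif(n, 20, 40), sex = sample(0:1, n, TRUE),
                     iq = rnorm(n, 100, 10), icv = rnorm(n, 1.5e6, 1e5),
                     mean_thickness = rnorm(n, 2.8, 0.1),
                     mean_area = rnorm(n, 2500, 200),
                     stringsAsFactors = FALSE)
    as_roi_table(cbind(df, as.data.frame(vals, check.names = FALSE)))
  })
}

# residual-scale table wrapper around a bare subjects x 75 matrix
make_bare_residuals <- function(mat, diagnosis = "control", site = "sim") {
  mrscore:::.bare_residuals(mat, diagnosis, site)
}

# a null simulation config: identical groups, no effect, no covariate
# structure, one site -- per-region values are pure Gaussian noise
null_sim_config <- function(n_control = 100L, n_case = 100L, seed = 1L,
                            sites = list(list(label = "s1", prob = 1,
                                              shift = 0, scale = 1))) {
  g <- list(label = "control", n = n_control, case = FALSE, age_mean = 30,
            age_sd = 5, prop_male = 0.5, iq_mean = 100, iq_sd = 10,
            thickness_mean = 2.8, thickness_sd = 0.1, area_mean = 2500,
            area_sd = 200, icv_mean = 1.5e6, icv_sd = 1e5)
  g2 <- g; g2$label <- "schizophrenia"; g2$n <- n_case; g2$case <- TRUE
  sim_config(groups = list(g, g2), sites = sites,
             covariate_slopes = list(thickness = c(age = 0, sex = 0),
                                     area = c(age = 0, sex = 0),
                                     volume = c(age = 0, sex = 0)),
             global_coupling = rep(0, 75), seed = seed)
}
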
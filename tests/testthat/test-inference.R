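test_that("IQR labeling flags exactly the points beyond the 1.5-IQR fences", {
  out <- iqr_outlier_filter(c(1:9, 100))
  expect_equal(unname(out$fences), c(-3.5, 14.5))  # Q1 = 3.25, Q3 = 7.75
  expect_identical(which(out$flags), 10L)
  expect_equal(out$values, 1:9)
  const <- iqr_outlier_filter(rep(5, 10))
  expect_false(any(const$flags))
  sym <- iqr_outlier_filter(c(-2, -1, 0, 1, 2))
  expect_equal(sym$values, c(-2, -1, 0, 1, 2))
  expect_error(iqr_outlier_filter(c(1, 2, 3)), "at least 4")
})

test_that("BH adjustment equals the definition-level enumeration", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.3), 0.3)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "outside")
  # exhaustive-definition oracle: adj_i = min over cutoffs k with
  # p_(k) >= p_i of m * p_(k) / k, capped at 1
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- vapply(seq_len(m), function(i)
      min(1, min((m / (i:m)) * ps[i:m])), numeric(1))
    out <- numeric(m)
    out[o] <- adj
    out
  }
  withr::with_seed(31, {
    for (i in 1:20) {
      p <- runif(sample(3:40, 1))
      expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-15)
    }
  })
})

test_that("the group model reduces to hand-computed OLS on a toy", {
  toy <- data.frame(
    subject_id = paste0("s", 1:8),
    diagnosis = rep(c("control", "schizophrenia"), each = 4),
    site = "x")
  y <- c(1.2, 0.8, 1.1, 0.9, 2.1, 1.7, 2.2, 2.0)
  gs <- group_model(y, toy, covariates = character(0), site = "none",
                    outlier_filter = FALSE, z_scale = FALSE)
  X <- cbind(1, rep(0:1, each = 4))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  se <- sqrt(drop(crossprod(res)) / 6 * solve(t(X) %*% X)[2, 2])
  expect_equal(gs$beta, beta[2], tolerance = 1e-10)
  expect_equal(gs$se, se, tolerance = 1e-10)
  expect_equal(gs$t, beta[2] / se, tolerance = 1e-10)
  expect_equal(gs$df, 6)
  expect_equal(gs$cohens_d, 2 * gs$t / sqrt(6), tolerance = 1e-12)
})

test_that("a fully confounded outcome has no diagnosis slope", {
  coh <- simulate_cohort(emulate_table1("discovery", seed = 17))
  y <- 3 + 0.2 * coh$table$age
  gs <- suppressWarnings(   # lm warns about the essentially perfect fit
    group_model(y, coh$table, covariates = "age", site = "none",
                outlier_filter = FALSE, z_scale = FALSE))
  expect_lt(abs(gs$beta), 1e-8)
})

test_that("site handling spans random, fixed and none", {
  coh <- simulate_cohort(emulate_table1("discovery", seed = 23))
  h <- harmonize(coh$table)
  sc <- mrs_score(h$residuals, synthetic_weights("scz"))
  fits <- lapply(c("fixed", "none"), function(s)
    group_model(sc, coh$table, site = s))
  expect_true(all(vapply(fits, function(f) is.finite(f$p_raw), logical(1))))
  rand <- suppressWarnings(group_model(sc, coh$table, site = "random"))
  expect_true(is.finite(rand$p_raw))
  bp <- which(coh$table$diagnosis == "bipolar")
  thin <- coh$table[-bp[-1], ]   # keep a single bipolar subject
  expect_error(group_model(sc$phi[-bp[-1]], thin, contrast = "diagnosis",
                           outlier_filter = FALSE), "< 2 subjects")
})

test_that("post-hoc contrasts localize a single shifted group", {
  withr::with_seed(41, {
    toy <- data.frame(
      subject_id = paste0("s", 1:150),
      diagnosis = rep(c("control", "schizophrenia", "bipolar"), each = 50),
      site = "x")
    y <- rnorm(150) + rep(c(0, 2, 0), each = 50)
  })
  pc <- posthoc_contrasts(y, toy, covariates = character(0), site = "none")
  expect_equal(nrow(pc), 3L)
  scz_rows <- grepl("schizophrenia", pc$contrast)
  expect_true(all(pc$p_adjusted[scz_rows] < 1e-6))
  expect_gt(pc$p_adjusted[!scz_rows], 0.05)
  # two-level input: the single contrast matches the group model
  two <- toy$diagnosis != "bipolar"
  pc2 <- posthoc_contrasts(y[two], toy[two, ], covariates = character(0),
                           site = "none")
  gs2 <- group_model(y[two], toy[two, ], covariates = character(0),
                     site = "none", contrast = "diagnosis")
  expect_equal(nrow(pc2), 1L)
  expect_equal(abs(pc2$beta), abs(gs2$beta), tolerance = 1e-8)
})

test_that("dependent-correlation test matches the Williams formula oracle", {
  withr::with_seed(13, {
    n <- 100L
    z <- rnorm(n)
    a <- 0.5 * z + rnorm(n)
    b <- 0.3 * z + 0.4 * a + rnorm(n)
  })
  got <- dependent_correlation_test(z, a, b)
  # independently scripted oracle using the determinant of the correlation
  # matrix
  R <- stats::cor(cbind(z, a, b))
  r13 <- R[1, 2]; r23 <- R[1, 3]; r12 <- R[2, 3]
  rbar <- (r13 + r23) / 2
  t_oracle <- (r13 - r23) * sqrt(((n - 1) * (1 + r12)) /
    (2 * ((n - 1) / (n - 3)) * det(R) + rbar^2 * (1 - r12)^3))
  expect_equal(got$t, t_oracle, tolerance = 1e-10)
  expect_equal(got$df, n - 3)
  expect_equal(got$p, 2 * stats::pt(-abs(t_oracle), n - 3),
               tolerance = 1e-12)
})

test_that("identical or symmetric scores give a null dependent test", {
  withr::with_seed(14, { y <- rnorm(40); a <- rnorm(40) })
  same <- dependent_correlation_test(y, a, a, alternative = "greater")
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  # symmetrized toy: b is a mirrored copy with the same correlation to y
  y2 <- c(y, y); a2 <- c(a, rnorm(40)); b2 <- c(a2[41:80], a2[1:40])
  sym <- dependent_correlation_test(y2, a2, b2)
  expect_equal(sym$t, 0, tolerance = 1e-12)
  expect_error(dependent_correlation_test(y, rep(1, 40), a), "zero variance")
})

test_that("composite-vs-regional z comparison follows its affine definition", {
  withr::with_seed(15, roi <- rnorm(75))
  ctr <- smd_vs_roi_distribution(mean(abs(roi)), roi)
  expect_equal(ctr$z, 0, tolerance = 1e-12)
  expect_equal(ctr$p, 1, tolerance = 1e-12)
  two <- smd_vs_roi_distribution(mean(abs(roi)) + 2 * stats::sd(abs(roi)), roi)
  expect_equal(two$z, 2, tolerance = 1e-10)
  z <- (2.597 * stats::sd(abs(roi))) + mean(abs(roi))
  pz <- smd_vs_roi_distribution(z, roi)
  expect_equal(pz$p, 2 * stats::pnorm(-2.597), tolerance = 1e-6)
  expect_error(smd_vs_roi_distribution(1, rep(0.2, 75)), "zero spread")
})

test_that("analytic power matches the null, the published case and Monte Carlo", {
  expect_equal(power_two_sample_t(0, 30, 40, alpha = 0.05), 0.05,
               tolerance = 1e-6)
  expect_gt(power_two_sample_t(0.61, 47, 77, alpha = 0.05), 0.90)
  # Monte-Carlo oracle via the defining representation of the noncentral t
  d <- 0.5; n1 <- 50; n2 <- 50; df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  withr::with_seed(77, {
    tstat <- (rnorm(1e6) + ncp) / sqrt(rchisq(1e6, df) / df)
  })
  mc <- mean(abs(tstat) > stats::qt(0.975, df))
  expect_lt(abs(power_two_sample_t(0.5, 50, 50) - mc), 0.005)
  expect_error(power_two_sample_t(0.5, 1, 10), "n1")
})

test_that("profile correlation handles identity, reflection and stratification", {
  w <- synthetic_weights("scz")
  smds <- stats::setNames(w$theta, w$region)
  expect_equal(effect_profile_correlation(smds, w)$r, 1)
  expect_equal(effect_profile_correlation(-smds, w)$r, -1)
  # hand-computed Pearson on a toy profile
  withr::with_seed(19, v <- rnorm(75))
  names(v) <- w$region
  r_hand <- sum((v - mean(v)) * (w$theta - mean(w$theta))) /
    sqrt(sum((v - mean(v))^2) * sum((w$theta - mean(w$theta))^2))
  expect_equal(effect_profile_correlation(v, w)$r, r_hand,
               tolerance = 1e-12)
  strat <- effect_profile_correlation(smds, w, stratify_by_metric = TRUE)
  expect_equal(length(strat$by_class), 3L)
  expect_equal(unname(strat$by_class), rep(1, 3), tolerance = 1e-12)
})
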
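test_that("deconfounding residuals match hand-solved least squares", {
  tab <- make_toy_roi_table(12L, seed = 3)
  rt <- deconfound(tab)
  m <- attr(rt, "deconfound_model")
  # independent oracle: normal equations per metric class, first region each
  for (cl in c("thickness", "area", "volume")) {
    reg <- canonical_regions()$region[canonical_regions()$metric_class == cl][1]
    g <- switch(cl, thickness = tab$mean_thickness, area = tab$mean_area,
                volume = tab$icv)
    X <- cbind(1, tab$age, tab$sex, g)
    beta <- solve(t(X) %*% X, t(X) %*% tab[[reg]])
    raw_res <- tab[[reg]] - X %*% beta
    expect_equal(unname(m$coefficients[, reg]), unname(drop(beta)),
                 tolerance = 1e-10)
    expect_equal(rt[[reg]],
                 unname(drop((raw_res - mean(raw_res)) / stats::sd(raw_res))),
                 tolerance = 1e-10)
  }
  # fitting-population moments
  M <- region_matrix(rt)
  expect_lt(max(abs(colMeans(M))), 1e-8)
  expect_lt(max(abs(apply(M, 2, stats::sd) - 1)), 1e-8)
})

test_that("deconfounding leaves covariate-orthogonal values centered", {
  tab <- make_toy_roi_table(20L, seed = 9)
  # orthogonalize one region against the design so OLS has nothing to absorb
  reg <- "fusiform_thickness"
  X <- cbind(1, tab$age, tab$sex, tab$mean_thickness)
  v <- region_matrix(tab)[, reg]
  v_orth <- drop(v - X %*% solve(t(X) %*% X, t(X) %*% v)) + mean(v)
  tab[[reg]] <- v_orth
  rt <- deconfound(tab)
  expect_equal(rt[[reg]], as.numeric(scale(v_orth - mean(v_orth))),
               tolerance = 1e-8)
})

test_that("deconfounding is idempotent on its own residuals", {
  tab <- make_toy_roi_table(15L, seed = 4)
  rt <- deconfound(tab)
  tab2 <- tab
  tab2[, canonical_regions()$region] <- as.data.frame(region_matrix(rt))
  rt2 <- deconfound(tab2)
  expect_lt(max(abs(region_matrix(rt2) - region_matrix(rt))), 1e-8)
})

test_that("the fitted transform reapplies exactly to new data", {
  tab <- make_toy_roi_table(30L, seed = 5)
  rt <- deconfound(tab)
  again <- apply_deconfound(rt, tab)
  expect_equal(region_matrix(again), region_matrix(rt), tolerance = 1e-12)
  # controls-only fitting population changes the norm, not the contract
  rtc <- deconfound(tab, fit_population = "controls")
  ctrl <- tab$diagnosis == "control"
  Mc <- region_matrix(rtc)[ctrl, ]
  expect_lt(max(abs(colMeans(Mc))), 1e-8)
})

test_that("single-site harmonization is the identity with a warning", {
  tab <- make_toy_roi_table(10L)
  rt <- deconfound(tab)
  expect_warning(cb <- combat_adjust(rt), "single site")
  expect_equal(region_matrix(cb$residuals), region_matrix(rt),
               tolerance = 1e-10)
  expect_identical(cb$model$mode, "identity")
})

test_that("a pure additive site shift is removed exactly", {
  # deterministic toy: balanced within-site pattern, identical across
  # regions, so EB shrinkage is exact and site means equalize to 0
  pat <- rep(c(-0.001, 0.001), 5)
  df <- data.frame(subject_id = paste0("s", 1:20), diagnosis = "control",
                   site = rep(c("A", "B"), each = 10),
                   r1 = c(pat, 2 + pat), r2 = c(pat, 2 + pat),
                   r3 = c(pat, 2 + pat))
  cb <- combat_adjust(df)
  m <- mrscore:::.value_matrix(cb$residuals)
  gap <- abs(colMeans(m[1:10, ]) - colMeans(m[11:20, ]))
  expect_lt(max(gap), 1e-6)
  # grand mean and pooled variance preserved on this balanced toy
  expect_lt(max(abs(colMeans(m) - 1)), 1e-6)
})

test_that("parametric EB matches an independently scripted oracle", {
  withr::with_seed(21, {
    n1 <- 14L; n2 <- 10L
    Y <- rbind(matrix(rnorm(n1 * 3), n1), matrix(rnorm(n2 * 3, 1, 1.5), n2))
  })
  df <- data.frame(subject_id = paste0("s", 1:24), diagnosis = "control",
                   site = rep(c("A", "B"), c(14L, 10L)))
  df[, c("g1", "g2", "g3")] <- Y
  cb <- combat_adjust(df, tol = 1e-12)

  # step-by-step oracle: standardize -> LS batch effects -> moment-matched
  # priors -> conditional shrinkage iterated to convergence -> adjust
  batch <- rep(1:2, c(14L, 10L)); ns <- c(14L, 10L); n <- 24L
  Bhat <- rbind(colMeans(Y[batch == 1, ]), colMeans(Y[batch == 2, ]))
  grand <- (ns[1] * Bhat[1, ] + ns[2] * Bhat[2, ]) / n
  vpool <- colMeans((Y - Bhat[batch, ])^2)
  Z <- sweep(sweep(Y, 2, grand), 2, sqrt(vpool), "/")
  ghat <- rbind(colMeans(Z[batch == 1, ]), colMeans(Z[batch == 2, ]))
  dhat <- rbind(apply(Z[batch == 1, ], 2, var), apply(Z[batch == 2, ], 2, var))
  adj_oracle <- Z
  for (s in 1:2) {
    gbar <- mean(ghat[s, ]); t2 <- var(ghat[s, ])
    m <- mean(dhat[s, ]); s2 <- var(dhat[s, ])
    a <- (2 * s2 + m^2) / s2; b <- (m * s2 + m^3) / s2
    g <- ghat[s, ]; d <- dhat[s, ]
    for (i in 1:5000) {
      g_new <- (ns[s] * t2 * ghat[s, ] + d * gbar) / (ns[s] * t2 + d)
      d_new <- (0.5 * colSums(sweep(Z[batch == s, ], 2, g_new)^2) + b) /
        (ns[s] / 2 + a - 1)
      if (max(abs(c(g_new - g, d_new - d))) < 1e-14) { g <- g_new; d <- d_new; break }
      g <- g_new; d <- d_new
    }
    adj_oracle[batch == s, ] <- sweep(sweep(Z[batch == s, ], 2, g), 2,
                                      sqrt(d), "/")
    expect_equal(unname(cb$model$gamma_star[s, ]), unname(g),
                 tolerance = 1e-6)
    expect_equal(unname(cb$model$delta_star[s, ]), unname(d),
                 tolerance = 1e-6)
  }
  adj_oracle <- sweep(sweep(adj_oracle, 2, sqrt(vpool), "*"), 2, grand, "+")
  expect_equal(unname(mrscore:::.value_matrix(cb$residuals)),
               unname(adj_oracle), tolerance = 1e-6)
})

test_that("harmonization matches the reference implementation on a cohort", {
  skip_if_not_installed("sva")
  coh <- simulate_cohort(emulate_table1("discovery", seed = 11))
  rt <- deconfound(coh$table)
  cb <- combat_adjust(rt)
  ref <- suppressMessages(
    sva::ComBat(dat = t(region_matrix(rt)), batch = factor(rt$site)))
  expect_lt(max(abs(t(ref) - region_matrix(cb$residuals))), 1e-4)
})

test_that("injected site effects no longer drive region-on-site ANOVA", {
  hits <- vapply(1:10, function(i) {
    coh <- simulate_cohort(emulate_table1("discovery", seed = 400 + i))
    cb <- combat_adjust(deconfound(coh$table))
    M <- region_matrix(cb$residuals)
    p <- apply(M, 2, function(v)
      summary(stats::aov(v ~ factor(cb$residuals$site)))[[1]][1, "Pr(>F)"])
    sum(p < 0.05 / 75)
  }, numeric(1))
  expect_lte(sum(hits > 0), 1)
})

test_that("combat errors on degenerate sites", {
  tab <- make_toy_roi_table(9L, sites = c(rep("A", 8), "B"))
  rt <- deconfound(tab)
  expect_error(combat_adjust(rt), "fewer than 2")
  df <- data.frame(subject_id = paste0("s", 1:8), diagnosis = "control",
                   site = rep(c("A", "B"), each = 4),
                   r1 = c(rep(1, 4), rnorm(4)), r2 = rnorm(8))
  expect_error(combat_adjust(df), "zero within-site variance")
})
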
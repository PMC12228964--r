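test_that("contrast vectors encode time powers and covariate profiles", {
  fit <- quick_fit(n = 50, seed = 6, fixed_degree = 2, random_degree = 1)
  expect_equal(unname(contrast_vector(fit, 2)), c(1, 2, 4))

  fitg <- quick_fit(n = 60, seed = 7, fixed_degree = 2, random_degree = 1,
                    group = list(prevalence = 0.5, coef = c(0.4, 0.1, 0, 0)))
  cc <- contrast_vector(fitg, 5)                         # reference level
  expect_equal(unname(cc), c(1, 5, 25, 0, 0, 0))
  c1 <- contrast_vector(fitg, 5, profile = list(group = "1"))
  expect_equal(unname(c1), c(1, 5, 25, 1, 5, 25))
  expect_error(contrast_vector(fitg, 5, profile = list(group = "9")),
               "known levels")
})

test_that("predictions satisfy the delta-method identities", {
  fit <- quick_fit(n = 40, seed = 2, fixed_degree = 1, random_degree = 0)
  f2 <- inject_estimates(fit, beta = c(1, 2), Vbeta = diag(2))
  pr <- suppressWarnings(predict(f2, at = 3))
  expect_equal(pr$estimate, 7)                       # 1 + 2*3
  expect_equal(pr$se, sqrt(1 + 9), tolerance = 1e-12)
  expect_equal(pr$ci_low, 7 - qnorm(0.975) * sqrt(10), tolerance = 1e-12)
  expect_equal(pr$ci_high, 7 + qnorm(0.975) * sqrt(10), tolerance = 1e-12)

  expect_warning(predict(fit, at = fit$time_range[2] + 5), "extrapolation")
  expect_silent(predict(fit, at = mean(fit$time_range)))
})

test_that("trajectory grids are consistent with pointwise prediction", {
  fit <- quick_fit(n = 50, seed = 3, fixed_degree = 3, random_degree = 1)
  g2 <- trajectory_grid(fit, 4, 12, n_points = 2)
  expect_equal(g2$time, c(4, 12))
  expect_equal(g2$estimate,
               predict(fit, at = c(4, 12), warn_extrapolation = FALSE)$estimate)
  g <- trajectory_grid(fit, 4, 12, n_points = 25)
  expect_equal(nrow(g), 25L)
  expect_equal(g$time[c(1, 25)], c(4, 12))
  expect_error(trajectory_grid(fit, 5, 5), "less than")
  expect_error(trajectory_grid(fit, 4, 12, n_points = 1), "at least 2")
})

test_that("standard errors widen monotonically under extrapolation", {
  for (seed in 1:5) {
    fit <- quick_fit(n = 60, seed = seed, fixed_degree = 2, random_degree = 1)
    se_centre <- predict(fit, at = fit$encoding$fit_center)$se
    se_out <- suppressWarnings(predict(fit, at = fit$time_range[2] + 6))$se
    expect_gt(se_out, se_centre)
  }
})

test_that("analytic AUC reproduces hand-computed polynomial integrals", {
  f1 <- inject_estimates(quick_fit(n = 40, seed = 2, fixed_degree = 1,
                                   random_degree = 0),
                         beta = c(2, 3))
  expect_equal(traj_auc(f1, 0, 2)$estimate, 10, tolerance = 1e-12)

  f3 <- inject_estimates(quick_fit(n = 40, seed = 2, fixed_degree = 3,
                                   random_degree = 1),
                         beta = c(1, 1, -1, 0.5))
  expect_equal(traj_auc(f3, 0, 2)$estimate, 10 / 3, tolerance = 1e-12)
})

test_that("AUC equals numerical quadrature of the predicted curve", {
  fit <- quick_fit(n = 60, seed = 4, fixed_degree = 3, random_degree = 2)
  a <- traj_auc(fit, 3, 10)
  quad <- integrate(function(t) {
    vapply(t, function(ti) predict(fit, at = ti,
                                   warn_extrapolation = FALSE)$estimate,
           numeric(1))
  }, 3, 10, rel.tol = 1e-12)
  expect_equal(a$estimate, quad$value, tolerance = 1e-9)
})

test_that("AUC is additive, homogeneous and symmetric in its pieces", {
  fit <- quick_fit(n = 60, seed = 5, fixed_degree = 3, random_degree = 1)
  a_ab <- traj_auc(fit, 3, 7); a_bc <- traj_auc(fit, 7, 12)
  a_ac <- traj_auc(fit, 3, 12)
  expect_equal(a_ac$estimate, a_ab$estimate + a_bc$estimate, tolerance = 1e-12)
  expect_equal(attr(a_ac, "weights"),
               attr(a_ab, "weights") + attr(a_bc, "weights"), tolerance = 1e-12)
  f2 <- inject_estimates(fit, beta = 2 * fit$beta)
  expect_equal(traj_auc(f2, 3, 12)$estimate, 2 * a_ac$estimate,
               tolerance = 1e-12)
  expect_error(traj_auc(fit, 7, 7), "less than")
})

test_that("group differences use the full covariance and are antisymmetric", {
  fitg <- quick_fit(n = 120, seed = 11, fixed_degree = 3, random_degree = 2,
                    group = list(prevalence = 0.5,
                                 coef = c(0.5, 0.08, -0.01, 0)))
  d_ab <- difference_at_time(fitg, 9, c("1", "0"))
  d_ba <- difference_at_time(fitg, 9, c("0", "1"))
  expect_equal(d_ab$estimate, -d_ba$estimate, tolerance = 1e-15)
  expect_equal(d_ab$se, d_ba$se, tolerance = 1e-15)

  p1 <- predict(fitg, at = 9, profile = list(group = "1"))
  p0 <- predict(fitg, at = 9, profile = list(group = "0"))
  expect_equal(d_ab$estimate, p1$estimate - p0$estimate, tolerance = 1e-12)
  # the groupwise standard errors do not combine by themselves: the correct
  # se comes from the full covariance through the difference contrast
  cc <- attr(d_ab, "contrast")
  expect_equal(d_ab$se, sqrt(drop(cc %*% vcov(fitg) %*% cc)), tolerance = 1e-12)

  # zero interaction coefficients give a zero difference, with uncertainty
  # from the interaction block alone
  z <- fitg
  ib <- startsWith(z$block, "int:")
  z <- inject_estimates(z, beta = replace(z$beta, ib, 0))
  expect_equal(difference_at_time(z, 9, c("1", "0"))$estimate, 0)

  fit0 <- quick_fit(n = 40, seed = 2, fixed_degree = 1, random_degree = 0)
  expect_error(difference_at_time(fit0, 9, c("1", "0")), "interaction")
})

test_that("AUC differences equal the difference of groupwise AUCs exactly", {
  fitg <- quick_fit(n = 100, seed = 13, fixed_degree = 2, random_degree = 1,
                    group = list(prevalence = 0.4, coef = c(0.6, 0.05, 0, 0)))
  ad <- auc_difference(fitg, 4, 12, c("1", "0"))
  a1 <- traj_auc(fitg, 4, 12, profile = list(group = "1"))
  a0 <- traj_auc(fitg, 4, 12, profile = list(group = "0"))
  expect_equal(ad$estimate, a1$estimate - a0$estimate, tolerance = 1e-12)
  z <- inject_estimates(fitg,
                        beta = replace(fitg$beta, startsWith(fitg$block, "int:"), 0))
  expect_equal(auc_difference(z, 4, 12, c("1", "0"))$estimate, 0)
})

test_that("the parametric bootstrap is seeded, degenerate-safe and consistent", {
  fit <- quick_fit(n = 60, seed = 14, fixed_degree = 2, random_degree = 1)
  cc <- contrast_vector(fit, 8)
  b1 <- boot_ci(fit, cc, n_draws = 500, seed = 99)
  b2 <- boot_ci(fit, cc, n_draws = 500, seed = 99)
  expect_identical(b1, b2)
  expect_error(boot_ci(fit, cc, n_draws = 50), "at least 100")

  # a zero contrast has zero variance: the interval collapses to the estimate
  b0 <- boot_ci(fit, rep(0, length(coef(fit))), n_draws = 200, seed = 1)
  expect_equal(unname(b0), c(0, 0), ignore_attr = TRUE)

  # large-sample convergence to the delta interval
  pr <- predict(fit, at = 8)
  bb <- boot_ci(fit, cc, n_draws = 50000, seed = 7)
  width_ratio <- (bb[["ci_high"]] - bb[["ci_low"]]) / (pr$ci_high - pr$ci_low)
  expect_gt(width_ratio, 0.95)
  expect_lt(width_ratio, 1.05)
})

test_that("models round-trip through the JSON artifact", {
  fitg <- quick_fit(n = 80, seed = 15, fixed_degree = 3, random_degree = 2,
                    group = list(prevalence = 0.5, coef = c(0.4, 0.06, 0, 0)))
  path <- tempfile(fileext = ".json")
  save_model(fitg, path)
  back <- load_model(path)
  expect_identical(back$term_names, fitg$term_names)
  expect_equal(back$beta, fitg$beta, tolerance = 1e-15)
  expect_equal(back$Vbeta, fitg$Vbeta, tolerance = 1e-15)
  expect_equal(back$G, fitg$G, tolerance = 1e-15)
  expect_equal(back$deviance, fitg$deviance, tolerance = 1e-15)

  # contrasts and inference rebuilt from the artifact equal the in-session ones
  for (t in c(4, 9.5, 13)) {
    expect_equal(contrast_vector(back, t, list(group = "1")),
                 contrast_vector(fitg, t, list(group = "1")), tolerance = 1e-15)
  }
  expect_equal(predict(back, at = 7)$se, predict(fitg, at = 7)$se,
               tolerance = 1e-14)
  expect_equal(auc_difference(back, 3, 10, c("1", "0")),
               auc_difference(fitg, 3, 10, c("1", "0")), tolerance = 1e-14,
               ignore_attr = TRUE)
})
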
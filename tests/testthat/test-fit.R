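test_that("noise-free linear data is recovered exactly with a flagged boundary fit", {
  d <- expand.grid(id = paste0("s", 1:4), occ = 1:4)
  d$t <- d$occ * 2
  d$y <- 3 + 0.5 * d$t                     # identical deterministic subjects
  fit <- suppressWarnings(trajlmm(d, "y", "t", "id",
                                  fixed_degree = 1, random_degree = 0))
  expect_equal(unname(coef(fit)), c(3, 0.5), tolerance = 1e-6)
  expect_true(fit$singular)
  expect_true(fit$sigma2 < 1e-6)
  expect_equal(unname(fitted(fit)), d$y[order(d$id)], tolerance = 1e-6)
})

test_that("balanced random-intercept ML matches the ANOVA closed form", {
  set.seed(42)
  for (rep in 1:5) {
    fit <- fit_intercept_only(m = sample(8:15, 1), k = sample(3:5, 1),
                              mu = 2, sd_b = 1.5, sd_e = 0.7)
    oracle <- balanced_anova_ml(fit$dm$y, fit$dm$subject)
    expect_equal(unname(fit$beta), oracle$mu, tolerance = 1e-6)
    expect_equal(fit$G[1, 1], oracle$sigma_b2, tolerance = 1e-5)
    expect_equal(fit$sigma2, oracle$sigma_e2, tolerance = 1e-5)
  }
})

test_that("ML deviance is non-increasing in the fixed polynomial degree", {
  for (seed in 1:6) {
    cfg <- quick_cfg(60, seed = seed)
    long <- reshape_wide_to_long(simulate_cohort(cfg)$data,
                                 trajlmm:::.sim_wide_spec(cfg))
    devs <- vapply(1:4, function(d) {
      deviance(suppressWarnings(trajlmm(long, "y", "age", "subject",
                                        fixed_degree = d, random_degree = 1)))
    }, numeric(1))
    expect_true(all(diff(devs) <= 1e-6))
  }
})

test_that("unit weights and absent weights give the same fit", {
  cfg <- quick_cfg(50, seed = 8)
  long <- reshape_wide_to_long(simulate_cohort(cfg)$data,
                               trajlmm:::.sim_wide_spec(cfg))
  long$w1 <- 1
  f0 <- suppressWarnings(trajlmm(long, "y", "age", "subject", 2, 1))
  f1 <- suppressWarnings(trajlmm(long, "y", "age", "subject", 2, 1,
                                 weights = "w1"))
  expect_lt(abs(deviance(f0) - deviance(f1)), 1e-8)
  expect_equal(coef(f0), coef(f1), tolerance = 1e-8)
})

test_that("every reported quantity is invariant to the time centring", {
  cfg <- quick_cfg(60, seed = 12, group = list(prevalence = 0.5,
                                               coef = c(0.3, 0.05, 0, 0)))
  long <- reshape_wide_to_long(simulate_cohort(cfg)$data,
                               trajlmm:::.sim_wide_spec(cfg))
  fits <- lapply(c(0, 8.5, NA), function(ctr) {
    suppressWarnings(trajlmm(long, "y", "age", "subject", 3, 2,
                             interaction = "group",
                             time_center = if (is.na(ctr)) NULL else ctr))
  })
  at <- c(4, 9, 13.5)
  base_pred <- predict(fits[[1]], at = at)
  base_auc <- traj_auc(fits[[1]], 3, 10)
  base_diff <- difference_at_time(fits[[1]], 9, c("1", "0"))
  for (f in fits[-1]) {
    p <- predict(f, at = at)
    expect_equal(p$estimate, base_pred$estimate, tolerance = 1e-8)
    expect_equal(p$se, base_pred$se, tolerance = 1e-6)
    a <- traj_auc(f, 3, 10)
    expect_equal(a$estimate, base_auc$estimate, tolerance = 1e-8)
    expect_equal(a$se, base_auc$se, tolerance = 1e-6)
    dd <- difference_at_time(f, 9, c("1", "0"))
    expect_equal(dd$estimate, base_diff$estimate, tolerance = 1e-8)
    # original-scale coefficients agree after the exact change of basis
    expect_equal(coef(f), coef(fits[[1]]), tolerance = 1e-6)
  }
})

test_that("the fixed-effects covariance equals the inverse GLS information", {
  fit <- quick_fit(n = 80, seed = 5, fixed_degree = 2, random_degree = 1)
  dm <- fit$dm
  q <- nrow(fit$G)
  Sxx <- matrix(0, dm$p, dm$p)
  for (s in levels(dm$subject)) {
    rows <- which(dm$subject == s)
    Zi <- outer(dm$time_c[rows], 0:(q - 1), `^`)
    Vi <- Zi %*% fit$G_centered %*% t(Zi) +
      fit$sigma2 * diag(1 / dm$w[rows], nrow = length(rows))
    Xi <- dm$X[rows, , drop = FALSE]
    Sxx <- Sxx + t(Xi) %*% solve(Vi, Xi)
  }
  V_oracle <- solve(Sxx)
  expect_lt(max(abs(vcov(fit, scale = "centered") - V_oracle)), 1e-8)
})

test_that("fits agree with the reference mixed-model implementation", {
  skip_if_not_installed("lme4")
  cfg <- quick_cfg(150, seed = 77)
  long <- reshape_wide_to_long(simulate_cohort(cfg)$data,
                               trajlmm:::.sim_wide_spec(cfg))
  fit <- suppressWarnings(trajlmm(long, "y", "age", "subject", 3, 2,
                                  control = list(rel_tol = 1e-12)))
  long$agec <- long$age - fit$encoding$fit_center
  lmer_quiet <- function(...) {
    suppressWarnings(suppressMessages(lme4::lmer(...)))
  }
  lf <- lmer_quiet(y ~ agec + I(agec^2) + I(agec^3) +
                     (1 + agec + I(agec^2) | subject),
                   data = long, REML = FALSE)
  # both optimisers stop near the same optimum of the same deviance surface
  expect_equal(deviance(fit), deviance(lf), tolerance = 1e-5)
  expect_equal(unname(coef(fit, scale = "centered")),
               unname(lme4::fixef(lf)), tolerance = 1e-3)
  expect_equal(fit$sigma2, lme4::getME(lf, "sigma")^2, tolerance = 1e-2)

  fitR <- suppressWarnings(trajlmm(long, "y", "age", "subject", 3, 2,
                                   estimator = "REML",
                                   control = list(rel_tol = 1e-12)))
  lfR <- lmer_quiet(y ~ agec + I(agec^2) + I(agec^3) +
                      (1 + agec + I(agec^2) | subject),
                    data = long, REML = TRUE)
  expect_equal(deviance(fitR), lme4::REMLcrit(lfR), tolerance = 1e-5)
})

test_that("effect tables satisfy their arithmetic identities", {
  fit <- quick_fit(n = 50, seed = 9, fixed_degree = 2, random_degree = 1)
  fe <- fixed_effects(fit)
  z975 <- qnorm(0.975)
  expect_equal(fe$ci_low, fe$estimate - z975 * fe$se, tolerance = 1e-12)
  expect_equal(fe$ci_high, fe$estimate + z975 * fe$se, tolerance = 1e-12)
  expect_equal(fe$z, fe$estimate / fe$se, tolerance = 1e-12)
  expect_equal(fe$p, 2 * (1 - pnorm(abs(fe$z))), tolerance = 1e-12)

  # one fixed example: estimate 2, se 1
  f2 <- inject_estimates(quick_fit(n = 40, seed = 2, fixed_degree = 1,
                                   random_degree = 0),
                         beta = c(2, 0), Vbeta = diag(c(1, 1e-12)))
  row <- fixed_effects(f2)[1, ]
  expect_equal(row$ci_low, 2 - qnorm(0.975), tolerance = 1e-9)
  expect_equal(row$ci_high, 2 + qnorm(0.975), tolerance = 1e-9)
  expect_equal(row$p, 2 * (1 - pnorm(2)), tolerance = 1e-9)

  # degenerate zero standard error
  f3 <- inject_estimates(f2, Vbeta = diag(c(0, 1)))
  expect_warning(fe3 <- fixed_effects(f3), "zero standard error")
  expect_true(is.na(fe3$z[1]) && is.na(fe3$p[1]))
})

test_that("random-effect summaries derive exactly from G and sigma2", {
  fit <- quick_fit(n = 50, seed = 10, fixed_degree = 2, random_degree = 1)
  re <- random_effects(fit)
  expect_equal(re$variances$variance[1:2], unname(diag(fit$G)))
  expect_equal(re$variances$variance[3], fit$sigma2)
  expect_equal(re$correlation[1, 2],
               fit$G[1, 2] / sqrt(fit$G[1, 1] * fit$G[2, 2]),
               tolerance = 1e-12)
  expect_true(all(abs(re$correlation[!is.na(re$correlation)]) <= 1 + 1e-12))

  # fixed example G = [[4,1],[1,1]]
  f2 <- quick_fit(n = 40, seed = 2, fixed_degree = 1, random_degree = 1)
  f2$G <- matrix(c(4, 1, 1, 1), 2, 2,
                 dimnames = dimnames(f2$G))
  re2 <- random_effects(f2)
  expect_equal(re2$variances$sd[1:2], c(2, 1))
  expect_equal(re2$correlation[1, 2], 0.5)

  f0 <- quick_fit(n = 40, seed = 2, fixed_degree = 1, random_degree = 0)
  expect_equal(nrow(random_effects(f0)$variances), 2L)  # intercept + residual
})

test_that("non-convergence raises a structured error with diagnostics", {
  cfg <- quick_cfg(40, seed = 3)
  long <- reshape_wide_to_long(simulate_cohort(cfg)$data,
                               trajlmm:::.sim_wide_spec(cfg))
  err <- tryCatch(
    suppressWarnings(trajlmm(long, "y", "age", "subject", 3, 2,
                             control = list(max_iter = 1))),
    trajlmm_convergence_error = function(e) e,
    error = function(e) e)
  if (inherits(err, "trajlmm_convergence_error")) {
    expect_match(conditionMessage(err), "failed to converge")
    expect_true(is.numeric(err$diagnostics$iterations))
  } else {
    # a 1-iteration budget may still satisfy the optimizer's own test on easy
    # data; in that case the fit must at least be a valid model object
    expect_s3_class(err, c("trajlmm", "error"))
  }
})

test_that("model summaries print without error", {
  fit <- quick_fit(n = 40, seed = 4, fixed_degree = 2, random_degree = 1)
  expect_output(print(fit), "growth-curve")
  expect_output(print(summary(fit)), "Fixed effects")
  expect_s3_class(formula(fit), "formula")
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), -deviance(fit) / 2)
  expect_equal(attr(ll, "df"), 3 + 3 + 1)
})
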
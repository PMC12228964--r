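test_that("BLUPs shrink to zero as the random-effect covariance vanishes", {
  fit <- quick_fit(n = 40, seed = 21, fixed_degree = 2, random_degree = 1)
  small <- fit
  small$G_centered <- fit$G_centered * 1e-10
  u <- subject_effects(small)
  expect_lt(max(abs(as.matrix(u[, c("u0", "u1")]))), 1e-6)
})

test_that("a subject lying exactly on the population curve has zero BLUP", {
  fit <- quick_fit(n = 40, seed = 22, fixed_degree = 2, random_degree = 1)
  # force one subject's outcomes onto the fitted population curve
  dm <- fit$dm
  s <- levels(dm$subject)[1]
  rows <- which(dm$subject == s)
  fit$dm$y[rows] <- drop(dm$X[rows, ] %*% fit$beta_centered)
  u <- subject_effects(fit)
  expect_equal(unname(unlist(u[u$subject == s, c("u0", "u1")])), c(0, 0),
               tolerance = 1e-10)
})

test_that("BLUPs maximise the per-subject conditional density", {
  fit <- quick_fit(n = 30, seed = 23, fixed_degree = 2, random_degree = 1)
  dm <- fit$dm
  G <- fit$G_centered
  Ginv <- solve(G)
  res <- dm$y - drop(dm$X %*% fit$beta_centered)
  u_pkg <- trajlmm:::.blups_centered(fit)
  some <- sample(seq_along(u_pkg$subjects), 5)
  for (i in some) {
    rows <- which(dm$subject == u_pkg$subjects[i])
    Zi <- outer(dm$time_c[rows], 0:1, `^`)
    negdens <- function(u) {
      e <- res[rows] - Zi %*% u
      sum(e^2) / (2 * fit$sigma2) + drop(t(u) %*% Ginv %*% u) / 2
    }
    opt <- optim(c(0, 0), negdens, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_equal(unname(u_pkg$u[i, ]), opt$par, tolerance = 1e-5)
  }
})

test_that("the mixed-model-equation identity holds at the fitted BLUPs", {
  fit <- quick_fit(n = 60, seed = 24, fixed_degree = 2, random_degree = 1)
  skip_if(fit$singular)
  dm <- fit$dm
  b <- trajlmm:::.blups_centered(fit)
  Ginv <- solve(fit$G_centered)
  res <- dm$y - drop(dm$X %*% fit$beta_centered)
  worst <- 0
  for (i in seq_along(b$subjects)) {
    rows <- which(dm$subject == b$subjects[i])
    Zi <- outer(dm$time_c[rows], 0:1, `^`)
    e <- res[rows] - drop(Zi %*% b$u[i, ])
    gap <- drop(t(Zi) %*% (dm$w[rows] * e)) / fit$sigma2 -
      drop(Ginv %*% b$u[i, ])
    worst <- max(worst, max(abs(gap)))
  }
  expect_lt(worst, 1e-6)
  # GLS score for the fixed effects is zero at the optimum
  score <- numeric(length(fit$beta))
  for (s in levels(dm$subject)) {
    rows <- which(dm$subject == s)
    Zi <- outer(dm$time_c[rows], 0:1, `^`)
    Vi <- Zi %*% fit$G_centered %*% t(Zi) +
      fit$sigma2 * diag(1 / dm$w[rows], nrow = length(rows))
    score <- score + drop(t(dm$X[rows, , drop = FALSE]) %*% solve(Vi, res[rows]))
  }
  expect_lt(max(abs(score)), 1e-4)
})

test_that("individual curves decompose into population plus random polynomial", {
  fit <- quick_fit(n = 50, seed = 25, fixed_degree = 3, random_degree = 2)
  u <- subject_effects(fit)
  cur <- individual_curves(fit, subjects = u$subject[3], n_points = 11)
  ui <- unlist(u[3, c("u0", "u1", "u2")])
  dev_expected <- ui[1] + ui[2] * cur$time + ui[3] * cur$time^2
  expect_equal(cur$individual - cur$population, unname(dev_expected),
               tolerance = 1e-10)
  # observed points carried through unmodified
  obs <- cur[!is.na(cur$observed), ]
  rows <- which(fit$dm$subject == u$subject[3])
  expect_equal(sort(obs$observed), sort(fit$dm$y[rows]))
  expect_equal(sort(obs$time), sort(fit$dm$time_raw[rows]))
  # default grid stays inside the subject's own observed range
  expect_gte(min(cur$time), min(fit$dm$time_raw[rows]))
  expect_lte(max(cur$time), max(fit$dm$time_raw[rows]))
  expect_error(individual_curves(fit, subjects = "nobody"), "unknown subject")
})

test_that("random-intercept-only curves are a constant offset from the population", {
  fit <- quick_fit(n = 40, seed = 26, fixed_degree = 2, random_degree = 0)
  cur <- individual_curves(fit, subjects = levels(fit$dm$subject)[1:2],
                           n_points = 7)
  for (s in unique(cur$subject)) {
    off <- cur$individual[cur$subject == s] - cur$population[cur$subject == s]
    expect_lt(diff(range(off)), 1e-10)
  }
})

test_that("averaging individual curves over subjects approaches the population curve", {
  fit <- quick_fit(n = 300, seed = 27, fixed_degree = 2, random_degree = 1)
  grid <- c(5, 8, 11)
  cur <- individual_curves(fit, grid = grid)
  cur <- cur[is.na(cur$observed), ]
  for (t in grid) {
    ind <- cur$individual[cur$time == t]
    pop <- cur$population[cur$time == t][1]
    # subject effects average to ~0 across n subjects: 3 MC SEs
    expect_lt(abs(mean(ind) - pop), 3 * sd(ind) / sqrt(length(ind)))
  }
})

test_that("individual subsampling is seeded, clamped and group-aware", {
  fitg <- quick_fit(n = 80, seed = 28, fixed_degree = 2, random_degree = 1,
                    group = list(prevalence = 0.5, coef = c(0.5, 0.05, 0, 0)))
  s1 <- sample_individuals(fitg, n = 10, seed = 5)
  s2 <- sample_individuals(fitg, n = 10, seed = 5)
  expect_identical(attr(s1, "subjects"), attr(s2, "subjects"))
  expect_length(attr(s1, "subjects"), 10L)

  expect_message(all10 <- sample_individuals(fitg, n = 1000),
                 "returning all")
  expect_length(attr(all10, "subjects"), fitg$n_subjects)

  g1 <- sample_individuals(fitg, n = 8, group = "1", seed = 3)
  ids <- attr(g1, "subjects")
  first <- vapply(trajlmm:::.subject_index(fitg$dm)[ids], `[[`, numeric(1), 1L)
  expect_true(all(fitg$dm$frame$group[first] == 1))

  s3 <- sample_individuals(fitg, subjects = ids[1:3])
  expect_identical(attr(s3, "subjects"), ids[1:3])

  # seeded draws are close to uniform over subjects
  counts <- table(unlist(lapply(1:300, function(s)
    attr(sample_individuals(fitg, n = 10, seed = s, n_points = 2), "subjects"))))
  p <- 10 / fitg$n_subjects
  bound <- 3 * sqrt(300 * p * (1 - p))
  expect_true(all(abs(counts - 300 * p) < bound + 10))
})

test_that("BLUPs never exceed the per-subject least-squares deviation", {
  fit <- quick_fit(n = 60, seed = 29, fixed_degree = 2, random_degree = 0)
  st <- shrinkage_table(fit)
  ok <- !is.na(st$ols_0)
  expect_true(all(abs(st$blup_0[ok]) <= abs(st$ols_0[ok]) + 1e-10))
  expect_true(all(st$ratio_0[ok] >= -1e-10 & st$ratio_0[ok] <= 1 + 1e-10))
})

test_that("single-observation subjects keep a BLUP but no OLS estimate", {
  cfg <- quick_cfg(40, seed = 30)
  wide <- simulate_cohort(cfg)$data
  # strip subject 1 down to one occasion
  for (j in 2:5) {
    wide[1, paste0("age_t", j)] <- NA
    wide[1, paste0("y_t", j)] <- NA
  }
  long <- reshape_wide_to_long(wide, trajlmm:::.sim_wide_spec(cfg))
  fit <- suppressWarnings(trajlmm(long, "y", "age", "subject", 2, 1))
  st <- shrinkage_table(fit)
  row <- st[st$subject == "S00001", ]
  expect_equal(row$n_obs_used, 1L)
  expect_true(is.na(row$ols_0) && is.na(row$ols_1))
  expect_true(is.finite(row$blup_0))
})

test_that("BLUPs from a reloaded artifact match the fitting session", {
  fit <- quick_fit(n = 50, seed = 31, fixed_degree = 2, random_degree = 1)
  cfg <- quick_cfg(50, seed = 31)
  long <- reshape_wide_to_long(simulate_cohort(cfg)$data,
                               trajlmm:::.sim_wide_spec(cfg))
  path <- tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path, data = long)
  expect_equal(subject_effects(back), subject_effects(fit), tolerance = 1e-12)
})
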
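# Independent oracles and fixture builders. Everything here is deliberately
# written from first principles (dense linear algebra, closed forms), not via
# the package's own computational path.

# Stacked-dense multivariate-normal log-likelihood oracle: builds the full
# n x n block-diagonal covariance for the whole dataset and evaluates the
# Gaussian log-density directly.
dense_loglik <- function(dm, beta, G, sigma2, estimator = "ML") {
  n <- dm$n_obs
  q <- nrow(as.matrix(G))
  V <- matrix(0, n, n)
  for (s in levels(dm$subject)) {
    rows <- which(dm$subject == s)
    Zi <- outer(dm$time_c[rows], 0:(q - 1L), `^`)
    V[rows, rows] <- Zi %*% G %*% t(Zi) +
      sigma2 * diag(1 / dm$w[rows], nrow = length(rows))
  }
  r <- dm$y - dm$X %*% beta
  ld <- determinant(V, logarithm = TRUE)$modulus[1]
  ll <- -0.5 * (n * log(2 * pi) + ld + drop(t(r) %*% solve(V, r)))
  if (estimator == "REML") {
    Sxx <- t(dm$X) %*% solve(V, dm$X)
    beta_gls <- solve(Sxx, t(dm$X) %*% solve(V, dm$y))
    r2 <- dm$y - dm$X %*% beta_gls
    ll <- -0.5 * (n * log(2 * pi) + ld + drop(t(r2) %*% solve(V, r2))) +
      0.5 * ncol(dm$X) * log(2 * pi) -
      0.5 * determinant(Sxx, logarithm = TRUE)$modulus[1]
  }
  ll
}

# Closed-form ML estimates for the balanced one-way random-intercept layout
# (m subjects, k observations each, no slope): with
# W = sum (y_ij - ybar_i)^2 and B = k sum (ybar_i - ybar)^2, the deviance
# separates as (N-m) log se2 + m log(lambda) + W/se2 + B/lambda with
# lambda = se2 + k sb2, giving mu = ybar, se2 = W/(N-m), lambda = B/m when the
# implied sb2 is nonnegative; otherwise the constrained maximum sits on the
# boundary sb2 = 0 with se2 = (W + B)/N.
balanced_anova_ml <- function(y, subject) {
  ybar_i <- tapply(y, subject, mean)
  k <- as.integer(table(subject)[1])
  m <- length(ybar_i)
  N <- m * k
  ybar <- mean(y)
  W <- sum((y - ybar_i[as.character(subject)])^2)
  B <- k * sum((ybar_i - ybar)^2)
  se2 <- W / (N - m)
  lambda <- B / m
  if (lambda >= se2) {
    list(mu = ybar, sigma_e2 = se2, sigma_b2 = (lambda - se2) / k,
         boundary = FALSE)
  } else {
    list(mu = ybar, sigma_e2 = (W + B) / N, sigma_b2 = 0, boundary = TRUE)
  }
}

# Balanced one-way layout fitted with an intercept-only fixed part and a
# random intercept, through the internal fitter (the user-facing family
# starts at a linear fixed term, which would not nest the ANOVA model).
fit_intercept_only <- function(m, k, mu, sd_b, sd_e,
                               ctrl = list(rel_tol = 1e-12, max_iter = 500L,
                                           polish = TRUE)) {
  b <- stats::rnorm(m, sd = sd_b)
  d <- expand.grid(id = seq_len(m), occ = seq_len(k))
  d$t <- d$occ
  d$y <- mu + b[d$id] + stats::rnorm(nrow(d), sd = sd_e)
  dm <- trajlmm:::build_design(
    d, trajlmm:::traj_model_spec("y", "t", "id", 1, 0, time_center = 0))
  dm$X <- dm$X[, 1, drop = FALSE]
  dm$p <- 1L
  dm$term_names <- "(Intercept)"
  dm$block <- "poly"
  dm$spec$fixed_degree <- 0L   # internal only: makes the basis transform 1x1
  suppressWarnings(trajlmm:::.fit_lmm(dm, ctrl))
}

# small random long dataset (optionally with weights) for likelihood checks
random_long <- function(seed, n_subj = NULL, weights = FALSE) {
  set.seed(seed)
  if (is.null(n_subj)) n_subj <- sample(3:8, 1)
  rows <- lapply(seq_len(n_subj), function(i) {
    ni <- sample(1:5, 1)
    data.frame(id = paste0("s", i),
               t = round(stats::runif(ni, 0, 10), 2),
               y = round(stats::rnorm(ni, 2, 1.5), 3),
               w = if (weights) round(stats::runif(ni, 0.5, 2), 3) else 1)
  })
  do.call(rbind, rows)
}

# small simulated cohort config for fast fits
quick_cfg <- function(n = 120, seed = NULL, group = NULL, missing = NULL) {
  sim_config(n_subjects = n,
             occasions = data.frame(nominal_age = c(3, 5, 7, 11, 14),
                                    jitter_sd = 0.25),
             beta_true = c(2.2, -0.35, 0.045, -0.0013),
             sigma2_true = 0.49,
             group = group, missing = missing, seed = seed)
}

# simulate + reshape + fit in one go
quick_fit <- function(n = 120, seed = 1, fixed_degree = 3, random_degree = 2,
                      group = NULL, estimator = "ML", ...) {
  cfg <- quick_cfg(n, seed = seed, group = group)
  long <- reshape_wide_to_long(simulate_cohort(cfg)$data,
                               trajlmm:::.sim_wide_spec(cfg))
  suppressWarnings(trajlmm(long, "y", "age", "subject",
                           fixed_degree = fixed_degree,
                           random_degree = random_degree,
                           interaction = if (!is.null(group)) "group",
                           estimator = estimator, ...))
}

# overwrite the estimates of a fitted model with chosen values (for exercising
# contrast/interval arithmetic at known parameters)
inject_estimates <- function(fm, beta = NULL, Vbeta = NULL) {
  if (!is.null(beta)) {
    stopifnot(length(beta) == length(fm$beta))
    fm$beta <- stats::setNames(beta, fm$term_names)
  }
  if (!is.null(Vbeta)) fm$Vbeta <- Vbeta
  fm
}
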
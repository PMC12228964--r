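# Synthetic longitudinal cohorts with known ground truth, for testing and
# parameter-recovery studies.

#' Configuration for the synthetic cohort generator
#'
#' Describes the data-generating process: subject-level polynomial
#' trajectories with correlated random intercept/slope deviations, Gaussian
#' residual noise, per-occasion age jitter, and optionally a binary group
#' effect and missingness.
#'
#' The defaults emulate a five-occasion childhood/adolescence cohort measured
#' at nominal ages 3, 5, 7, 11 and 14 (ages jittered per subject-occasion,
#' sd 0.25), with a cubic mean trend on a 0-10 symptom-score scale, random
#' intercept, linear and quadratic terms, and residual sd 0.7.
#'
#' @param n_subjects Number of subjects.
#' @param occasions Data frame with columns `nominal_age` and `jitter_sd`
#'   (one row per occasion, at least 2).
#' @param beta_true Fixed polynomial coefficients on the original age scale
#'   (length = degree + 1).
#' @param G_true Random-effect covariance matrix (`q x q`, positive
#'   semidefinite, on the original age scale).
#' @param sigma2_true Residual variance (> 0).
#' @param group Optional list `list(prevalence =, coef =)`: binary group with
#'   the given prevalence whose members' mean coefficients are
#'   `beta_true + coef` (`coef[1]` is the main effect, `coef[d+1]` the
#'   interaction with `age^d`).
#' @param missing Optional list `list(mcar_rate =, dropout_hazard =)`:
#'   missing-completely-at-random deletion of each (age, outcome) occasion
#'   pair (scalar or per-occasion vector), and/or per-occasion dropout hazard
#'   (monotone missingness from the second occasion onward).
#' @param seed Default seed used by [simulate_cohort()].
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 500,
                       occasions = data.frame(nominal_age = c(3, 5, 7, 11, 14),
                                              jitter_sd = 0.25),
                       beta_true = c(2.2, -0.35, 0.045, -0.0013),
                       G_true = default_G_true(),
                       sigma2_true = 0.49,
                       group = NULL, missing = NULL, seed = NULL) {
  stopifnot(n_subjects >= 2, nrow(occasions) >= 2,
            all(c("nominal_age", "jitter_sd") %in% names(occasions)),
            all(occasions$jitter_sd >= 0), sigma2_true > 0)
  G_true <- as.matrix(G_true)
  if (max(abs(G_true - t(G_true))) > 1e-12) stop("G_true must be symmetric", call. = FALSE)
  ev <- eigen(G_true, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("G_true must be positive semidefinite", call. = FALSE)
  }
  if (nrow(G_true) > length(beta_true)) {
    stop("random-effect degree cannot exceed the fixed polynomial degree", call. = FALSE)
  }
  if (!is.null(group)) {
    stopifnot(is.list(group), group$prevalence > 0, group$prevalence < 1,
              length(group$coef) == length(beta_true))
  }
  if (!is.null(missing)) {
    missing <- modifyList(list(mcar_rate = 0, dropout_hazard = 0), missing)
    stopifnot(all(missing$mcar_rate >= 0), all(missing$mcar_rate <= 1),
              all(missing$dropout_hazard >= 0), all(missing$dropout_hazard <= 1))
  }
  structure(list(n_subjects = n_subjects, occasions = occasions,
                 beta_true = beta_true, G_true = G_true,
                 sigma2_true = sigma2_true, group = group,
                 missing = missing, seed = seed),
            class = "sim_config")
}

#' Default random-effect covariance for the synthetic cohort
#'
#' Random intercept/linear/quadratic sds 0.9, 0.10 and 0.008 on the raw age
#' scale with correlations -0.4 (intercept-linear), 0.1
#' (intercept-quadratic) and -0.5 (linear-quadratic).
#'
#' @return A 3 x 3 covariance matrix.
#' @export
default_G_true <- function() {
  s <- c(0.9, 0.10, 0.008)
  R <- matrix(c(1, -0.4, 0.1,
                -0.4, 1, -0.5,
                0.1, -0.5, 1), 3, 3)
  diag(s) %*% R %*% diag(s)
}

#' Simulate a wide-format synthetic cohort
#'
#' Generates, for subject `i` at occasion `j`:
#' `age_ij = nominal_age_j + N(0, jitter_sd_j^2)` and
#' `y_ij = sum_d (beta_d + group_i * gamma_d) age_ij^d
#'        + sum_{d<q} u_id age_ij^d + eps_ij`,
#' with `u_i ~ N(0, G_true)`, `eps_ij ~ N(0, sigma2_true)` and
#' `group_i ~ Bernoulli(prevalence)`. Column layout is wide: `subject`,
#' `age_t1..age_tk`, `y_t1..y_tk` and (if configured) `group`.
#' Missingness is *not* applied here; see [apply_missingness()].
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (default `cfg$seed`); the same seed reproduces
#'   the table bit for bit.
#' @return A list with `data` (wide data frame) and `truth` (the generating
#'   parameters).
#' @export
simulate_cohort <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_subjects
  k <- nrow(cfg$occasions)
  q <- nrow(cfg$G_true)
  d <- length(cfg$beta_true) - 1L

  u <- MASS::mvrnorm(n, mu = rep(0, q), Sigma = cfg$G_true)
  if (n == 1L) u <- matrix(u, nrow = 1L)
  ages <- matrix(rep(cfg$occasions$nominal_age, each = n), n, k) +
    matrix(stats::rnorm(n * k, sd = rep(cfg$occasions$jitter_sd, each = n)), n, k)
  grp <- if (!is.null(cfg$group)) stats::rbinom(n, 1L, cfg$group$prevalence)

  y <- matrix(0, n, k)
  for (j in seq_len(k)) {
    P <- outer(ages[, j], 0:d, `^`)               # n x (d+1)
    mu <- drop(P %*% cfg$beta_true)
    if (!is.null(grp)) mu <- mu + grp * drop(P %*% cfg$group$coef)
    re <- rowSums(P[, 1:q, drop = FALSE] * u)
    y[, j] <- mu + re + stats::rnorm(n, sd = sqrt(cfg$sigma2_true))
  }

  out <- data.frame(subject = sprintf("S%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) out[[paste0("age_t", j)]] <- ages[, j]
  for (j in seq_len(k)) out[[paste0("y_t", j)]] <- y[, j]
  if (!is.null(grp)) out$group <- grp
  list(data = out,
       truth = list(beta = cfg$beta_true, G = cfg$G_true,
                    sigma2 = cfg$sigma2_true,
                    group_coef = if (!is.null(cfg$group)) cfg$group$coef,
                    u = u))
}

#' Apply missingness to a wide synthetic cohort
#'
#' Two mechanisms, both seeded: MCAR deletes each (age, outcome) occasion
#' cell pair independently with probability `mcar_rate`; dropout removes all
#' occasions from `j` onward once a subject drops at occasion `j`
#' (per-occasion hazard, evaluated from the second occasion).
#'
#' @param wide Wide data frame from [simulate_cohort()].
#' @param cfg A [sim_config()] whose `missing` component holds the rates.
#' @param seed Optional integer seed.
#' @return The wide data frame with `NA` cells.
#' @export
apply_missingness <- function(wide, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$missing)) return(wide)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(wide)
  k <- nrow(cfg$occasions)
  mcar <- rep(cfg$missing$mcar_rate, length.out = k)   # scalar or per-occasion
  miss <- matrix(stats::runif(n * k), n, k) <
    matrix(mcar, n, k, byrow = TRUE)
  hz <- rep(cfg$missing$dropout_hazard, length.out = k)
  if (any(hz > 0) && k >= 2L) {
    dropped <- rep(FALSE, n)
    for (j in 2:k) {
      dropped <- dropped | (stats::runif(n) < hz[j])
      miss[, j] <- miss[, j] | dropped
    }
  }
  for (j in seq_len(k)) {
    wide[[paste0("age_t", j)]][miss[, j]] <- NA_real_
    wide[[paste0("y_t", j)]][miss[, j]] <- NA_real_
  }
  wide
}

# wide_spec matching simulate_cohort's column layout
.sim_wide_spec <- function(cfg) {
  k <- nrow(cfg$occasions)
  wide_spec("subject", paste0("age_t", seq_len(k)), paste0("y_t", seq_len(k)),
            occasion_name = "occ", outcome_name = "y", age_name = "age")
}

#' Parameter-recovery simulation study
#'
#' Repeatedly simulates a cohort from `cfg`, reshapes it to long format, fits
#' the growth-curve model, and aggregates estimates against the generating
#' truth: mean estimate, bias, empirical standard error, the Monte-Carlo
#' standard error of the bias, and coverage of the nominal-level confidence
#' intervals. Replicates whose fit fails to converge are recorded, not fatal.
#'
#' @param cfg A [sim_config()].
#' @param n_replicates Number of replicates.
#' @param fixed_degree,random_degree Model to fit (defaults: the generating
#'   degrees).
#' @param estimator `"ML"` or `"REML"`.
#' @param level Confidence level for coverage.
#' @param auc_range Optional length-2 vector: also track the trajectory AUC
#'   over this range (reference group), whose analytic truth is the integral
#'   of the generating polynomial.
#' @param seed Integer seed; replicate `r` uses `seed + r`.
#' @return A data frame with one row per parameter (`parameter`, `true`,
#'   `mean_estimate`, `bias`, `empirical_se`, `mc_se`, `coverage`), with
#'   attributes `n_replicates`, `n_converged` and `convergence_rate`.
#' @export
recovery_study <- function(cfg, n_replicates = 200,
                           fixed_degree = length(cfg$beta_true) - 1L,
                           random_degree = nrow(cfg$G_true) - 1L,
                           estimator = "ML", level = 0.95,
                           auc_range = NULL, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"), fixed_degree >= length(cfg$beta_true) - 1L)
  sp <- .sim_wide_spec(cfg)
  has_group <- !is.null(cfg$group)

  est_list <- list(); cover_list <- list()
  auc_est <- numeric(0); auc_cover <- logical(0)
  n_fail <- 0L
  for (r in seq_len(n_replicates)) {
    sim <- simulate_cohort(cfg, seed = seed + r)
    wide <- apply_missingness(sim$data, cfg, seed = seed + r)
    long <- reshape_wide_to_long(wide, sp)
    fit <- tryCatch(
      suppressWarnings(trajlmm(long, outcome = "y", time = "age",
                               subject = "subject",
                               fixed_degree = fixed_degree,
                               random_degree = random_degree,
                               interaction = if (has_group) "group",
                               estimator = estimator)),
      error = function(e) NULL)
    if (is.null(fit)) { n_fail <- n_fail + 1L; next }
    fe <- fixed_effects(fit, level = level)
    est_list[[length(est_list) + 1L]] <- stats::setNames(fe$estimate, fe$term)
    truth <- .truth_vector(cfg, fit$term_names)
    cover_list[[length(cover_list) + 1L]] <-
      fe$ci_low <= truth & truth <= fe$ci_high
    if (!is.null(auc_range)) {
      a <- traj_auc(fit, auc_range[1], auc_range[2], level = level)
      auc_est <- c(auc_est, a$estimate)
      auc_cover <- c(auc_cover, a$ci_low <= .auc_truth(cfg, auc_range) &
                       .auc_truth(cfg, auc_range) <= a$ci_high)
    }
  }
  if (length(est_list) == 0L) stop("no replicate converged", call. = FALSE)

  E <- do.call(rbind, est_list)
  Cv <- do.call(rbind, cover_list)
  truth <- .truth_vector(cfg, colnames(E))
  R <- nrow(E)
  out <- data.frame(parameter = colnames(E),
                    true = unname(truth),
                    mean_estimate = colMeans(E),
                    bias = colMeans(E) - unname(truth),
                    empirical_se = apply(E, 2, stats::sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$mc_se <- out$empirical_se / sqrt(R)
  out$coverage <- colMeans(Cv)
  if (!is.null(auc_range)) {
    out <- rbind(out, data.frame(
      parameter = sprintf("AUC[%g,%g]", auc_range[1], auc_range[2]),
      true = .auc_truth(cfg, auc_range),
      mean_estimate = mean(auc_est),
      bias = mean(auc_est) - .auc_truth(cfg, auc_range),
      empirical_se = stats::sd(auc_est),
      mc_se = stats::sd(auc_est) / sqrt(R),
      coverage = mean(auc_cover)))
  }
  attr(out, "n_replicates") <- n_replicates
  attr(out, "n_converged") <- R
  attr(out, "convergence_rate") <- R / n_replicates
  out
}

# generating truth for each fitted term name
.truth_vector <- function(cfg, terms) {
  d <- length(cfg$beta_true) - 1L
  poly_names <- c("(Intercept)", "age", if (d >= 2) sprintf("I(age^%d)", 2:d))
  truth <- stats::setNames(rep(NA_real_, length(terms)), terms)
  truth[poly_names] <- cfg$beta_true
  if (!is.null(cfg$group)) {
    truth[c("group1", paste0("group1:", poly_names[-1]))] <- cfg$group$coef
  }
  if (anyNA(truth)) {
    stop("no generating truth for term(s): ",
         paste(terms[is.na(truth)], collapse = ", "), call. = FALSE)
  }
  truth
}

# analytic AUC of the generating mean polynomial (reference group)
.auc_truth <- function(cfg, range) {
  d <- length(cfg$beta_true) - 1L
  sum(cfg$beta_true * (range[2]^(1:(d + 1)) - range[1]^(1:(d + 1))) / (1:(d + 1)))
}
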
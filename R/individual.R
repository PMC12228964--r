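# Individual-level trajectories: BLUPs (conditional modes), predicted vs
# observed curves, and reproducible subsamples of individual curves.

# BLUPs on the centred basis: u_i = G Z_i' V_i^{-1} (y_i - X_i beta),
# V_i = Z_i G Z_i' + sigma2 * diag(1/w_i). Valid for singular G.
.blups_centered <- function(fm) {
  dm <- fm$dm
  q <- nrow(fm$G)
  G <- fm$G_centered
  idx <- .subject_index(dm)
  res <- dm$y - drop(dm$X %*% fm$beta_centered)
  out <- matrix(NA_real_, length(idx), q)
  n_used <- integer(length(idx))
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    Zi <- .Z_of(dm$time_c[rows], q)
    Vi <- Zi %*% G %*% t(Zi) +
      fm$sigma2 * diag(1 / dm$w[rows], nrow = length(rows))
    out[i, ] <- drop(G %*% t(Zi) %*% solve(Vi, res[rows]))
    n_used[i] <- length(rows)
  }
  list(u = out, n_used = n_used, subjects = names(idx))
}

#' Subject-level random-effect estimates (BLUPs)
#'
#' The conditional mode (equivalently, mean) of each subject's random effects
#' given the data and the fitted parameters — the best linear unbiased
#' predictor. Reported on the original time scale: `u0` is the subject's
#' deviation in intercept, `u1` in the linear term, and so on. Subjects with
#' no modelled rows are absent.
#'
#' @param fm A fitted [trajlmm()] model.
#' @return A data frame with columns `subject`, `n_obs_used` and `u0`, ...,
#'   `u{q-1}`.
#' @export
subject_effects <- function(fm) {
  stopifnot(inherits(fm, "trajlmm"), fm$converged)
  b <- .blups_centered(fm)
  q <- ncol(b$u)
  Ar <- .basis_transform(q - 1L, fm$encoding$fit_center)
  u_raw <- b$u %*% Ar          # u_raw = t(Ar) %*% u_c, rowwise
  out <- data.frame(subject = b$subjects, n_obs_used = b$n_used,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (k in seq_len(q)) out[[paste0("u", k - 1L)]] <- u_raw[, k]
  out
}

# covariate profile implied by a subject's own observed covariate values
.subject_profile <- function(fm, rows) {
  enc <- fm$encoding
  prof <- list()
  fr <- fm$dm$frame
  for (v in names(enc$covariates)) prof[[v]] <- fr[[v]][rows[1L]]
  if (!is.null(enc$interaction)) {
    v <- enc$interaction$name
    prof[[v]] <- fr[[v]][rows[1L]]
  }
  prof
}

#' Individual predicted trajectories
#'
#' For each requested subject, evaluates the population curve (at the
#' subject's own covariate values) and the individual curve
#' (population plus the subject's random-effect polynomial) over a time grid,
#' and carries the subject's observed points through unmodified. The default
#' grid spans each subject's own observed time range, so individual curves
#' are never extrapolated.
#'
#' @param fm A fitted [trajlmm()] model.
#' @param subjects Character vector of subject identifiers (default: all).
#' @param grid Optional numeric vector of times common to all subjects;
#'   default is `n_points` evenly spaced times over each subject's own range.
#' @param n_points Grid size per subject when `grid` is `NULL`.
#' @return A long data frame with columns `subject`, `time`, `population`,
#'   `individual`, `observed` (`NA` except at observed times, which are
#'   appended to the grid).
#' @export
individual_curves <- function(fm, subjects = NULL, grid = NULL, n_points = 25) {
  stopifnot(inherits(fm, "trajlmm"), fm$converged)
  dm <- fm$dm
  idx <- .subject_index(dm)
  if (is.null(subjects)) subjects <- names(idx)
  unknown <- setdiff(subjects, names(idx))
  if (length(unknown) > 0L) {
    stop("unknown subject(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  b <- .blups_centered(fm)
  q <- ncol(b$u)
  p <- length(fm$beta)
  pieces <- lapply(subjects, function(s) {
    rows <- idx[[s]]
    tt <- if (is.null(grid)) {
      rng <- range(dm$time_raw[rows])
      if (diff(rng) > 0) seq(rng[1], rng[2], length.out = n_points) else rng[1]
    } else grid
    prof <- .subject_profile(fm, rows)
    C <- t(vapply(tt, function(t) contrast_vector(fm, t, prof), numeric(p)))
    pop <- drop(C %*% fm$beta)
    u_c <- b$u[match(s, b$subjects), ]
    dev <- drop(.Z_of(tt - fm$encoding$fit_center, q) %*% u_c)
    obs_t <- dm$time_raw[rows]
    C_obs <- t(vapply(obs_t, function(t) contrast_vector(fm, t, prof), numeric(p)))
    pop_obs <- drop(C_obs %*% fm$beta)
    dev_obs <- drop(.Z_of(obs_t - fm$encoding$fit_center, q) %*% u_c)
    data.frame(subject = s,
               time = c(tt, obs_t),
               population = c(pop, pop_obs),
               individual = c(pop + dev, pop_obs + dev_obs),
               observed = c(rep(NA_real_, length(tt)), dm$y[rows]),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Random subsample of individual trajectories
#'
#' Draws up to `n` subjects (default 30) without replacement — overall, or
#' within one level of the interaction variable — and returns their
#' individual curves. Sampling is seeded and reproducible (R's Mersenne
#' Twister; the seed is recorded in the output attributes). If the pool has
#' fewer than `n` subjects, all are returned with a message. An explicit
#' `subjects` vector bypasses sampling.
#'
#' @param fm A fitted [trajlmm()] model.
#' @param n Maximum number of subjects (default 30).
#' @param group Optional interaction-variable level to subsample within.
#' @param subjects Optional explicit subject identifiers (bypasses sampling).
#' @param seed Optional integer seed.
#' @param ... Passed to [individual_curves()].
#' @return As [individual_curves()], with attributes `"subjects"` and
#'   `"seed"`.
#' @export
sample_individuals <- function(fm, n = 30, group = NULL, subjects = NULL,
                               seed = NULL, ...) {
  stopifnot(inherits(fm, "trajlmm"), n >= 1)
  dm <- fm$dm
  idx <- .subject_index(dm)
  if (is.null(subjects)) {
    pool <- names(idx)
    if (!is.null(group)) {
      v <- .require_interaction(fm)
      first <- vapply(idx, `[[`, numeric(1), 1L)
      vals <- as.character(dm$frame[[v]][first])
      pool <- pool[vals == as.character(group)]
      if (length(pool) == 0L) {
        stop("no subjects with ", v, " = ", group, call. = FALSE)
      }
    }
    if (length(pool) <= n) {
      if (length(pool) < n) {
        message("only ", length(pool), " subjects available; returning all")
      }
      subjects <- pool
    } else {
      if (!is.null(seed)) set.seed(seed)
      subjects <- sample(pool, n)
    }
  }
  out <- individual_curves(fm, subjects = subjects, ...)
  attr(out, "subjects") <- subjects
  attr(out, "seed") <- seed
  out
}

#' Shrinkage of subject effects relative to per-subject least squares
#'
#' Compares each subject's BLUP with the unpooled ordinary-least-squares
#' estimate of the same deviation (regressing the subject's residuals from
#' the population curve on the random-effect polynomial basis). BLUPs are
#' shrunken towards zero; the ratio approaches 1 as a subject contributes
#' more observations. Subjects with fewer observations than random-effect
#' terms have `NA` in the OLS columns but keep their BLUP.
#'
#' @param fm A fitted [trajlmm()] model.
#' @return A data frame with columns `subject`, `n_obs_used`, then per
#'   random-effect component `blup_k`, `ols_k`, `ratio_k` (BLUP / OLS).
#' @export
shrinkage_table <- function(fm) {
  stopifnot(inherits(fm, "trajlmm"), fm$converged)
  dm <- fm$dm
  idx <- .subject_index(dm)
  b <- .blups_centered(fm)
  q <- ncol(b$u)
  Ar <- .basis_transform(q - 1L, fm$encoding$fit_center)
  u_raw <- b$u %*% Ar
  res <- dm$y - drop(dm$X %*% fm$beta_centered)
  out <- data.frame(subject = b$subjects, n_obs_used = b$n_used,
                    row.names = NULL, stringsAsFactors = FALSE)
  ols <- matrix(NA_real_, length(idx), q)
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    if (length(rows) >= q) {
      Zi <- .Z_of(dm$time_c[rows], q)
      fit_i <- tryCatch(stats::lm.wfit(Zi, res[rows], dm$w[rows]),
                        error = function(e) NULL)
      if (!is.null(fit_i) && fit_i$rank == q) {
        ols[i, ] <- drop(t(Ar) %*% fit_i$coefficients) # original time scale
      }
    }
  }
  for (k in seq_len(q)) {
    out[[paste0("blup_", k - 1L)]] <- u_raw[, k]
    out[[paste0("ols_", k - 1L)]] <- ols[, k]
    out[[paste0("ratio_", k - 1L)]] <- ifelse(ols[, k] != 0,
                                              u_raw[, k] / ols[, k], NA_real_)
  }
  out
}
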
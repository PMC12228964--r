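# Delta-method inference for trajectory quantities. Every quantity here is a
# linear contrast c'beta with exact variance c' V c, V = Var(beta_hat);
# confidence intervals are Wald intervals with the normal quantile.

.z975 <- function(level) stats::qnorm((1 + level) / 2)

# Resolve the encoded value of each design column at time t under a covariate
# profile. `poly_fun(k)` supplies the entry for a polynomial column of power k
# (t^k for predictions, the integral of t^k for AUCs), so the same machinery
# serves both.
.contrast_build <- function(fm, poly_fun, profile = list()) {
  enc <- fm$encoding
  d <- fm$spec$fixed_degree
  out <- numeric(length(fm$term_names))
  names(out) <- fm$term_names
  out[1:(d + 1L)] <- vapply(0:d, poly_fun, numeric(1))

  pos <- d + 1L
  for (v in names(enc$covariates)) {
    info <- enc$covariates[[v]]
    if (info$kind == "continuous") {
      pos <- pos + 1L
      val <- if (!is.null(profile[[v]])) as.numeric(profile[[v]]) else info$mean
      out[pos] <- val * poly_fun(0)   # constant column scales like the intercept
    } else {
      lev <- if (!is.null(profile[[v]])) as.character(profile[[v]]) else info$levels[1]
      if (!lev %in% info$levels) {
        stop("unknown level '", lev, "' for '", v, "'; known levels: ",
             paste(info$levels, collapse = ", "), call. = FALSE)
      }
      for (l in info$levels[-1L]) {
        pos <- pos + 1L
        out[pos] <- as.numeric(lev == l) * poly_fun(0)
      }
    }
  }

  if (!is.null(enc$interaction)) {
    v <- enc$interaction$name
    if (enc$interaction$kind == "continuous") {
      code <- if (!is.null(profile[[v]])) {
        (as.numeric(profile[[v]]) - enc$interaction$mean) / enc$interaction$sd
      } else 0
      out[pos + 1:(d + 1L)] <- code * vapply(0:d, poly_fun, numeric(1))
      pos <- pos + d + 1L
    } else {
      levs <- enc$interaction$levels
      lev <- if (!is.null(profile[[v]])) as.character(profile[[v]]) else levs[1]
      if (!lev %in% levs) {
        stop("unknown level '", lev, "' for '", v, "'; known levels: ",
             paste(levs, collapse = ", "), call. = FALSE)
      }
      for (l in levs[-1L]) {
        out[pos + 1:(d + 1L)] <- as.numeric(lev == l) * vapply(0:d, poly_fun, numeric(1))
        pos <- pos + d + 1L
      }
    }
  }
  out
}

#' Contrast vector for a prediction at a given time
#'
#' Builds the linear-contrast vector `c` such that the model-predicted mean at
#' time `t` under the covariate profile is `c' beta`. Polynomial entries are
#' `1, t, t^2, ...` (original time scale); covariates take their profile value
#' (default: fit-sample mean for continuous, reference level for categorical,
#' as recorded at fit time); interaction entries are the group code times the
#' matching polynomial entry.
#'
#' @param fm A fitted [trajlmm()] model.
#' @param t Time at which to predict.
#' @param profile Named list of covariate/interaction values
#'   (e.g. `list(female = "1")`).
#' @return Numeric vector of length `length(coef(fm))`.
#' @export
contrast_vector <- function(fm, t, profile = list()) {
  stopifnot(inherits(fm, "trajlmm"))
  .contrast_build(fm, function(k) t^k, profile)
}

# warn (once per call) when predicting outside the observed time range
.check_extrapolation <- function(fm, t, warn = TRUE) {
  out <- t < fm$time_range[1] | t > fm$time_range[2]
  if (warn && any(out)) {
    warning("prediction at time(s) outside the observed range [",
            format(fm$time_range[1]), ", ", format(fm$time_range[2]),
            "] is an extrapolation", call. = FALSE)
  }
  out
}

#' Predict the trajectory at given times
#'
#' Model-predicted mean outcome at each requested time with delta-method
#' standard errors and Wald confidence intervals. Times outside the observed
#' range are allowed but flagged as extrapolations with a warning.
#'
#' @param object A fitted [trajlmm()] model.
#' @param at Numeric vector of times.
#' @param profile Named list of covariate/interaction values (defaults:
#'   continuous covariates at their fit-sample mean, categorical variables at
#'   their reference level).
#' @param level Confidence level (default 0.95).
#' @param warn_extrapolation Emit a warning for out-of-range times?
#' @param ... Unused.
#' @return A data frame with columns `time`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `extrapolated`; the contrast matrix is attached as attribute
#'   `"contrasts"` (one row per time).
#' @export
predict.trajlmm <- function(object, at, profile = list(), level = 0.95,
                            warn_extrapolation = TRUE, ...) {
  stopifnot(object$converged, is.numeric(at), length(at) >= 1L)
  C <- t(vapply(at, function(t) contrast_vector(object, t, profile),
                numeric(length(object$beta))))
  est <- drop(C %*% object$beta)
  se <- sqrt(pmax(rowSums((C %*% object$Vbeta) * C), 0))
  zq <- .z975(level)
  extra <- .check_extrapolation(object, at, warn_extrapolation)
  out <- data.frame(time = at, estimate = est, se = se,
                    ci_low = est - zq * se, ci_high = est + zq * se,
                    extrapolated = extra, row.names = NULL)
  attr(out, "contrasts") <- C
  out
}

#' Evenly spaced trajectory predictions
#'
#' Predictions on an evenly spaced grid of `n_points` times from `from` to
#' `to` inclusive, for one covariate profile.
#'
#' @param fm A fitted [trajlmm()] model.
#' @param from,to Grid endpoints (`from < to`).
#' @param n_points Number of grid points (at least 2).
#' @param profile,level,warn_extrapolation As in [predict.trajlmm()].
#' @return As [predict.trajlmm()].
#' @export
trajectory_grid <- function(fm, from, to, n_points = 101, profile = list(),
                            level = 0.95, warn_extrapolation = FALSE) {
  if (!(from < to)) stop("'from' must be less than 'to'", call. = FALSE)
  if (n_points < 2) stop("n_points must be at least 2", call. = FALSE)
  predict(fm, at = seq(from, to, length.out = n_points), profile = profile,
          level = level, warn_extrapolation = warn_extrapolation)
}

# weight vector whose inner product with beta is the integral of the predicted
# mean over [a, b]
.auc_weights <- function(fm, a, b, profile = list()) {
  .contrast_build(fm, function(k) (b^(k + 1) - a^(k + 1)) / (k + 1), profile)
}

#' Area under the fitted trajectory
#'
#' The integral of the model-predicted mean outcome over `[from, to]` — the
#' cumulative "exposure" to the outcome over that period. Because the fitted
#' mean is polynomial, the integral is an exact linear contrast `w' beta`
#' (polynomial column of power `k` contributes
#' `(to^(k+1) - from^(k+1)) / (k+1)`; constant columns contribute their encoded
#' value times `to - from`), with delta-method variance `w' V w`. The AUC is
#' signed: negative outcomes integrate negatively.
#'
#' @param fm A fitted [trajlmm()] model.
#' @param from,to Integration bounds (`from < to`).
#' @param profile Covariate profile as in [predict.trajlmm()].
#' @param level Confidence level.
#' @return A one-row data frame with columns `from`, `to`, `estimate`, `se`,
#'   `ci_low`, `ci_high`; the weight vector is attached as attribute
#'   `"weights"`.
#' @export
traj_auc <- function(fm, from, to, profile = list(), level = 0.95) {
  stopifnot(inherits(fm, "trajlmm"), fm$converged)
  if (!(from < to)) stop("'from' must be less than 'to'", call. = FALSE)
  w <- .auc_weights(fm, from, to, profile)
  est <- sum(w * fm$beta)
  se <- sqrt(max(drop(w %*% fm$Vbeta %*% w), 0))
  zq <- .z975(level)
  out <- data.frame(from = from, to = to, estimate = est, se = se,
                    ci_low = est - zq * se, ci_high = est + zq * se,
                    row.names = NULL)
  attr(out, "weights") <- w
  out
}

.require_interaction <- function(fm) {
  if (is.null(fm$encoding$interaction)) {
    stop("this model has no interaction variable; refit with `interaction =` ",
         "to compare groups", call. = FALSE)
  }
  fm$encoding$interaction$name
}

#' Group difference in the trajectory at a given time
#'
#' Difference in the model-predicted mean at time `at` between two levels (or
#' two values, for a continuous interaction variable) of the interaction
#' variable: contrast `c(level_a) - c(level_b)`, in which all non-interaction
#' covariate entries cancel. Standard errors use the full covariance of the
#' estimates — they are not obtained by subtracting the two groupwise
#' standard errors.
#'
#' @param fm A fitted [trajlmm()] model with an interaction variable.
#' @param at Time of comparison.
#' @param levels Length-2 vector: the two interaction levels/values compared
#'   (`levels[1]` minus `levels[2]`).
#' @param profile Additional covariate profile values.
#' @param level Confidence level.
#' @return A one-row data frame (`time`, `estimate`, `se`, `ci_low`,
#'   `ci_high`) with the contrast as attribute `"contrast"`.
#' @export
difference_at_time <- function(fm, at, levels, profile = list(), level = 0.95) {
  v <- .require_interaction(fm)
  stopifnot(length(levels) == 2L, length(at) == 1L)
  pa <- pb <- profile
  pa[[v]] <- levels[1]; pb[[v]] <- levels[2]
  cc <- contrast_vector(fm, at, pa) - contrast_vector(fm, at, pb)
  est <- sum(cc * fm$beta)
  se <- sqrt(max(drop(cc %*% fm$Vbeta %*% cc), 0))
  zq <- .z975(level)
  out <- data.frame(time = at, estimate = est, se = se,
                    ci_low = est - zq * se, ci_high = est + zq * se,
                    row.names = NULL)
  attr(out, "contrast") <- cc
  out
}

#' Group difference in the area under the curve
#'
#' Difference in trajectory AUC over `[from, to]` between two levels of the
#' interaction variable, with delta-method confidence interval. Exactly equals
#' `traj_auc(level_a) - traj_auc(level_b)` in estimate.
#'
#' @inheritParams difference_at_time
#' @param from,to Integration bounds.
#' @return A one-row data frame (`from`, `to`, `estimate`, `se`, `ci_low`,
#'   `ci_high`) with the weight vector as attribute `"weights"`.
#' @export
auc_difference <- function(fm, from, to, levels, profile = list(), level = 0.95) {
  v <- .require_interaction(fm)
  stopifnot(length(levels) == 2L)
  if (!(from < to)) stop("'from' must be less than 'to'", call. = FALSE)
  pa <- pb <- profile
  pa[[v]] <- levels[1]; pb[[v]] <- levels[2]
  w <- .auc_weights(fm, from, to, pa) - .auc_weights(fm, from, to, pb)
  est <- sum(w * fm$beta)
  se <- sqrt(max(drop(w %*% fm$Vbeta %*% w), 0))
  zq <- .z975(level)
  out <- data.frame(from = from, to = to, estimate = est, se = se,
                    ci_low = est - zq * se, ci_high = est + zq * se,
                    row.names = NULL)
  attr(out, "weights") <- w
  out
}

#' Parametric-bootstrap percentile interval for a linear contrast
#'
#' Draws `n_draws` fixed-effect vectors from `N(beta_hat, V)` and returns the
#' percentile interval of `c' beta*`. Intended as a check on (and alternative
#' to) the delta-method Wald interval, to which it converges as `n_draws`
#' grows.
#'
#' @param fm A fitted [trajlmm()] model.
#' @param contrast Numeric contrast/weight vector of length `length(coef(fm))`
#'   (e.g. from [contrast_vector()] or the `"weights"` attribute of
#'   [traj_auc()]).
#' @param n_draws Number of draws (at least 100).
#' @param seed Optional integer seed; the same seed reproduces the interval.
#' @param level Confidence level.
#' @return Named numeric vector `c(ci_low, ci_high)` with attribute
#'   `"estimate"`.
#' @export
boot_ci <- function(fm, contrast, n_draws = 2000, seed = NULL, level = 0.95) {
  stopifnot(inherits(fm, "trajlmm"), length(contrast) == length(fm$beta))
  if (n_draws < 100) stop("n_draws must be at least 100", call. = FALSE)
  ev <- eigen(fm$Vbeta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("covariance of the fixed effects is not positive semidefinite",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- MASS::mvrnorm(n_draws, mu = fm$beta, Sigma = fm$Vbeta, tol = 1e-6)
  vals <- drop(draws %*% contrast)
  qs <- stats::quantile(vals, c((1 - level) / 2, (1 + level) / 2), names = FALSE)
  structure(c(ci_low = qs[1], ci_high = qs[2]),
            estimate = sum(contrast * fm$beta))
}
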
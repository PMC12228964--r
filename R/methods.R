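# S3 methods and effect tables for fitted growth-curve models.

#' Table of fixed effects with Wald intervals
#'
#' One row per fixed-effect term: estimate, standard error, Wald `z`,
#' two-sided normal p-value, and a confidence interval
#' `estimate +/- qnorm((1 + level)/2) * se`. A zero standard error yields
#' missing `z` and `p` with a warning.
#'
#' @param fm A fitted [trajlmm()] model.
#' @param level Confidence level (default 0.95).
#' @param scale `"original"` (default) or `"centered"` time basis.
#' @return A data frame with columns `term`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `z`, `p`.
#' @export
fixed_effects <- function(fm, level = 0.95, scale = c("original", "centered")) {
  stopifnot(inherits(fm, "trajlmm"), fm$converged)
  scale <- match.arg(scale)
  b <- coef(fm, scale = scale)
  V <- vcov(fm, scale = scale)
  se <- sqrt(pmax(diag(V), 0))
  zq <- stats::qnorm((1 + level) / 2)
  z <- ifelse(se > 0, b / se, NA_real_)
  if (any(se == 0)) {
    warning("zero standard error for term(s): ",
            paste(fm$term_names[se == 0], collapse = ", "), call. = FALSE)
  }
  data.frame(term = fm$term_names,
             estimate = unname(b),
             se = se,
             ci_low = unname(b) - zq * se,
             ci_high = unname(b) + zq * se,
             z = z,
             p = 2 * stats::pnorm(-abs(z)),
             row.names = NULL)
}

#' Random-effect variance components
#'
#' Variances, standard deviations, covariances and correlations of the random
#' intercept/slope terms (on the original time scale), plus the residual
#' variance. Correlations are derived exactly from the covariance matrix.
#'
#' @param fm A fitted [trajlmm()] model.
#' @return A list with `variances` (data frame of term, variance, sd, with the
#'   residual as the last row), `covariance` (the `q x q` matrix `G`) and
#'   `correlation` (its correlation matrix; `NA` where a variance is zero).
#' @export
random_effects <- function(fm) {
  stopifnot(inherits(fm, "trajlmm"), fm$converged)
  G <- fm$G
  v <- diag(G)
  s <- sqrt(pmax(v, 0))
  corr <- matrix(NA_real_, nrow(G), ncol(G), dimnames = dimnames(G))
  nz <- s > 0
  if (any(nz)) {
    corr[nz, nz] <- G[nz, nz, drop = FALSE] / tcrossprod(s[nz])
  }
  diag(corr)[nz] <- 1
  vars <- data.frame(term = c(rownames(G), "Residual"),
                     variance = c(unname(v), fm$sigma2),
                     sd = c(unname(s), sqrt(fm$sigma2)),
                     row.names = NULL)
  list(variances = vars, covariance = G, correlation = corr)
}

#' @export
print.trajlmm <- function(x, digits = 4, ...) {
  cat("Polynomial growth-curve linear mixed model (", x$estimator, ")\n", sep = "")
  cat("Formula: ", formula_string(x), "\n", sep = "")
  cat("Observations: ", x$n_obs, ";  subjects: ", x$n_subjects,
      ";  rows dropped (incomplete): ", x$n_dropped, "\n", sep = "")
  cat("Deviance: ", format(x$deviance, digits = digits + 2), "\n\n", sep = "")
  cat("Fixed effects:\n")
  fe <- fixed_effects(x)
  print(data.frame(estimate = signif(fe$estimate, digits),
                   se = signif(fe$se, digits),
                   row.names = fe$term))
  re <- random_effects(x)
  cat("\nRandom-effect standard deviations:\n")
  print(stats::setNames(signif(re$variances$sd, digits), re$variances$term))
  if (x$singular) cat("\nNote: fit is singular (a variance component is zero).\n")
  invisible(x)
}

#' @export
summary.trajlmm <- function(object, level = 0.95, ...) {
  out <- list(formula = formula_string(object),
              estimator = object$estimator,
              n_obs = object$n_obs, n_subjects = object$n_subjects,
              n_dropped = object$n_dropped,
              fixed = fixed_effects(object, level = level),
              random = random_effects(object),
              deviance = object$deviance, loglik = object$loglik,
              singular = object$singular, level = level)
  class(out) <- "summary.trajlmm"
  out
}

#' @export
print.summary.trajlmm <- function(x, digits = 4, ...) {
  cat("Formula: ", x$formula, "\n", sep = "")
  cat("Estimator: ", x$estimator, ";  deviance: ",
      format(x$deviance, digits = digits + 2), "\n", sep = "")
  cat("Observations: ", x$n_obs, ";  subjects: ", x$n_subjects,
      ";  rows dropped (incomplete): ", x$n_dropped, "\n\n", sep = "")
  cat("Fixed effects (", format(100 * x$level), "% CI):\n", sep = "")
  fe <- x$fixed
  fe[-1] <- lapply(fe[-1], signif, digits = digits)
  print(fe, row.names = FALSE)
  cat("\nRandom effects:\n")
  rv <- x$random$variances
  rv[-1] <- lapply(rv[-1], signif, digits = digits)
  print(rv, row.names = FALSE)
  if (nrow(x$random$covariance) > 1L) {
    cat("\nRandom-effect correlations:\n")
    print(signif(x$random$correlation, digits))
  }
  if (x$singular) cat("\nNote: fit is singular (a variance component is zero).\n")
  invisible(x)
}

# centred display basis: the basis centred at encoding$time_center (which is
# the internal fitting centre unless the user chose another)
.centered_view <- function(object) {
  enc <- object$encoding
  if (isTRUE(all.equal(enc$time_center, enc$fit_center))) {
    return(list(beta = object$beta_centered, V = object$Vbeta_centered))
  }
  Tm <- .coef_transform(object$block, object$spec$fixed_degree, enc$time_center)
  S <- solve(Tm)
  beta <- drop(S %*% object$beta)
  names(beta) <- object$term_names
  list(beta = beta, V = S %*% object$Vbeta %*% t(S))
}

#' @export
coef.trajlmm <- function(object, scale = c("original", "centered"), ...) {
  scale <- match.arg(scale)
  if (scale == "original") object$beta else .centered_view(object)$beta
}

#' @export
vcov.trajlmm <- function(object, scale = c("original", "centered"), ...) {
  scale <- match.arg(scale)
  if (scale == "original") object$Vbeta else .centered_view(object)$V
}

#' @export
logLik.trajlmm <- function(object, ...) {
  q <- nrow(object$G)
  structure(object$loglik,
            df = length(object$beta) + q * (q + 1) / 2 + 1,
            nobs = object$n_obs, class = "logLik")
}

#' @export
deviance.trajlmm <- function(object, ...) object$deviance

#' @export
nobs.trajlmm <- function(object, ...) object$n_obs

#' @export
formula.trajlmm <- function(x, ...) {
  stats::as.formula(formula_string(x), env = globalenv())
}

#' @export
fitted.trajlmm <- function(object, ...) {
  drop(object$dm$X %*% object$beta_centered)
}

#' @export
residuals.trajlmm <- function(object, type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  r <- object$dm$y - fitted(object)
  if (type == "conditional") {
    u <- subject_effects(object)
    q <- nrow(object$G)
    uc <- as.matrix(u[, paste0("u", 0:(q - 1L)), drop = FALSE])
    Z <- .Z_of(object$dm$time_raw, q)   # effects are on the original time scale
    key <- match(as.character(object$dm$subject), u$subject)
    r <- r - rowSums(Z * uc[key, , drop = FALSE])
  }
  r
}

#' Simulate outcomes from a fitted growth-curve model
#'
#' Draws new outcome vectors at the observed design: fresh random effects per
#' subject from `N(0, G)` and residuals from `N(0, sigma2 / w)`.
#'
#' @param object A fitted [trajlmm()] model.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns, rows aligned with the modelled
#'   rows (see `object$dm`).
#' @export
simulate.trajlmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dm <- object$dm
  q <- nrow(object$G)
  Z <- .Z_of(dm$time_c, q)
  mu <- fitted(object)
  m <- dm$n_subjects
  idx <- as.integer(dm$subject)
  out <- matrix(NA_real_, dm$n_obs, nsim)
  for (s in seq_len(nsim)) {
    U <- MASS::mvrnorm(m, mu = rep(0, q), Sigma = object$G_centered)
    eps <- stats::rnorm(dm$n_obs, sd = sqrt(object$sigma2 / dm$w))
    out[, s] <- mu + rowSums(Z * U[idx, , drop = FALSE]) + eps
  }
  stats::setNames(as.data.frame(out), paste0("sim_", seq_len(nsim)))
}

#' Plot a fitted trajectory with its confidence band
#'
#' Draws the model-predicted mean trajectory over the observed time range with
#' a pointwise 95% confidence band, optionally one curve per level of the
#' interaction variable, and optionally overlays observed per-occasion means
#' (as computed by [describe_by_occasion()]).
#'
#' @param x A fitted [trajlmm()] model.
#' @param from,to Time range (default: observed range).
#' @param n_points Grid size.
#' @param obs_means Optional data frame from [describe_by_occasion()] to
#'   overlay (`mean_time` vs `mean`).
#' @param level Confidence level.
#' @param ... Passed to [plot()].
#' @export
plot.trajlmm <- function(x, from = NULL, to = NULL, n_points = 101,
                         obs_means = NULL, level = 0.95, ...) {
  if (is.null(from)) from <- x$time_range[1]
  if (is.null(to)) to <- x$time_range[2]
  int <- x$encoding$interaction
  profiles <- list(list())
  labels <- "population"
  if (!is.null(int) && int$kind == "categorical") {
    profiles <- lapply(int$levels, function(l) stats::setNames(list(l), int$name))
    labels <- paste0(int$name, "=", int$levels)
  }
  grids <- lapply(profiles, function(pr)
    trajectory_grid(x, from, to, n_points, profile = pr, level = level))
  ylim <- range(unlist(lapply(grids, function(g) c(g$ci_low, g$ci_high))),
                if (!is.null(obs_means)) obs_means$mean, na.rm = TRUE)
  plot(NA, xlim = c(from, to), ylim = ylim,
       xlab = x$spec$time, ylab = x$spec$outcome, ...)
  for (i in seq_along(grids)) {
    g <- grids[[i]]
    graphics::polygon(c(g$time, rev(g$time)), c(g$ci_low, rev(g$ci_high)),
                      col = grDevices::adjustcolor(i, alpha.f = 0.2), border = NA)
    graphics::lines(g$time, g$estimate, col = i, lwd = 2)
  }
  if (!is.null(obs_means)) {
    graphics::points(obs_means$mean_time, obs_means$mean, pch = 19)
  }
  if (length(grids) > 1L) {
    graphics::legend("topleft", legend = labels, col = seq_along(grids),
                     lwd = 2, bty = "n")
  }
  invisible(x)
}
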
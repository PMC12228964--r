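# Marginal log-likelihood of the growth-curve LMM at explicit parameter values.

# split row indices by subject; rows are already subject-contiguous in a design
.subject_index <- function(dm) {
  idx <- split(seq_len(dm$n_obs), dm$subject)
  idx[lengths(idx) > 0L]
}

# random-effects design for one subject: columns 1, t_c, ..., t_c^(q-1)
.Z_of <- function(t_c, q) {
  outer(t_c, 0:(q - 1L), `^`)
}

#' Marginal log-likelihood at given parameters
#'
#' Evaluates the (restricted) log-likelihood of the growth-curve linear mixed
#' model at explicit parameter values: per subject the outcome vector is
#' multivariate normal with mean `X_i beta` and covariance
#' `Z_i G Z_i' + sigma2 * diag(1/w_i)`. For `estimator = "REML"` the value is
#' the restricted likelihood
#' `loglik(beta_gls) + (p/2) log(2 pi) - (1/2) log|X' V^-1 X|`,
#' which does not depend on `beta`.
#'
#' @param dm A design as built by [build_design()].
#' @param beta Fixed-effect vector (on the centred-time basis of `dm`).
#' @param G Random-effect covariance matrix (`q x q`, positive semidefinite).
#' @param sigma2 Residual variance (> 0).
#' @param estimator `"ML"` or `"REML"`.
#' @return The log-likelihood (a scalar).
#' @keywords internal
lmm_loglik <- function(dm, beta, G, sigma2, estimator = c("ML", "REML")) {
  estimator <- match.arg(estimator)
  stopifnot(sigma2 > 0)
  G <- as.matrix(G)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("G must be positive semidefinite", call. = FALSE)
  }
  q <- nrow(G)
  idx <- .subject_index(dm)
  p <- dm$p

  ll <- 0
  Sxx <- matrix(0, p, p)
  sxy <- numeric(p)
  for (rows in idx) {
    Xi <- dm$X[rows, , drop = FALSE]
    Zi <- .Z_of(dm$time_c[rows], q)
    yi <- dm$y[rows]
    Vi <- Zi %*% G %*% t(Zi) + sigma2 * diag(1 / dm$w[rows], nrow = length(rows))
    R <- chol(Vi)
    ri <- backsolve(R, yi - Xi %*% beta, transpose = TRUE)
    ll <- ll - 0.5 * (length(rows) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(ri^2))
    if (estimator == "REML") {
      Xw <- backsolve(R, Xi, transpose = TRUE)
      yw <- backsolve(R, yi, transpose = TRUE)
      Sxx <- Sxx + crossprod(Xw)
      sxy <- sxy + crossprod(Xw, yw)
    }
  }
  if (estimator == "REML") {
    # restricted likelihood: evaluate the ML part at the GLS solution, then
    # apply the integrated-likelihood adjustment
    beta_gls <- solve(Sxx, sxy)
    if (max(abs(beta_gls - beta)) > 0) {
      ll <- lmm_loglik(dm, beta_gls, G, sigma2, "ML")
    }
    ll <- ll + 0.5 * p * log(2 * pi) - 0.5 * determinant(Sxx, logarithm = TRUE)$modulus[1]
  }
  as.numeric(ll)
}

# Precomputed pieces for repeated profiled-deviance evaluations.
.profiled_ctx <- function(dm) {
  q <- dm$q
  idx <- .subject_index(dm)
  list(Z = .Z_of(dm$time_c, q),
       starts = as.integer(vapply(idx, function(r) r[1L] - 1L, integer(1))),
       lens = as.integer(lengths(idx)))
}

# Profiled deviance wrapper around the compiled core.
.profiled <- function(theta, dm, reml, want_components = FALSE, ctx = NULL) {
  if (is.null(ctx)) ctx <- .profiled_ctx(dm)
  .lmm_profiled_cpp(theta, dm$X, ctx$Z, dm$y, dm$w,
                    ctx$starts, ctx$lens, reml, want_components)
}
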
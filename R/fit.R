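#' Fit a polynomial growth-curve linear mixed model
#'
#' Fits the multilevel growth-curve model
#' \deqn{y_{ij} = \sum_{d=0}^{D} \beta_d t_{ij}^d + x_{ij}'\gamma + \sum_{d=0}^{q-1} u_{id} t_{ij}^d + \varepsilon_{ij}}
#' with subject random effects \eqn{u_i \sim N(0, G)} and residuals
#' \eqn{\varepsilon_{ij} \sim N(0, \sigma^2 / w_{ij})}, by maximum likelihood
#' (default) or REML. The deviance is profiled over the fixed effects and the
#' residual variance and minimised over the log-Cholesky factor of the relative
#' random-effect covariance, which is therefore positive semidefinite by
#' construction.
#'
#' Time is always centred at the mean observed time internally (raw-age
#' polynomial bases up to degree 4 are badly conditioned) and estimates are
#' transformed back to the original time scale exactly, so every reported
#' quantity — coefficients, predictions, areas under the curve — is invariant
#' to the centring. The `time_center` argument only chooses the basis on which
#' `coef(fit, scale = "centered")` is displayed.
#'
#' An interaction variable enters as a full block: its main effect plus its
#' product with every polynomial term, giving group-specific trajectories.
#' Continuous interaction variables are standardised (mean 0, sd 1);
#' categorical variables are treatment-coded with the lowest level (numeric
#' order when all levels parse as numbers, byte order otherwise) as reference.
#'
#' @param data Long-format data frame, or a model formula in the
#'   `y ~ t + I(t^2) + (1 + t | id)` dialect (then pass the data frame as the
#'   second argument). In a formula the first right-hand-side term is the time
#'   variable; terms containing `:` define the interaction variable.
#' @param outcome,time,subject Column names of the outcome, age/time and
#'   subject-identifier variables.
#' @param fixed_degree Degree of the fixed polynomial in time (1--4).
#' @param random_degree Degree of the random polynomial (0 = random intercept
#'   only; up to 2). Must not exceed `fixed_degree`.
#' @param covariates Character vector of covariate column names; optionally
#'   named by the column with values `"continuous"` or `"categorical"`
#'   (unnamed entries are classified from the data: numeric columns are
#'   continuous).
#' @param interaction Optional interaction variable: a column name, or
#'   `list(name =, kind =)`.
#' @param estimator `"ML"` (default) or `"REML"`.
#' @param weights Optional column of strictly positive precision (survey)
#'   weights; the residual variance of a row is `sigma2 / w`.
#' @param time_center Optional display centre for the centred coefficient
#'   basis; default is the mean observed time. Reported results are invariant
#'   to this choice.
#' @param control List of optimiser settings: `rel_tol` (relative objective
#'   tolerance, default `1e-8`), `max_iter` (default 500).
#' @return An object of class `"trajlmm"` with components `beta`, `Vbeta`,
#'   `G`, `sigma2` (original time scale), `loglik`, `deviance`, `converged`,
#'   `singular`, sample sizes and the encoding needed to rebuild contrasts.
#' @examples
#' cfg <- sim_config(n_subjects = 120, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' sp <- wide_spec("subject", paste0("age_t", 1:5), paste0("y_t", 1:5),
#'                 occasion_name = "occ", outcome_name = "y")
#' long <- reshape_wide_to_long(cohort$data, sp)
#' fit <- trajlmm(long, outcome = "y", time = "age", subject = "subject",
#'                fixed_degree = 2, random_degree = 1)
#' summary(fit)
#' @export
trajlmm <- function(data, outcome, time, subject,
                    fixed_degree = 1L, random_degree = 1L,
                    covariates = NULL, interaction = NULL,
                    estimator = c("ML", "REML"),
                    weights = NULL, time_center = NULL,
                    control = list()) {
  cl <- match.call()
  if (inherits(data, "formula")) {
    parsed <- parse_growth_formula(data)
    if (!is.data.frame(outcome)) {
      stop("when the first argument is a formula, pass the data frame second",
           call. = FALSE)
    }
    df <- outcome
    return(trajlmm(df, outcome = parsed$outcome, time = parsed$time,
                   subject = parsed$subject,
                   fixed_degree = parsed$fixed_degree,
                   random_degree = parsed$random_degree,
                   covariates = parsed$covariates,
                   interaction = parsed$interaction,
                   estimator = estimator, weights = weights,
                   time_center = time_center, control = control))
  }
  estimator <- match.arg(estimator)
  ctrl <- modifyList(list(rel_tol = 1e-8, max_iter = 500L), control)

  spec <- traj_model_spec(outcome = outcome, time = time, subject = subject,
                          fixed_degree = fixed_degree,
                          random_degree = random_degree,
                          covariates = covariates, interaction = interaction,
                          estimator = estimator, weights_col = weights,
                          time_center = time_center)
  dm <- build_design(data, spec)
  fit <- .fit_lmm(dm, ctrl)
  fit$call <- cl
  fit
}

# A few damped Newton steps with central-difference gradient and Hessian,
# used (via control$polish) when agreement with closed forms to ~1e-8 in the
# objective is wanted; quasi-Newton stopping rules alone leave the variance
# parameters accurate only to about sqrt(objective tolerance).
.newton_polish <- function(opt, obj, ntheta, h = 1e-4, steps = 4L) {
  par <- opt$par
  f0 <- obj(par)
  for (s in seq_len(steps)) {
    g <- numeric(ntheta)
    H <- matrix(0, ntheta, ntheta)
    fp <- fm <- numeric(ntheta)
    for (i in seq_len(ntheta)) {
      ei <- replace(numeric(ntheta), i, h)
      fp[i] <- obj(par + ei); fm[i] <- obj(par - ei)
      g[i] <- (fp[i] - fm[i]) / (2 * h)
      H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
    }
    if (ntheta > 1) {
      for (i in 1:(ntheta - 1)) {
        for (j in (i + 1):ntheta) {
          ei <- replace(numeric(ntheta), i, h)
          ej <- replace(numeric(ntheta), j, h)
          H[i, j] <- H[j, i] <-
            (obj(par + ei + ej) - obj(par + ei - ej) -
               obj(par - ei + ej) + obj(par - ei - ej)) / (4 * h^2)
        }
      }
    }
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    nrm <- sqrt(sum(step^2))
    if (nrm > 1) step <- step / nrm          # trust region of radius 1
    f1 <- obj(par - step)
    if (!is.finite(f1) || f1 > f0 + 1e-10) break
    par <- par - step
    if (f0 - f1 < 1e-11) { f0 <- f1; break }
    f0 <- f1
  }
  if (f0 <= opt$objective) {
    opt$par <- par
    opt$objective <- f0
    opt$message <- paste(opt$message, "+ newton polish")
    opt$convergence <- 0L
  }
  opt
}

# Optimise the profiled deviance and assemble the fitted-model object.
.fit_lmm <- function(dm, ctrl = list(rel_tol = 1e-8, max_iter = 500L)) {
  reml <- dm$spec$estimator == "REML"
  q <- dm$q
  ntheta <- q * (q + 1L) / 2L

  ctx <- .profiled_ctx(dm)
  obj <- function(theta) {
    r <- .profiled(theta, dm, reml, ctx = ctx)
    if (!isTRUE(r$ok)) return(1e12)
    r$deviance
  }

  accepted <- c("relative convergence", "both x and relative",
                "x convergence", "singular convergence",
                "converged")
  is_ok <- function(o) {
    o$convergence == 0 ||
      any(vapply(accepted, grepl, logical(1), x = tolower(o$message)))
  }
  run <- function(start) {
    stats::nlminb(start, obj,
                  control = list(rel.tol = ctrl$rel_tol,
                                 iter.max = ctrl$max_iter,
                                 eval.max = 4L * ctrl$max_iter))
  }

  opt <- run(rep(0, ntheta))
  # PORT sometimes stops with "singular"/"false convergence" slightly short
  # of the optimum: restart from the solution until the objective stops
  # improving. Clean relative/X-convergence results skip this. Restarting
  # *at* an optimum can itself report "false convergence", so a
  # non-improving restart is only adopted if its own status is acceptable.
  clean <- function(o) {
    grepl("relative convergence|x convergence|both x", tolower(o$message))
  }
  if (!clean(opt)) {
    for (i in 1:3) {
      opt2 <- run(opt$par)
      if (opt2$objective < opt$objective - 1e-10) { opt <- opt2; next }
      if (is_ok(opt2) && opt2$objective <= opt$objective) opt <- opt2
      break
    }
  }
  # if genuinely stalled, probe fixed alternative starts for a better optimum
  if (!is_ok(opt)) {
    for (s in list(rep(-1, ntheta), rep(0.5, ntheta), opt$par - 0.25)) {
      alt <- run(s)
      if (alt$objective < opt$objective - 1e-10) {
        opt <- alt
        polish2 <- run(alt$par)
        if (polish2$objective < opt$objective) opt <- polish2
      }
    }
  }
  if (isTRUE(ctrl$polish)) opt <- .newton_polish(opt, obj, ntheta)
  # a "false convergence" report that no restart or probe can improve upon is
  # a confirmed (typically boundary) optimum, not a failure
  if (!is_ok(opt) && grepl("false convergence", tolower(opt$message))) {
    opt$message <- paste(opt$message,
                         "- accepted: restart probes found no improvement")
    opt$convergence <- 0L
  }
  if (!is_ok(opt)) {
    cond <- structure(
      class = c("trajlmm_convergence_error", "error", "condition"),
      list(message = paste0("growth-curve model failed to converge: ",
                            opt$message,
                            " (", opt$iterations, " iterations)"),
           call = NULL,
           diagnostics = list(iterations = opt$iterations,
                              evaluations = opt$evaluations,
                              message = opt$message,
                              objective = opt$objective)))
    stop(cond)
  }

  comp <- .profiled(opt$par, dm, reml, want_components = TRUE, ctx = ctx)
  if (!isTRUE(comp$ok)) {
    stop("deviance components could not be evaluated at the optimum", call. = FALSE)
  }

  beta_c <- drop(comp$beta)
  Vbeta_c <- comp$Vbeta
  G_c <- comp$G
  sigma2 <- comp$sigma2

  # singularity: any relative-covariance eigenvalue (numerically) zero
  evG <- eigen(G_c, symmetric = TRUE, only.values = TRUE)$values
  singular <- isTRUE(comp$sigma2_floored) ||
    min(evG) < 1e-8 * max(sum(diag(G_c)), 1)
  if (singular) {
    warning("fit is singular: a random-effect variance is (numerically) zero",
            call. = FALSE)
  }

  # exact change of basis back to the original time scale
  Tm <- .coef_transform(dm$block, dm$spec$fixed_degree, dm$encoding$fit_center)
  beta <- drop(Tm %*% beta_c)
  Vbeta <- Tm %*% Vbeta_c %*% t(Tm)
  names(beta) <- dm$term_names
  dimnames(Vbeta) <- list(dm$term_names, dm$term_names)
  Ar <- .basis_transform(q - 1L, dm$encoding$fit_center)
  G <- t(Ar) %*% G_c %*% Ar
  rand_names <- c("(Intercept)", if (q >= 2) dm$spec$time,
                  if (q >= 3) sprintf("I(%s^%d)", dm$spec$time, 2:(q - 1L)))
  dimnames(G) <- list(rand_names, rand_names)

  dev <- opt$objective
  fit <- structure(list(
    beta = beta, Vbeta = Vbeta, G = G, sigma2 = sigma2,
    beta_centered = stats::setNames(beta_c, dm$term_names),
    Vbeta_centered = Vbeta_c, G_centered = G_c,
    loglik = -dev / 2, deviance = dev,
    estimator = dm$spec$estimator,
    converged = TRUE, singular = singular,
    optimizer = list(iterations = opt$iterations,
                     evaluations = opt$evaluations,
                     message = opt$message,
                     theta = opt$par),
    n_obs = dm$n_obs, n_subjects = dm$n_subjects, n_dropped = dm$n_dropped,
    term_names = dm$term_names, block = dm$block,
    random_names = rand_names,
    spec = dm$spec, encoding = dm$encoding,
    time_range = range(dm$time_raw),
    dm = dm), class = "trajlmm")
  fit
}
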
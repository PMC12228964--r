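# Design construction for polynomial growth-curve models.
#
# The model is fitted on centred time t_c = t - time_center (raw-age polynomial
# bases up to degree 4 are ill-conditioned); estimates are transformed back to
# the original time scale exactly (see .basis_transform), so all reported
# quantities are invariant to the centring constant.

# polynomial basis columns 1, t, t^2, ..., t^degree
.poly_basis <- function(t, degree) {
  outer(t, 0:degree, `^`)
}

# A such that p_centered(t) = A %*% p_raw(t) where p_*(t) = (1, t, ..., t^d)':
# (t - c)^k = sum_j choose(k, j) (-c)^(k-j) t^j.
# Coefficients transform as beta_raw = t(A) %*% beta_centered.
.basis_transform <- function(degree, center) {
  d1 <- degree + 1L
  A <- matrix(0, d1, d1)
  for (k in 0:degree) {
    for (j in 0:k) {
      A[k + 1L, j + 1L] <- choose(k, j) * (-center)^(k - j)
    }
  }
  A
}

# Categorical levels ordered so the "lowest" level is the reference group:
# numerically when every level parses as a number, otherwise byte order.
.order_levels <- function(x) {
  lev <- unique(as.character(x[!is.na(x)]))
  num <- suppressWarnings(as.numeric(lev))
  if (!anyNA(num)) lev[order(num)] else lev[order(lev, method = "radix")]
}

# Internal model-specification record. `covariates` is a named character
# vector mapping column name -> kind ("continuous"/"categorical");
# `interaction` is NULL or list(name=, kind=).
traj_model_spec <- function(outcome, time, subject,
                            fixed_degree = 1L, random_degree = 1L,
                            covariates = NULL, interaction = NULL,
                            estimator = c("ML", "REML"),
                            weights_col = NULL, time_center = NULL) {
  estimator <- match.arg(estimator)
  fixed_degree <- as.integer(fixed_degree)
  random_degree <- as.integer(random_degree)
  if (!fixed_degree %in% 1:4) stop("fixed_degree must be 1, 2, 3 or 4", call. = FALSE)
  if (!random_degree %in% 0:2) stop("random_degree must be 0, 1 or 2", call. = FALSE)
  if (random_degree > fixed_degree) {
    stop("random_degree cannot exceed fixed_degree", call. = FALSE)
  }
  if (!is.null(interaction)) {
    if (is.character(interaction)) interaction <- list(name = interaction, kind = NA)
    if (interaction$name %in% names(covariates)) {
      stop("'", interaction$name, "' cannot be both a covariate and the interaction variable",
           call. = FALSE)
    }
  }
  structure(list(outcome = outcome, time = time, subject = subject,
                 fixed_degree = fixed_degree, random_degree = random_degree,
                 covariates = covariates, interaction = interaction,
                 estimator = estimator, weights_col = weights_col,
                 time_center = time_center),
            class = "traj_model_spec")
}

# Resolve covariate kinds from the data when not stated by the user.
.resolve_kinds <- function(data, spec) {
  resolve1 <- function(name, kind) {
    if (!is.na(kind) && nzchar(kind)) {
      return(match.arg(kind, c("continuous", "categorical")))
    }
    x <- data[[name]]
    # numeric columns are continuous, except indicator-style columns (two or
    # fewer distinct values, e.g. 0/1 sex) which are treated as categorical
    if (is.numeric(x) && length(unique(x[!is.na(x)])) > 2L) "continuous"
    else "categorical"
  }
  if (!is.null(spec$covariates)) {
    nm <- names(spec$covariates)
    if (is.null(nm) || any(!nzchar(nm))) {
      nm <- as.character(spec$covariates)
      spec$covariates <- stats::setNames(rep(NA_character_, length(nm)), nm)
    }
    spec$covariates <- stats::setNames(
      vapply(nm, function(v) resolve1(v, spec$covariates[[v]]), character(1)), nm)
  }
  if (!is.null(spec$interaction)) {
    k <- spec$interaction$kind
    spec$interaction$kind <- resolve1(spec$interaction$name,
                                      if (is.null(k)) NA_character_ else as.character(k))
  }
  spec
}

#' Build growth-curve design matrices
#'
#' Assembles the fixed-effects design matrix for a polynomial growth-curve
#' model: intercept and powers of (centred) time, covariate main effects, and
#' optionally a full interaction block (the interaction variable's main effect
#' plus its product with every polynomial term). Rows with a missing outcome,
#' time, weight or covariate are dropped (listwise deletion for covariates;
#' missing outcomes are handled by the likelihood simply by not contributing
#' rows). Continuous interaction variables are standardised to mean 0, sd 1
#' (sample sd); categorical variables are treatment-coded with the lowest
#' level as reference.
#'
#' @param data Long-format data frame.
#' @param spec Internal model specification (as built by [trajlmm()]).
#' @param encoding Optional encoding information from a previous fit; when
#'   supplied, its centring/standardisation constants and factor levels are
#'   reused rather than recomputed, so designs built from a reloaded model
#'   artifact match the original exactly.
#' @return A list with the design matrix `X` (centred time basis), outcome `y`,
#'   weights `w`, subject index, raw and centred times, term names (original
#'   time scale), encoding information, and drop counts.
#' @keywords internal
build_design <- function(data, spec, encoding = NULL) {
  spec <- .resolve_kinds(data, spec)
  needed <- c(spec$outcome, spec$time, spec$subject, names(spec$covariates),
              if (!is.null(spec$interaction)) spec$interaction$name,
              spec$weights_col)
  for (col in needed) {
    if (!col %in% names(data)) stop("column '", col, "' not found in the data",
                                    call. = FALSE)
  }

  y <- data[[spec$outcome]]
  t_raw <- data[[spec$time]]
  subj <- data[[spec$subject]]
  w <- if (is.null(spec$weights_col)) rep(1, nrow(data)) else data[[spec$weights_col]]

  keep <- !is.na(y) & !is.na(t_raw) & !is.na(subj) & !is.na(w)
  for (v in names(spec$covariates)) keep <- keep & !is.na(data[[v]])
  if (!is.null(spec$interaction)) keep <- keep & !is.na(data[[spec$interaction$name]])
  n_dropped <- sum(!keep)
  if (sum(keep) == 0L) stop("no complete rows available for modelling", call. = FALSE)
  if (!is.null(spec$weights_col) && any(w[keep] <= 0)) {
    stop("weights must be strictly positive", call. = FALSE)
  }

  dat <- data[keep, , drop = FALSE]
  y <- y[keep]; t_raw <- t_raw[keep]; subj <- as.character(subj[keep]); w <- w[keep]

  if (length(unique(subj)) < 2L) {
    stop("at least 2 subjects with complete rows are required", call. = FALSE)
  }

  enc <- list()
  # fitting always centres at the sample mean (conditioning); `time_center`
  # only selects the basis on which centred coefficients are *displayed*, so
  # all reported quantities are exactly invariant to it
  enc$fit_center <- if (!is.null(encoding)) encoding$fit_center else mean(t_raw)
  enc$time_center <- if (!is.null(encoding)) encoding$time_center
                     else if (!is.null(spec$time_center)) spec$time_center
                     else enc$fit_center
  t_c <- t_raw - enc$fit_center

  d <- spec$fixed_degree
  X <- .poly_basis(t_c, d)
  terms <- c("(Intercept)", spec$time,
             if (d >= 2) sprintf("I(%s^%d)", spec$time, 2:d))
  block <- rep("poly", d + 1L)

  enc$covariates <- list()
  for (v in names(spec$covariates)) {
    kind <- spec$covariates[[v]]
    if (kind == "continuous") {
      val <- as.numeric(dat[[v]])
      m <- if (!is.null(encoding)) encoding$covariates[[v]]$mean else mean(val)
      enc$covariates[[v]] <- list(kind = "continuous", mean = m)
      X <- cbind(X, val)
      terms <- c(terms, v); block <- c(block, "covar")
    } else {
      levs <- if (!is.null(encoding)) encoding$covariates[[v]]$levels
              else .order_levels(dat[[v]])
      if (length(levs) < 2L) {
        stop("categorical variable '", v, "' has fewer than 2 levels", call. = FALSE)
      }
      obs <- as.character(dat[[v]])
      unknown <- setdiff(unique(obs), levs)
      if (length(unknown) > 0L) {
        stop("unknown level(s) ", paste0("'", unknown, "'", collapse = ", "),
             " for '", v, "'; known levels: ", paste(levs, collapse = ", "),
             call. = FALSE)
      }
      enc$covariates[[v]] <- list(kind = "categorical", levels = levs)
      for (l in levs[-1L]) {
        X <- cbind(X, as.numeric(obs == l))
        terms <- c(terms, paste0(v, l)); block <- c(block, "covar")
      }
    }
  }

  enc$interaction <- NULL
  if (!is.null(spec$interaction)) {
    v <- spec$interaction$name
    kind <- spec$interaction$kind
    poly_cols <- .poly_basis(t_c, d)
    if (kind == "continuous") {
      val <- as.numeric(dat[[v]])
      if (!is.null(encoding)) {
        m <- encoding$interaction$mean; s <- encoding$interaction$sd
      } else {
        m <- mean(val); s <- stats::sd(val)
        if (!is.finite(s) || s == 0) {
          stop("interaction variable '", v, "' has zero variance", call. = FALSE)
        }
      }
      g <- (val - m) / s
      enc$interaction <- list(name = v, kind = "continuous", mean = m, sd = s)
      X <- cbind(X, g * poly_cols)
      terms <- c(terms, v, paste0(v, ":", terms[2:(d + 1L)]))
      block <- c(block, rep(paste0("int:", v), d + 1L))
    } else {
      levs <- if (!is.null(encoding)) encoding$interaction$levels
              else .order_levels(dat[[v]])
      if (length(levs) < 2L) {
        stop("interaction variable '", v, "' has fewer than 2 levels", call. = FALSE)
      }
      obs <- as.character(dat[[v]])
      unknown <- setdiff(unique(obs), levs)
      if (length(unknown) > 0L) {
        stop("unknown level(s) ", paste0("'", unknown, "'", collapse = ", "),
             " for '", v, "'; known levels: ", paste(levs, collapse = ", "),
             call. = FALSE)
      }
      enc$interaction <- list(name = v, kind = "categorical", levels = levs)
      for (l in levs[-1L]) {
        g <- as.numeric(obs == l)
        X <- cbind(X, g * poly_cols)
        terms <- c(terms, paste0(v, l), paste0(v, l, ":", terms[2:(d + 1L)]))
        block <- c(block, rep(paste0("int:", v, l), d + 1L))
      }
    }
  }

  colnames(X) <- terms
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- terms[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  subj_f <- factor(subj, levels = unique(subj))
  ord <- order(as.integer(subj_f))
  frame_cols <- unique(c(spec$subject, spec$time, spec$outcome,
                         names(spec$covariates),
                         if (!is.null(spec$interaction)) spec$interaction$name,
                         spec$weights_col))
  list(X = X[ord, , drop = FALSE],
       frame = dat[ord, frame_cols, drop = FALSE],
       y = y[ord], w = w[ord],
       time_raw = t_raw[ord], time_c = t_c[ord],
       subject = subj_f[ord],
       term_names = terms, block = block,
       q = spec$random_degree + 1L, p = ncol(X),
       n_obs = length(y), n_subjects = nlevels(subj_f),
       n_dropped = n_dropped,
       encoding = enc,
       spec = spec)
}

# Block-diagonal transform Tm such that beta_raw = Tm %*% beta_centred for a
# basis centred at `center`: poly and interaction blocks use the polynomial
# change of basis, covariate columns are unaffected.
.coef_transform <- function(block, fixed_degree, center) {
  A <- .basis_transform(fixed_degree, center)
  p <- length(block)
  Tm <- diag(p)
  Tm[1:(fixed_degree + 1L), 1:(fixed_degree + 1L)] <- t(A)
  for (b in unique(block[startsWith(block, "int:")])) {
    idx <- which(block == b)
    Tm[idx, idx] <- t(A)
  }
  Tm
}
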
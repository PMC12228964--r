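# The model formula in the mixed-model (Wilkinson) dialect, and its parser.

#' Model formula string for a growth-curve specification
#'
#' Emits the mixed-model formula corresponding to a fitted model or
#' specification, e.g. a cubic fixed / quadratic random model for outcome
#' `sdq`, time `age` and subject `subject` is
#' `"sdq ~ age + I(age^2) + I(age^3) + (1 + age + I(age^2) | subject)"`.
#' Covariates are appended after the polynomial terms; an interaction variable
#' `f` appends `+ f + f:age + f:I(age^2) + ...`.
#'
#' @param x A fitted [trajlmm()] model or an internal model specification.
#' @param ... Unused.
#' @return A character scalar.
#' @export
formula_string <- function(x, ...) {
  spec <- if (inherits(x, "trajlmm")) x$spec else x
  stopifnot(inherits(spec, "traj_model_spec"))
  d <- spec$fixed_degree
  r <- spec$random_degree
  tm <- spec$time
  poly_terms <- c(tm, if (d >= 2) sprintf("I(%s^%d)", tm, 2:d))
  terms <- poly_terms
  if (!is.null(spec$covariates)) terms <- c(terms, names(spec$covariates))
  if (!is.null(spec$interaction)) {
    f <- spec$interaction$name
    terms <- c(terms, f, paste0(f, ":", poly_terms[seq_len(d)]))
  }
  rand <- if (r == 0) "1" else paste(c("1", poly_terms[seq_len(r)]), collapse = " + ")
  paste0(spec$outcome, " ~ ", paste(terms, collapse = " + "),
         " + (", rand, " | ", spec$subject, ")")
}

#' Parse a growth-curve model formula
#'
#' Inverts [formula_string()]: reads a formula (or its character form) in the
#' `y ~ t + I(t^2) + x + f + f:t + (1 + t | id)` dialect back into a model
#' specification. The first right-hand-side term is taken as the time
#' variable; plain terms are covariates; terms containing `:` identify the
#' interaction variable. Covariate kinds are left unresolved (they are
#' classified from the data at fit time).
#'
#' @param f A formula or character scalar.
#' @return A list with elements `outcome`, `time`, `subject`, `fixed_degree`,
#'   `random_degree`, `covariates`, `interaction`.
#' @export
parse_growth_formula <- function(f) {
  s <- if (inherits(f, "formula")) paste(deparse(f), collapse = " ") else as.character(f)
  s <- gsub("\\s+", " ", trimws(s))

  bar <- regmatches(s, regexpr("\\(([^|()]|I\\([^)]*\\))*\\|[^)]*\\)", s))
  if (length(bar) != 1L) {
    stop("formula must contain one random-effects term '( ... | subject)'",
         call. = FALSE)
  }
  fixed_part <- trimws(sub(bar, "", s, fixed = TRUE))
  fixed_part <- trimws(sub("\\+\\s*$", "", fixed_part))

  halves <- strsplit(fixed_part, "~", fixed = TRUE)[[1]]
  if (length(halves) != 2L) stop("formula must have the form 'y ~ ...'", call. = FALSE)
  outcome <- trimws(halves[1])
  rhs_terms <- trimws(strsplit(halves[2], "+", fixed = TRUE)[[1]])
  rhs_terms <- rhs_terms[nzchar(rhs_terms)]
  if (length(rhs_terms) == 0L) stop("no fixed-effect terms found", call. = FALSE)

  time <- rhs_terms[1]
  if (grepl("[:()]", time)) {
    stop("the first right-hand-side term must be the (plain) time variable",
         call. = FALSE)
  }
  pow_pat <- paste0("^I\\(", time, "\\^([0-9]+)\\)$")
  powers <- regmatches(rhs_terms, regexec(pow_pat, rhs_terms))
  degs <- as.integer(vapply(powers, function(m) if (length(m)) m[2] else NA_character_,
                            character(1)))
  fixed_degree <- max(1L, degs, na.rm = TRUE)

  rest <- rhs_terms[-1]
  rest <- rest[is.na(degs[-1])]
  inter_terms <- rest[grepl(":", rest, fixed = TRUE)]
  interaction <- NULL
  if (length(inter_terms) > 0L) {
    iv <- unique(vapply(strsplit(inter_terms, ":", fixed = TRUE), `[[`, character(1), 1L))
    if (length(iv) != 1L) {
      stop("only a single interaction variable is supported; found: ",
           paste(iv, collapse = ", "), call. = FALSE)
    }
    interaction <- list(name = iv, kind = NA)
    rest <- rest[!grepl(":", rest, fixed = TRUE) & rest != iv]
  }
  covariates <- if (length(rest) > 0L) {
    stats::setNames(rep(NA_character_, length(rest)), rest)
  }

  inner <- sub("^\\(", "", sub("\\)$", "", bar))
  parts <- strsplit(inner, "|", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed random-effects term", call. = FALSE)
  subject <- trimws(parts[2])
  rand_terms <- trimws(strsplit(parts[1], "+", fixed = TRUE)[[1]])
  rand_terms <- rand_terms[nzchar(rand_terms)]
  rpow <- regmatches(rand_terms, regexec(pow_pat, rand_terms))
  rdegs <- vapply(seq_along(rand_terms), function(i) {
    tt <- rand_terms[i]
    if (tt == "1") 0L
    else if (tt == time) 1L
    else if (length(rpow[[i]])) as.integer(rpow[[i]][2])
    else stop("unrecognised random term '", tt, "'", call. = FALSE)
  }, integer(1))
  random_degree <- max(rdegs)

  list(outcome = outcome, time = time, subject = subject,
       fixed_degree = fixed_degree, random_degree = random_degree,
       covariates = covariates, interaction = interaction)
}
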
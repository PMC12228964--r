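# Summary-report bundle: collects every table a user would want from a fitted
# trajectory model, plus deterministic plain-language interpretation.

# display convention: two decimals, IEEE round-half-even (R's round())
.fmt2 <- function(x) formatC(round(x, 2), format = "f", digits = 2)

#' Assemble a trajectory analysis report bundle
#'
#' Collects the model formula, sample sizes, fixed- and random-effect tables,
#' deviance, requested predictions, areas under the curve, group comparisons,
#' plain-language interpretation and provenance into one object that
#' [render_report()] can write out. All numbers in the interpretation text are
#' drawn from the bundle's tables.
#'
#' @param fm A fitted [trajlmm()] model.
#' @param predict_at Optional numeric vector of times to predict at.
#' @param auc_range Optional length-2 vector of AUC bounds.
#' @param compare_levels Optional length-2 vector of interaction levels for
#'   group comparisons (difference at each `predict_at` time and, if
#'   `auc_range` is given, the AUC difference).
#' @param input_file Optional path of the analysed data file (hashed into the
#'   provenance section).
#' @param seed Optional seed(s) to record in the provenance section.
#' @return An object of class `"traj_report"`.
#' @export
traj_report <- function(fm, predict_at = NULL, auc_range = NULL,
                        compare_levels = NULL, input_file = NULL, seed = NULL) {
  stopifnot(inherits(fm, "trajlmm"), fm$converged)
  preds <- if (!is.null(predict_at)) {
    predict(fm, at = predict_at, warn_extrapolation = FALSE)
  }
  aucs <- if (!is.null(auc_range)) traj_auc(fm, auc_range[1], auc_range[2])
  diffs <- NULL; auc_d <- NULL
  if (!is.null(compare_levels)) {
    v <- .require_interaction(fm)
    if (!is.null(predict_at)) {
      diffs <- do.call(rbind, lapply(predict_at, function(t)
        difference_at_time(fm, t, compare_levels)))
    }
    if (!is.null(auc_range)) {
      auc_d <- auc_difference(fm, auc_range[1], auc_range[2], compare_levels)
    }
  }
  bundle <- list(formula = formula_string(fm),
                 estimator = fm$estimator,
                 outcome = fm$spec$outcome, time = fm$spec$time,
                 interaction = if (!is.null(fm$encoding$interaction))
                   fm$encoding$interaction$name,
                 compare_levels = compare_levels,
                 n_obs = fm$n_obs, n_subjects = fm$n_subjects,
                 n_dropped = fm$n_dropped,
                 fixed = fixed_effects(fm),
                 random = random_effects(fm),
                 deviance = fm$deviance, loglik = fm$loglik,
                 singular = fm$singular,
                 fixed_degree = fm$spec$fixed_degree,
                 predictions = preds, auc = aucs,
                 differences = diffs, auc_difference = auc_d,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("trajlmm")),
                   input_file = input_file,
                   input_md5 = if (!is.null(input_file) && file.exists(input_file))
                     unname(tools::md5sum(input_file)),
                   seed = seed,
                   timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")))
  bundle$interpretation <- interpret_report(bundle)
  class(bundle) <- "traj_report"
  bundle
}

#' Plain-language interpretation of a report bundle
#'
#' Deterministic template fill: direction words are chosen by the sign of the
#' estimate, "statistically distinguishable from zero at the 95% level" by
#' whether the confidence interval excludes zero, and numbers are formatted to
#' two decimals (round-half-even), matching the tables in the bundle.
#'
#' @param bundle A `"traj_report"` bundle (or the underlying list).
#' @return Character vector of paragraphs.
#' @export
interpret_report <- function(bundle) {
  tpl <- .report_templates
  out <- character(0)
  shape <- c("linear", "quadratic", "cubic", "quartic")[bundle$fixed_degree]
  out <- c(out, sprintf(tpl$model_intro, shape, bundle$fixed_degree,
                        bundle$time, bundle$estimator, bundle$n_obs,
                        bundle$n_subjects, bundle$n_dropped))

  lin <- bundle$fixed[bundle$fixed$term == bundle$time, ]
  if (nrow(lin) == 1L) {
    clear <- !is.na(lin$ci_low) && (lin$ci_low > 0 || lin$ci_high < 0)
    key <- if (!clear) "linear_flat" else if (lin$estimate > 0) "linear_up" else "linear_down"
    out <- c(out, sprintf(tpl[[key]], bundle$time, .fmt2(lin$estimate),
                          .fmt2(lin$ci_low), .fmt2(lin$ci_high),
                          bundle$outcome, bundle$time))
  }
  if (bundle$fixed_degree >= 2) out <- c(out, tpl$nonlinear)

  if (!is.null(bundle$predictions)) {
    for (i in seq_len(nrow(bundle$predictions))) {
      pr <- bundle$predictions[i, ]
      out <- c(out, sprintf(tpl$prediction, bundle$time, .fmt2(pr$time),
                            bundle$outcome, .fmt2(pr$estimate),
                            .fmt2(pr$ci_low), .fmt2(pr$ci_high)))
    }
  }
  if (!is.null(bundle$auc)) {
    a <- bundle$auc
    out <- c(out, sprintf(tpl$auc, bundle$time, .fmt2(a$from), .fmt2(a$to),
                          .fmt2(a$estimate), .fmt2(a$ci_low), .fmt2(a$ci_high),
                          bundle$outcome))
  }
  if (!is.null(bundle$differences)) {
    v <- bundle$interaction; lv <- bundle$compare_levels
    for (i in seq_len(nrow(bundle$differences))) {
      dd <- bundle$differences[i, ]
      clear <- dd$ci_low > 0 || dd$ci_high < 0
      key <- if (clear) "diff_clear" else "diff_unclear"
      args <- list(tpl[[key]], bundle$time, .fmt2(dd$time), bundle$outcome,
                   v, lv[1], v, lv[2], .fmt2(dd$estimate),
                   .fmt2(dd$ci_low), .fmt2(dd$ci_high))
      if (!clear) args <- c(args, bundle$time)
      out <- c(out, do.call(sprintf, args))
    }
  }
  if (!is.null(bundle$auc_difference)) {
    v <- bundle$interaction; lv <- bundle$compare_levels
    ad <- bundle$auc_difference
    clear <- ad$ci_low > 0 || ad$ci_high < 0
    key <- if (clear) "auc_diff_clear" else "auc_diff_unclear"
    out <- c(out, sprintf(tpl[[key]], bundle$time, .fmt2(ad$from), .fmt2(ad$to),
                          v, lv[1], v, lv[2], .fmt2(ad$estimate),
                          .fmt2(ad$ci_low), .fmt2(ad$ci_high)))
  }
  if (isTRUE(bundle$singular)) out <- c(out, tpl$singular_note)
  out
}

.report_sections <- function(bundle, md = FALSE) {
  h <- function(x) if (md) paste0("## ", x) else toupper(x)
  tab <- function(df) {
    if (is.null(df)) return("  (none requested)")
    paste(utils::capture.output(print(df, row.names = FALSE)), collapse = "\n")
  }
  rand <- bundle$random$variances
  prov <- bundle$provenance
  c(h("Model formula"), bundle$formula, "",
    h("Sample"),
    sprintf("observations: %d; subjects: %d; rows dropped (incomplete): %d",
            bundle$n_obs, bundle$n_subjects, bundle$n_dropped), "",
    h("Fixed effects"), tab(bundle$fixed), "",
    h("Random effects"), tab(rand), "",
    h("Model fit"),
    sprintf("deviance (%s): %.6f", bundle$estimator, bundle$deviance),
    if (bundle$estimator == "REML")
      "note: REML deviances are not comparable across different fixed-effects structures",
    "",
    h("Predicted scores"), tab(bundle$predictions), "",
    h("Area under the curve"), tab(bundle$auc), "",
    h("Group comparisons"), tab(bundle$differences), tab(bundle$auc_difference), "",
    h("Interpretation"), paste(bundle$interpretation, collapse = "\n\n"), "",
    h("Provenance"),
    sprintf("package version: %s", prov$package_version),
    if (!is.null(prov$input_file)) sprintf("input file: %s (md5 %s)",
                                           prov$input_file, prov$input_md5),
    if (!is.null(prov$seed)) sprintf("seed(s): %s", paste(prov$seed, collapse = ", ")),
    sprintf("timestamp: %s", prov$timestamp))
}

#' Render a report bundle to files
#'
#' Formats: `"text"` (plain text), `"markdown"`, or `"csv"` (a directory of
#' CSV files, one per table, re-parsable at full precision). Sections are
#' ordered: formula, sample, fixed effects, random effects, deviance,
#' predictions, AUC, group comparisons, interpretation, provenance.
#'
#' @param bundle A [traj_report()] bundle.
#' @param format `"text"`, `"markdown"` or `"csv"`.
#' @param path Output file (text/markdown) or directory (csv).
#' @return Invisibly, the path(s) written.
#' @export
render_report <- function(bundle, format = c("text", "markdown", "csv"), path) {
  stopifnot(inherits(bundle, "traj_report"))
  format <- match.arg(format)
  if (format %in% c("text", "markdown")) {
    lines <- .report_sections(bundle, md = format == "markdown")
    lines <- lines[!vapply(lines, is.null, logical(1))]
    writeLines(unlist(lines), path)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  tables <- list(fixed_effects = bundle$fixed,
                 random_effects = bundle$random$variances,
                 predictions = bundle$predictions,
                 auc = bundle$auc,
                 differences = bundle$differences,
                 auc_difference = bundle$auc_difference)
  written <- character(0)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE, na = "NA")
    written <- c(written, f)
  }
  meta <- data.frame(key = c("formula", "estimator", "deviance", "n_obs",
                             "n_subjects", "n_dropped", "timestamp"),
                     value = c(bundle$formula, bundle$estimator,
                               format(bundle$deviance, digits = 17),
                               bundle$n_obs, bundle$n_subjects,
                               bundle$n_dropped, bundle$provenance$timestamp))
  f <- file.path(path, "model.csv")
  utils::write.csv(meta, f, row.names = FALSE)
  interp <- file.path(path, "interpretation.txt")
  writeLines(bundle$interpretation, interp)
  invisible(c(written, f, interp))
}

#' @export
print.traj_report <- function(x, ...) {
  lines <- .report_sections(x, md = FALSE)
  lines <- lines[!vapply(lines, is.null, logical(1))]
  cat(unlist(lines), sep = "\n")
  invisible(x)
}
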
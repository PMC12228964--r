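# JSON model artifacts: everything needed to rebuild contrast vectors and
# delta-method inference away from the fitting session. Reals are written at
# full precision.

#' Save a fitted model as a JSON artifact
#'
#' Writes the estimates, their covariance, the random-effect covariance,
#' residual variance, likelihood, sample sizes, term names and the complete
#' encoding information (centring/standardisation constants, factor levels)
#' to a versioned JSON document. Contrast vectors rebuilt from the artifact
#' equal those built in-session.
#'
#' @param fm A fitted [trajlmm()] model.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(fm, path) {
  stopifnot(inherits(fm, "trajlmm"))
  spec <- unclass(fm$spec)
  doc <- list(schema_version = 1L,
              package_version = as.character(utils::packageVersion("trajlmm")),
              spec = spec,
              term_names = fm$term_names,
              block = fm$block,
              random_names = fm$random_names,
              beta = fm$beta, Vbeta = fm$Vbeta,
              G = fm$G, sigma2 = fm$sigma2,
              beta_centered = fm$beta_centered,
              Vbeta_centered = fm$Vbeta_centered,
              G_centered = fm$G_centered,
              loglik = fm$loglik, deviance = fm$deviance,
              estimator = fm$estimator,
              converged = fm$converged, singular = fm$singular,
              n_obs = fm$n_obs, n_subjects = fm$n_subjects,
              n_dropped = fm$n_dropped,
              encoding = fm$encoding,
              time_range = fm$time_range)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Load a fitted model from a JSON artifact
#'
#' Reconstructs a `"trajlmm"` object from [save_model()] output. Prediction,
#' AUC and contrast machinery work immediately; operations that need the
#' modelled rows (BLUPs, individual curves, fitted values) additionally need
#' the original long data, which is re-encoded with the *stored* constants —
#' never recomputed — so results match the fitting session.
#'
#' @param path Path to the JSON artifact.
#' @param data Optional long data frame (the data used to fit) to reattach.
#' @return An object of class `"trajlmm"`.
#' @export
load_model <- function(path, data = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L) {
    stop("unsupported model artifact (schema_version ",
         doc$schema_version, ")", call. = FALSE)
  }
  spec <- doc$spec
  if (!is.null(spec$covariates)) {
    spec$covariates <- unlist(spec$covariates)
  }
  class(spec) <- "traj_model_spec"

  enc <- doc$encoding
  # jsonlite reads nested lists; nothing to coerce beyond covariate entries
  fm <- list(beta = stats::setNames(as.numeric(doc$beta), doc$term_names),
             Vbeta = matrix(as.numeric(doc$Vbeta), length(doc$term_names),
                            dimnames = list(doc$term_names, doc$term_names)),
             G = matrix(as.numeric(doc$G), length(doc$random_names),
                        dimnames = list(doc$random_names, doc$random_names)),
             sigma2 = doc$sigma2,
             beta_centered = stats::setNames(as.numeric(doc$beta_centered),
                                             doc$term_names),
             Vbeta_centered = matrix(as.numeric(doc$Vbeta_centered),
                                     length(doc$term_names)),
             G_centered = matrix(as.numeric(doc$G_centered),
                                 length(doc$random_names)),
             loglik = doc$loglik, deviance = doc$deviance,
             estimator = doc$estimator,
             converged = doc$converged, singular = doc$singular,
             n_obs = doc$n_obs, n_subjects = doc$n_subjects,
             n_dropped = doc$n_dropped,
             term_names = doc$term_names, block = doc$block,
             random_names = doc$random_names,
             spec = spec, encoding = enc,
             time_range = as.numeric(doc$time_range),
             dm = NULL)
  class(fm) <- "trajlmm"
  if (!is.null(data)) {
    fm$dm <- build_design(data, spec, encoding = enc)
  }
  fm
}
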
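#' Read and write pipeline artifacts
#'
#' All tabular artifacts are plain CSV with documented headers; the
#' generator configuration is YAML; fitted models are JSON. A cohort CSV has
#' the header `subject_id,sex,group,age,iq,ses,site,` followed by the 20
#' feature ids in [feature_schema()] order.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return The input (writers, invisibly) or the parsed object (readers).
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[c(cohort_id_cols(), schema_ids())]
  out$site <- as.integer(as.character(out$site))
  readr::write_csv(out, path)
  invisible(cohort)
}

#' @rdname cohort_io
#' @param n_sites Number of site levels to type the `site` column with;
#'   inferred from the file when `NULL`.
#' @export
read_cohort <- function(path, n_sites = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(raw, n_sites = n_sites)
}

#' @rdname cohort_io
#' @export
write_feature_schema <- function(path) {
  readr::write_csv(feature_schema(), path)
  invisible(path)
}

#' Write or read a generator configuration as YAML
#' @param config A `cohort_config`.
#' @param path File path.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$stratum_sizes <- as.list(x$stratum_sizes)
  x$correlation <- as.list(x$correlation)
  x$covariate_group_shifts <- as.list(x$covariate_group_shifts)
  x$deficit_patterns <- lapply(x$deficit_patterns, as.list)
  yaml::write_yaml(x, path)
  invisible(config)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  generator_config(
    stratum_sizes = unlist(x$stratum_sizes),
    n_sites = x$n_sites,
    correlation = unlist(x$correlation),
    covariate_effects = list(
      age = unlist(x$covariate_effects$age),
      iq = unlist(x$covariate_effects$iq),
      ses = unlist(x$covariate_effects$ses),
      site_offsets = unlist(x$covariate_effects$site_offsets)),
    covariate_group_shifts = unlist(x$covariate_group_shifts),
    deficit_patterns = lapply(x$deficit_patterns, unlist),
    deficit_prevalence = x$deficit_prevalence,
    scale_intercept = x$scale_intercept,
    scale_slope = x$scale_slope,
    seed = x$seed)
}

#' Write per-repetition resampling results as tidy CSV
#'
#' One row per repetition with the index, retention flag, in-sample wACC,
#' the five test metrics, and the 20 relevance columns. The train/test
#' membership list columns are serialized as `;`-separated id strings.
#'
#' @param results A [holdout_resample()] tibble.
#' @param path File path.
#' @param include_ids Include train/test membership columns (default FALSE).
#' @export
write_resampling_results <- function(results, path, include_ids = FALSE) {
  out <- results[setdiff(names(results), c("train_ids", "test_ids"))]
  if (include_ids) {
    out$train_ids <- vapply(results$train_ids, paste, "", collapse = ";")
    out$test_ids <- vapply(results$test_ids, paste, "", collapse = ";")
  }
  readr::write_csv(out, path)
  invisible(results)
}

#' @rdname write_resampling_results
#' @export
read_resampling_results <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("train_ids", "test_ids")) {
    if (col %in% names(out)) out[[col]] <- strsplit(out[[col]], ";")
  }
  class(out) <- c("resampling_results", class(out))
  out
}

#' Serialize a fitted Angle-GMLVQ model to JSON
#'
#' Stores the feature order, prototypes with class labels, the relevance
#' transform, relevance scores, hyperparameters, seed and training history,
#' so a fit can be archived and reloaded without refitting.
#'
#' @param model An `angle_gmlvq` model.
#' @param path File path.
#' @export
write_gmlvq <- function(model, path) {
  stopifnot(inherits(model, "angle_gmlvq"))
  payload <- list(
    format = "cdlvq/angle_gmlvq@1",
    features = model$features,
    classes = model$classes,
    prototype_class = model$prototype_class,
    prototypes = apply(model$prototypes, 1, identity, simplify = FALSE),
    omega = apply(model$omega, 1, identity, simplify = FALSE),
    relevance_scores = as.list(model$relevance_scores),
    in_sample_wacc = model$in_sample_wacc,
    training_history = model$training_history,
    converged = model$converged,
    control = unclass(model$control))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(model)
}

#' @rdname write_gmlvq
#' @export
read_gmlvq <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_matrix <- function(m) if (is.matrix(m)) m else do.call(rbind, m)
  omega <- to_matrix(x$omega)
  prot <- to_matrix(x$prototypes)
  ctrl <- do.call(gmlvq_control, x$control)
  structure(
    list(prototypes = prot,
         prototype_class = x$prototype_class,
         omega = omega,
         lambda = crossprod(omega),
         relevance_scores = stats::setNames(unlist(x$relevance_scores),
                                            x$features),
         classes = x$classes,
         features = x$features,
         training_history = x$training_history,
         converged = x$converged,
         control = ctrl,
         in_sample_wacc = x$in_sample_wacc),
    class = "angle_gmlvq")
}
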
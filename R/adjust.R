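#' Residualize and standardize the feature scores within a sex stratum
#'
#' Because covariates cannot be entered into a prototype classifier directly,
#' every raw score is adjusted before classification: each of the 20 feature
#' columns is regressed (ordinary least squares) on age, IQ and SES
#' (continuous) and site (dummy-coded categorical, first site as reference)
#' over the pooled case + control stratum, and the residuals are divided by
#' their standard deviation. The result is a matrix of covariate-adjusted
#' z-scores with, per column, mean 0 and SD 1 over the fitting sample, and
#' zero sample correlation with every fitted covariate.
#'
#' The group label is never part of the regression, so no information about
#' the classification target leaks into preprocessing. The adjustment is
#' fitted once on the full stratum, before any train/test resampling; this
#' mirrors an adjust-then-classify order of operations and is a known (mild)
#' optimism source, discussed in the package vignette.
#'
#' @param cohort A cohort tibble as returned by [simulate_cohort()] or
#'   [read_cohort()] (columns `subject_id`, `sex`, `group`, `age`, `iq`,
#'   `ses`, `site`, then the 20 features).
#' @param sex Stratum to adjust: `"female"` or `"male"`. Use `NULL` only if
#'   the cohort already contains a single sex.
#' @return A tibble of class `adjusted_features` with columns `subject_id`,
#'   `group` and the 20 adjusted feature columns, rows in input order.
#'   Attributes: `sex`, `fit_info` (per-feature coefficient tibble and
#'   residual SD), `schema`.
#' @examples
#' cohort <- simulate_cohort(default_calibration("female"), seed = 1)
#' adj <- adjust_features(cohort, "female")
#' round(colMeans(as.matrix(adj[feature_schema()$feature_id])), 10)
#' @export
adjust_features <- function(cohort, sex = NULL) {
  ids <- schema_ids()
  missing_cols <- setdiff(c(cohort_id_cols(), ids), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  if (is.null(sex)) {
    sexes <- unique(cohort$sex)
    if (length(sexes) != 1) {
      stop("cohort contains ", length(sexes),
           " sexes; pass `sex` to select the stratum", call. = FALSE)
    }
    sex <- sexes
  }
  dat <- cohort[cohort$sex == sex, , drop = FALSE]
  if (nrow(dat) < 2) {
    stop("fewer than 2 subjects in the '", sex, "' stratum", call. = FALSE)
  }

  covars <- c("age", "iq", "ses", "site")
  bad <- vapply(covars, function(v) any(is.na(dat[[v]])), logical(1))
  if (any(bad)) {
    offenders <- dat$subject_id[rowSums(is.na(dat[covars])) > 0]
    stop("missing covariate values (no imputation is performed) for ",
         "subjects: ", paste(utils::head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) " ..." else "", call. = FALSE)
  }

  site <- factor(dat$site)
  site <- droplevels(site)
  X <- stats::model.matrix(~ age + iq + ses + site,
                           data = data.frame(age = dat$age, iq = dat$iq,
                                             ses = dat$ses, site = site))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular covariate design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  Y <- as.matrix(dat[ids])
  if (any(!is.finite(Y))) {
    stop("non-finite feature values in the '", sex, "' stratum",
         call. = FALSE)
  }
  coefs <- qr.coef(qrX, Y)
  resid <- Y - X %*% coefs
  sds <- apply(resid, 2, stats::sd)
  if (any(sds < 1e-12)) {
    stop("zero residual variance for feature(s): ",
         paste(ids[sds < 1e-12], collapse = ", "), call. = FALSE)
  }
  Z <- sweep(resid, 2, sds, "/")
  colnames(Z) <- ids

  fit_info <- tibble::tibble(
    feature_id = ids,
    residual_sd = unname(sds),
    coefficients = lapply(seq_along(ids), function(j) {
      stats::setNames(coefs[, j], colnames(X))
    }))

  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = dat$subject_id, group = dat$group),
    tibble::as_tibble(Z))
  class(out) <- c("adjusted_features", class(out))
  attr(out, "sex") <- sex
  attr(out, "fit_info") <- fit_info
  attr(out, "schema") <- feature_schema()
  out
}

#' Extract the feature matrix and labels from an adjusted stratum
#' @param adjusted An `adjusted_features` tibble.
#' @return List with `X` (n x 20 numeric matrix), `y` (character labels) and
#'   `subject_id`.
#' @keywords internal
adjusted_matrix <- function(adjusted) {
  ids <- schema_ids()
  list(X = as.matrix(adjusted[ids]),
       y = adjusted$group,
       subject_id = adjusted$subject_id)
}
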
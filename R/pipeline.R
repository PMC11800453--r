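#' Validate a cohort table against the battery's schema contract
#'
#' Checks the header contract (`subject_id,sex,group,age,iq,ses,site` plus
#' the 20 feature ids), value ranges (age 9-18 years, IQ >= 70, scores in
#' \[0, 100\]), label domains (`sex` in female/male, `group` in CD/control),
#' subject-id uniqueness and completeness, and returns a typed cohort tibble
#' (site coerced to factor) or the itemized list of violations.
#'
#' @param x A data frame, or a path to a cohort CSV.
#' @param n_sites Number of site levels; inferred from the data if `NULL`.
#' @param stop_on_error If `TRUE` (default) violations raise an error; if
#'   `FALSE` they are returned as a character vector (empty when valid).
#' @return The validated cohort tibble, or (with `stop_on_error = FALSE`)
#'   a character vector of violations.
#' @export
validate_cohort <- function(x, n_sites = NULL, stop_on_error = TRUE) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  ids <- schema_ids()
  required <- c(cohort_id_cols(), ids)
  violations <- character()
  add <- function(msg) violations <<- c(violations, msg)

  missing_cols <- setdiff(required, names(x))
  for (mc in missing_cols) add(paste0("missing column: ", mc))

  if (length(missing_cols) == 0) {
    if (anyDuplicated(x$subject_id) > 0) {
      dup <- unique(x$subject_id[duplicated(x$subject_id)])
      add(paste0("duplicate subject_id: ",
                 paste(utils::head(dup, 5), collapse = ", ")))
    }
    bad_sex <- setdiff(unique(x$sex), c("female", "male"))
    if (length(bad_sex) > 0) {
      add(paste0("invalid sex value(s): ", paste(bad_sex, collapse = ", ")))
    }
    bad_grp <- setdiff(unique(x$group), c("CD", "control"))
    if (length(bad_grp) > 0) {
      add(paste0("invalid group value(s): ", paste(bad_grp, collapse = ", ")))
    }
    check_range <- function(col, lo, hi, what) {
      v <- x[[col]]
      if (any(is.na(v))) {
        add(paste0("missing values in ", col))
        v <- v[!is.na(v)]
      }
      out <- v < lo | v > hi
      if (any(out)) {
        add(paste0(sum(out), " ", col, " value(s) outside ", what,
                   " (first offending value: ", format(v[out][1]), ")"))
      }
    }
    check_range("age", 9, 18, "the 9-18 year study range")
    check_range("iq", 70, Inf, "the IQ >= 70 inclusion bound")
    if (any(is.na(x$ses))) add("missing values in ses")
    if (any(is.na(x$site))) add("missing values in site")
    for (fid in ids) check_range(fid, 0, 100, "the percent scale [0, 100]")
  }

  if (length(violations) > 0) {
    if (stop_on_error) {
      stop("cohort validation failed:\n  - ",
           paste(violations, collapse = "\n  - "), call. = FALSE)
    }
    return(violations)
  }
  out <- tibble::as_tibble(x[required])
  levels <- if (is.null(n_sites)) sort(unique(as.integer(as.character(out$site))))
            else seq_len(n_sites)
  out$site <- factor(as.integer(as.character(out$site)), levels = levels)
  out
}

#' Run the full sex-stratified classification analysis
#'
#' The end-to-end pipeline: simulate (or accept) a cohort, then for each
#' requested sex stratum residualize the features, run the repeated holdout
#' evaluation, summarize model performance, and rank features; finally
#' compare the female and male models. All randomness derives
#' deterministically from `seed`, so two runs with the same inputs are
#' numerically identical. When `out_dir` is given, every artifact is written
#' there: per-repetition CSVs, summary CSVs, ranking CSVs, the comparison
#' CSV, one serialized exemplar model per sex (fitted on the full stratum),
#' and a JSON run log with the seed, a config hash, and package versions.
#'
#' @param config A `cohort_config` used to simulate the cohort; ignored if
#'   `cohort` is supplied.
#' @param cohort Optional cohort tibble (or CSV path), validated before use.
#' @param sexes Strata to analyze; default both.
#' @param n_resamplings,test_fraction,stratified Passed to
#'   [holdout_resample()].
#' @param control A [gmlvq_control()].
#' @param top_k,wacc_threshold Passed to [rank_features()].
#' @param out_dir Optional output directory (created if needed).
#' @param seed Global seed fanned out to the simulation and to each
#'   stratum's resampling run via a deterministic child-seed scheme.
#' @param verbose Emit progress messages (default TRUE).
#' @return A list of class `cdlvq_run`: `cohort`, per-sex entries (each with
#'   `adjusted`, `results`, `summary`, `ranking`, `model`), `comparison`
#'   (`NULL` with a logged notice when fewer than two sexes were analyzed),
#'   and `manifest` (seed, config hash, file paths, versions).
#' @export
run_full_analysis <- function(config = generator_config(),
                              cohort = NULL,
                              sexes = c("female", "male"),
                              n_resamplings = 500,
                              test_fraction = 0.2,
                              stratified = TRUE,
                              control = gmlvq_control(),
                              top_k = 5,
                              wacc_threshold = 0.6,
                              out_dir = NULL,
                              seed = 1L,
                              verbose = TRUE) {
  sexes <- match.arg(sexes, c("female", "male"), several.ok = TRUE)
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- if (is.null(cohort)) {
    say("simulating cohort (seed ", child_seed(seed, 1), ")")
    stage("simulate", simulate_cohort(config, seed = child_seed(seed, 1)))
  } else {
    stage("validate", validate_cohort(cohort))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  per_sex <- list()
  for (i in seq_along(sexes)) {
    sx <- sexes[i]
    say("stratum '", sx, "': adjust + ", n_resamplings, " resamplings")
    adj <- stage(paste0("adjust/", sx), adjust_features(cohort, sx))
    res <- stage(paste0("evaluate/", sx),
                 holdout_resample(adj, n_resamplings = n_resamplings,
                                  test_fraction = test_fraction,
                                  stratified = stratified,
                                  seed = child_seed(seed, 1 + i),
                                  control = control))
    smry <- stage(paste0("summarize/", sx), summarize_model(res))
    rnk <- stage(paste0("rank/", sx),
                 rank_features(res, top_k = top_k,
                               wacc_threshold = wacc_threshold))
    ctrl <- control
    ctrl$seed <- child_seed(seed, 10 + i)
    exemplar <- stage(paste0("fit/", sx), angle_gmlvq(adj, control = ctrl))
    per_sex[[sx]] <- list(adjusted = adj, results = res, summary = smry,
                          ranking = rnk, model = exemplar)
    if (!is.null(out_dir)) {
      write_resampling_results(res, file.path(out_dir,
                                              paste0("results_", sx, ".csv")))
      readr::write_csv(smry$metrics,
                       file.path(out_dir, paste0("summary_", sx, ".csv")))
      readr::write_csv(tibble::as_tibble(rnk),
                       file.path(out_dir, paste0("ranking_", sx, ".csv")))
      write_gmlvq(exemplar, file.path(out_dir, paste0("model_", sx, ".json")))
    }
  }

  comparison <- NULL
  if (length(sexes) == 2) {
    say("comparing female vs male models")
    comparison <- stage("compare",
                        compare_models(per_sex$female$results,
                                       per_sex$male$results))
    if (!is.null(out_dir)) {
      readr::write_csv(tibble::as_tibble(comparison),
                       file.path(out_dir, "comparison.csv"))
    }
  } else {
    say("comparison stage skipped: only one sex analyzed")
  }

  manifest <- list(
    seed = as.integer(seed),
    config_hash = rlang::hash(config),
    sexes = sexes,
    n_resamplings = n_resamplings,
    test_fraction = test_fraction,
    package_version = as.character(utils::packageVersion("cdlvq")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  structure(c(list(cohort = cohort), per_sex,
              list(comparison = comparison, manifest = manifest)),
            class = "cdlvq_run")
}

#' @export
print.cdlvq_run <- function(x, ...) {
  cat("<cdlvq_run> seed", x$manifest$seed, "|",
      paste(x$manifest$sexes, collapse = " + "), "|",
      x$manifest$n_resamplings, "resamplings per stratum\n")
  for (sx in x$manifest$sexes) {
    m <- x[[sx]]$summary$metrics
    w <- m[m$metric == "wacc", ]
    cat(sprintf("  %-6s mean wACC %.3f [%.3f, %.3f], retained %d/%d\n",
                sx, w$mean, w$ci_lower, w$ci_upper,
                x[[sx]]$summary$n_retained, x[[sx]]$summary$n_resamplings))
  }
  if (!is.null(x$comparison)) {
    w <- x$comparison[x$comparison$metric == "wacc", ]
    cat(sprintf("  female vs male wACC: p = %s, r = %.2f\n",
                format.pval(w$p_value, digits = 3, eps = 1e-16),
                w$effect_size_r))
  }
  invisible(x)
}
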
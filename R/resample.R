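#' Repeated holdout evaluation of the Angle-GMLVQ classifier
#'
#' The resampling engine behind the per-sex models: for each of
#' `n_resamplings` repetitions it draws a fresh random train/test split of
#' the adjusted stratum, fits an Angle-GMLVQ classifier on the training
#' part, predicts the held-out part, and records the confusion-matrix
#' metrics, the normalized relevance vector, the in-sample (training) wACC,
#' and the retention flag `retained = in_sample_wacc >= 0.5`. Retention
#' consults training data only, so no information leaks from the test set
#' into the decision of which relevance profiles to keep.
#'
#' Splits are stratified by default: each class contributes its own rounded
#' share of `test_fraction`, keeping test-set class proportions within one
#' subject of the stratum's. Every repetition gets a deterministic child
#' seed derived from `seed`, so the whole run is reproducible and any single
#' repetition can be reproduced in isolation.
#'
#' @param adjusted An [adjust_features()] result (or any tibble with
#'   `subject_id`, `group` and the schema feature columns).
#' @param n_resamplings Number of holdout repetitions; default 500.
#' @param test_fraction Fraction of each class held out; default 0.2.
#' @param stratified Stratify the split by class (default `TRUE`).
#' @param seed Integer master seed for the run.
#' @param control [gmlvq_control()] passed to each fit; its `seed` is
#'   replaced by the repetition's child seed so prototype jitter varies
#'   across repetitions.
#' @param positive_class Positive class for the metrics (default `"CD"`).
#' @return A tibble of class `resampling_results` with one row per
#'   repetition: `resampling`, `n_train`, `n_test`, `in_sample_wacc`,
#'   `retained`, `wacc`, `ppv`, `npv`, `tpr`, `tnr`, the 20 relevance
#'   columns `rel_<feature_id>`, and list columns `train_ids`, `test_ids`.
#' @examples
#' \donttest{
#' adj <- adjust_features(
#'   simulate_cohort(default_calibration("female"), seed = 1), "female")
#' res <- holdout_resample(adj, n_resamplings = 5, seed = 1)
#' res[, c("resampling", "in_sample_wacc", "retained", "wacc")]
#' }
#' @export
holdout_resample <- function(adjusted, n_resamplings = 500,
                             test_fraction = 0.2, stratified = TRUE,
                             seed = 1L, control = gmlvq_control(),
                             positive_class = "CD") {
  stopifnot(n_resamplings >= 1, test_fraction > 0, test_fraction < 1)
  am <- adjusted_matrix(adjusted)
  classes <- sort(unique(am$y), method = "radix")
  if (length(classes) != 2) {
    stop("exactly two classes required in `adjusted$group`", call. = FALSE)
  }
  n <- nrow(am$X)
  ids <- schema_ids()

  rows <- vector("list", n_resamplings)
  for (r in seq_len(n_resamplings)) {
    child <- child_seed(seed, r)
    set.seed(child)
    test_idx <- draw_test_indices(am$y, classes, test_fraction, stratified)
    train_idx <- setdiff(seq_len(n), test_idx)
    y_tr <- am$y[train_idx]
    y_te <- am$y[test_idx]
    if (length(unique(y_te)) < 2 || any(table(y_tr) < 2)) {
      stop("repetition ", r, ": split left a class empty or with < 2 ",
           "training subjects", call. = FALSE)
    }

    ctrl <- control
    ctrl$seed <- child
    fit <- tryCatch(
      fit_gmlvq_matrix(am$X[train_idx, , drop = FALSE], y_tr, ctrl, ids),
      error = function(e) {
        stop("repetition ", r, ": ", conditionMessage(e), call. = FALSE)
      })
    pred <- predict(fit, am$X[test_idx, , drop = FALSE])
    met <- compute_metrics(y_te, pred, positive_class)
    rel <- as.list(fit$relevance_scores)
    names(rel) <- paste0("rel_", ids)

    rows[[r]] <- tibble::tibble(
      resampling = r,
      n_train = length(train_idx),
      n_test = length(test_idx),
      in_sample_wacc = fit$in_sample_wacc,
      retained = fit$in_sample_wacc >= 0.5,
      !!!met,
      !!!rel,
      train_ids = list(am$subject_id[train_idx]),
      test_ids = list(am$subject_id[test_idx]))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("resampling_results", class(out))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "spec") <- list(n_resamplings = n_resamplings,
                            test_fraction = test_fraction,
                            stratified = stratified)
  attr(out, "sex") <- attr(adjusted, "sex")
  out
}

# Deterministic child seed for repetition r; kept inside 32-bit range.
child_seed <- function(seed, r) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(r)) %% 2147483629)
}

draw_test_indices <- function(y, classes, test_fraction, stratified) {
  if (stratified) {
    unlist(lapply(classes, function(cl) {
      idx <- which(y == cl)
      n_te <- max(1L, round(test_fraction * length(idx)))
      sample(idx, n_te)
    }), use.names = FALSE)
  } else {
    sample(length(y), max(1L, round(test_fraction * length(y))))
  }
}

#' Summarize a resampling run into model-level performance
#'
#' Produces the per-model summary: for each metric, the mean over all
#' repetitions with a 95 percent t-based confidence interval (undefined
#' entries excluded and counted); an exact two-sided binomial test of the
#' number of repetitions whose test wACC exceeds 0.5 against chance
#' (repetitions landing exactly at 0.5 are uninformative about direction
#' and are excluded from the trial count, sign-test style), with
#' Cohen's *g* (that proportion minus 0.5) as its effect size; and the mean
#' relevance profile over *retained* repetitions only -- the in-sample
#' retention rule gates relevance aggregation, not the performance summary.
#'
#' @param results A [holdout_resample()] tibble.
#' @param conf_level Confidence level for the CIs; default 0.95.
#' @return An object of class `model_summary`: list with `metrics` (tibble:
#'   `metric`, `mean`, `ci_lower`, `ci_upper`, `n_used`, `n_undefined`),
#'   `chance_test` (tibble: `k`, `n`, `n_at_chance`, `proportion`,
#'   `cohens_g`, `p_value`),
#'   `relevance` (tibble over retained repetitions), `n_resamplings`,
#'   `n_retained`, `sex`.
#' @export
summarize_model <- function(results, conf_level = 0.95) {
  metric_names <- c("wacc", "ppv", "npv", "tpr", "tnr")
  stopifnot(all(metric_names %in% names(results)))
  if (nrow(results) < 2) {
    stop("need >= 2 resampling results to summarize", call. = FALSE)
  }
  if (all(is.na(results$wacc))) {
    stop("all test metrics undefined; nothing to summarize", call. = FALSE)
  }

  alpha <- 1 - conf_level
  metrics <- purrr::map_dfr(metric_names, function(m) {
    v <- results[[m]]
    ok <- !is.na(v)
    v <- v[ok]
    se <- stats::sd(v) / sqrt(length(v))
    half <- stats::qt(1 - alpha / 2, df = length(v) - 1) * se
    tibble::tibble(metric = m, mean = mean(v),
                   ci_lower = mean(v) - half, ci_upper = mean(v) + half,
                   n_used = length(v), n_undefined = sum(!ok))
  })

  # sign-test convention: repetitions landing exactly at chance carry no
  # information about the direction and are excluded from the trial count
  wacc <- results$wacc[!is.na(results$wacc)]
  k <- sum(wacc > 0.5)
  n <- sum(wacc != 0.5)
  bt <- stats::binom.test(k, max(n, 1), p = 0.5, alternative = "two.sided")
  chance <- tibble::tibble(k = k, n = n,
                           n_at_chance = sum(wacc == 0.5),
                           proportion = if (n > 0) k / n else NA_real_,
                           cohens_g = if (n > 0) k / n - 0.5 else NA_real_,
                           p_value = if (n > 0) bt$p.value else 1)

  retained <- results[results$retained, , drop = FALSE]
  rel_cols <- paste0("rel_", schema_ids())
  relevance <- if (nrow(retained) > 0) {
    R <- as.matrix(retained[rel_cols])
    tibble::tibble(feature_id = schema_ids(),
                   domain = unname(schema_domains()[schema_ids()]),
                   mean_relevance = colMeans(R),
                   sd_relevance = apply(R, 2, stats::sd))
  } else {
    tibble::tibble(feature_id = schema_ids(),
                   domain = unname(schema_domains()[schema_ids()]),
                   mean_relevance = NA_real_, sd_relevance = NA_real_)
  }

  structure(list(metrics = metrics,
                 chance_test = chance,
                 relevance = relevance,
                 n_resamplings = nrow(results),
                 n_retained = nrow(retained),
                 sex = attr(results, "sex")),
            class = "model_summary")
}

#' @export
print.model_summary <- function(x, digits = 2, ...) {
  cat("<model_summary>", x$n_resamplings, "resamplings,", x$n_retained,
      "retained", if (!is.null(x$sex)) paste0("(", x$sex, " stratum)"), "\n")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-5s %.2f [%.2f, %.2f]%s\n", m$metric[i], m$mean[i],
                m$ci_lower[i], m$ci_upper[i],
                if (m$n_undefined[i] > 0)
                  paste0("  (", m$n_undefined[i], " undefined)") else ""))
  }
  ct <- x$chance_test
  cat(sprintf("  chance test: %d/%d above 0.5, Cohen's g = %.2f, p %s\n",
              ct$k, ct$n, ct$cohens_g,
              format.pval(ct$p_value, digits = 3, eps = 1e-16)))
  invisible(x)
}

#' @rdname summarize_model
#' @param x A `model_summary`.
#' @param ... Unused.
#' @method tidy model_summary
#' @export
tidy.model_summary <- function(x, ...) x$metrics

#' @rdname summarize_model
#' @method glance model_summary
#' @export
glance.model_summary <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_resamplings = x$n_resamplings,
                   n_retained = x$n_retained),
    x$chance_test)
}
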
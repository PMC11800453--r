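#' Rank features by top-5 membership across resamplings
#'
#' Aggregates the per-repetition relevance vectors into the feature-ranking
#' table: for each feature, the percentage of resamplings in which it was
#' among the `top_k` highest-relevance features of a classifier that reached
#' a test wACC of at least `wacc_threshold`. Only repetitions retained by
#' the in-sample rule enter the computation; by default the denominator is
#' the number of retained repetitions, so a low percentage reflects both the
#' rarity of sufficiently accurate classifiers and the rarity of top-`k`
#' membership (set `denominator = "qualifying"` to divide by the number of
#' repetitions above the wACC threshold instead).
#'
#' Relevance ranks are by descending score; ties are broken deterministically
#' by schema order.
#'
#' @param results A [holdout_resample()] tibble.
#' @param top_k Number of top-scoring features that count (default 5).
#' @param wacc_threshold Test-wACC threshold a repetition must reach for its
#'   top features to count (default 0.6).
#' @param denominator `"retained"` (default) or `"qualifying"`.
#' @return A tibble of class `ranking_table`: `feature_id`, `domain`,
#'   `n_top` (numerator), `n_retained`, `n_qualifying`, `denominator`,
#'   `percentage` in \[0, 100\], sorted in schema order.
#' @export
rank_features <- function(results, top_k = 5, wacc_threshold = 0.6,
                          denominator = c("retained", "qualifying")) {
  denominator <- match.arg(denominator)
  retained <- results[results$retained, , drop = FALSE]
  if (nrow(retained) == 0) stop("no retained resamplings", call. = FALSE)

  ids <- schema_ids()
  R <- as.matrix(retained[paste0("rel_", ids)])
  qualifies <- !is.na(retained$wacc) & retained$wacc >= wacc_threshold
  if (!any(qualifies)) {
    warning("no retained resampling reached wACC >= ", wacc_threshold,
            "; all percentages are 0", call. = FALSE)
  }

  # rank by descending relevance, ties broken by schema (column) order
  n_top <- integer(length(ids))
  for (i in which(qualifies)) {
    ord <- order(-R[i, ], seq_along(ids))
    n_top[ord[seq_len(min(top_k, length(ids)))]] <-
      n_top[ord[seq_len(min(top_k, length(ids)))]] + 1L
  }

  denom <- if (denominator == "retained") nrow(retained) else sum(qualifies)
  out <- tibble::tibble(
    feature_id = ids,
    domain = unname(schema_domains()[ids]),
    n_top = n_top,
    n_retained = nrow(retained),
    n_qualifying = sum(qualifies),
    denominator = denom,
    percentage = if (denom > 0) 100 * n_top / denom else 0)
  class(out) <- c("ranking_table", class(out))
  attr(out, "top_k") <- top_k
  attr(out, "wacc_threshold") <- wacc_threshold
  out
}

#' Compare the female and male models metric by metric
#'
#' Two-sided Mann-Whitney U tests on the per-repetition distributions of
#' each performance metric, female versus male model, with the effect size
#' \eqn{r = |Z| / \sqrt{n_1 + n_2}} (0.1 / 0.3 / 0.5 conventionally read as
#' small / medium / large). The p-value uses exact enumeration when both
#' samples have fewer than 20 defined values and no ties are present, and
#' the normal approximation with tie correction otherwise; `Z` (and hence
#' `r`) always comes from the tie-corrected normal approximation.
#'
#' Repetitions are treated as exchangeable draws from each model's
#' performance distribution. Because holdout resamples overlap, they are not
#' independent, so this comparison is anti-conservative; see the vignette.
#'
#' @param results_female,results_male [holdout_resample()] tibbles for the
#'   two strata.
#' @param metrics Which metric columns to compare.
#' @return A tibble of class `model_comparison`: `metric`, `n_female`,
#'   `n_male`, `statistic` (U for the female sample), `z`, `p_value`,
#'   `effect_size_r`.
#' @export
compare_models <- function(results_female, results_male,
                           metrics = c("wacc", "ppv", "npv", "tpr", "tnr")) {
  if (nrow(results_female) == 0 || nrow(results_male) == 0) {
    stop("both result sets must be non-empty", call. = FALSE)
  }
  out <- purrr::map_dfr(metrics, function(m) {
    x <- results_female[[m]]
    y <- results_male[[m]]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) {
      stop("metric '", m, "' is undefined in every repetition of one model",
           call. = FALSE)
    }
    mw <- mann_whitney(x, y)
    tibble::tibble(metric = m, n_female = length(x), n_male = length(y),
                   statistic = mw$U, z = mw$z, p_value = mw$p,
                   effect_size_r = mw$r)
  })
  class(out) <- c("model_comparison", class(out))
  out
}

# Two-sided Mann-Whitney U with tie-corrected normal Z; exact p for small
# untied samples.
mann_whitney <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  z <- if (sigma2 > 0) (U - n1 * n2 / 2) / sqrt(sigma2) else 0
  use_exact <- n1 < 20 && n2 < 20 && tie_term == 0
  p <- if (use_exact) {
    stats::wilcox.test(x, y, exact = TRUE,
                       alternative = "two.sided")$p.value
  } else if (sigma2 > 0) {
    min(1, 2 * stats::pnorm(-abs(z)))
  } else {
    1
  }
  list(U = unname(U), z = z, p = p, r = abs(z) / sqrt(N))
}
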
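#' The 20-feature emotion-processing test battery schema
#'
#' Returns the fixed schema of the neurocognitive feature set used throughout
#' the package: 20 subject-level performance scores, all expressed as error
#' percentages in \[0, 100\], drawn from three tasks that probe three emotion
#' skill domains:
#'
#' * **Emotion Hexagon** (emotion *recognition*): per-expression recognition
#'   error for happiness, sadness, anger, fear, disgust and surprise
#'   (6 features).
#' * **Passive Avoidance Learning** (emotion *learning*): omission errors to
#'   reward stimuli and avoidance errors to punishment stimuli, at incentive
#'   magnitudes 1, 700, 1400 and 2000 points (8 features).
#' * **Emotional Go/Nogo** (emotion *regulation*): false-alarm errors for six
#'   go/nogo expression pairings -- neutral-happy, neutral-fearful,
#'   happy-neutral, fearful-neutral, happy-fearful and fearful-happy
#'   (6 features).
#'
#' Feature order in this table defines the canonical column order of every
#' score matrix in the package and the deterministic tie-break order used in
#' relevance ranking.
#'
#' @return A tibble with columns `feature_id`, `domain` (one of
#'   `"recognition"`, `"learning"`, `"regulation"`), `task` (one of
#'   `"hexagon"`, `"passive_avoidance"`, `"emotional_gonogo"`),
#'   `description`, and `unit` (always `"percent-error"`), with 20 rows.
#' @examples
#' feature_schema()
#' @export
feature_schema <- function() {
  emotions <- c("happy", "sad", "anger", "fear", "disgust", "surprise")
  magnitudes <- c(1, 700, 1400, 2000)
  blocks <- c("neutral_happy", "neutral_fearful", "happy_neutral",
              "fearful_neutral", "happy_fearful", "fearful_happy")

  hexagon <- tibble::tibble(
    feature_id = paste0("hex_", emotions),
    domain = "recognition",
    task = "hexagon",
    description = paste0("Recognition errors (%) for '", emotions,
                         "' facial expressions")
  )
  pal <- tibble::tibble(
    feature_id = c(paste0("pal_omission_", magnitudes),
                   paste0("pal_avoidance_", magnitudes)),
    domain = "learning",
    task = "passive_avoidance",
    description = c(
      paste0("Omission errors (%) to reward stimuli worth ", magnitudes,
             " points"),
      paste0("Avoidance errors (%) to punishment stimuli worth ", magnitudes,
             " points"))
  )
  gonogo <- tibble::tibble(
    feature_id = paste0("gng_", blocks),
    domain = "regulation",
    task = "emotional_gonogo",
    description = paste0("False-alarm errors (%) in go/nogo block ",
                         gsub("_", "-", blocks))
  )
  out <- dplyr::bind_rows(hexagon, pal, gonogo)
  out$unit <- "percent-error"
  out
}

# Internal accessors used throughout; cheap enough to recompute.
schema_ids <- function() feature_schema()$feature_id

schema_domains <- function() {
  sc <- feature_schema()
  stats::setNames(sc$domain, sc$feature_id)
}

#' @keywords internal
cohort_id_cols <- function() {
  c("subject_id", "sex", "group", "age", "iq", "ses", "site")
}
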
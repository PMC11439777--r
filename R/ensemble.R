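# Test-time-augmentation ensemble scoring and the threshold-corrected
# decision rule. A trained network is biased toward the healthy class when
# scored naively; classifying R randomly augmented replicates and requiring
# a healthy-vote fraction of at least 0.8 (equivalently, calling any image
# with more than 20% infected votes infected) corrects that bias.

#' Score one image by repeated augmented classification
#'
#' Classifies `R` augmented replicates of the image and counts healthy
#' votes. Deterministic per `(image, mode, R, seed)`; under mode `"none"`
#' the replicates are identical so the score is exactly 0 or 1.
#'
#' @param object a `phyto_classifier`, or a function of an image returning
#'   either a label or a `(healthy, infected)` probability vector (useful
#'   for stubs and external models).
#' @param image H x W x 3 array in `[0, 1]`.
#' @param mode augmentation mode name or [augment_config()].
#' @param R replicate count (>= 1, default 32).
#' @param seed integer seed; replicate r uses the derived seed
#'   `derive_seed(seed, r)`.
#' @param id optional image identifier carried into reports.
#' @return a `phyto_ensemble_score`: `id`, `mode`, `R`, `healthy_votes`,
#'   `healthy_score = healthy_votes / R`.
#' @export
tta_score <- function(object, image, mode = "strong", R = 32, seed = 0,
                      id = NA_character_) {
  if (!is.numeric(R) || length(R) != 1 || R < 1 || R != round(R))
    stop_validation("R must be an integer >= 1")
  mode_name <- if (is.character(mode)) mode else "custom"
  votes <- 0L
  for (r in seq_len(R)) {
    rep_img <- augment(image, mode, seed = derive_seed(seed, r))
    lab <- if (is.function(object)) {
      res <- object(rep_img)
      if (is.character(res)) res
      else if (res[1] >= 0.5) "healthy" else "infected"
    } else classify(object, rep_img)
    if (identical(lab, "healthy")) votes <- votes + 1L
  }
  structure(list(id = id, mode = mode_name, R = as.integer(R),
                 healthy_votes = votes, healthy_score = votes / R),
            class = "phyto_ensemble_score")
}

#' Healthy-score decision rule
#'
#' An image with healthy score strictly below the threshold is called
#' infected; a score equal to the threshold is healthy (the published rule
#' is "below 80% healthy score ... as infected", so the boundary stays
#' healthy).
#'
#' @param threshold scalar in `(0, 1]`, default 0.8.
#' @return a `phyto_decision_rule`.
#' @export
decision_rule <- function(threshold = 0.8) {
  check_range(threshold, "threshold", 0, 1, lo_open = TRUE)
  structure(list(threshold = threshold), class = "phyto_decision_rule")
}

#' Apply a decision rule to an ensemble score
#'
#' @param score a `phyto_ensemble_score` or a bare healthy-score scalar.
#' @param rule a [decision_rule()].
#' @return `"healthy"` or `"infected"`.
#' @export
decide <- function(score, rule = decision_rule()) {
  s <- if (inherits(score, "phyto_ensemble_score")) score$healthy_score
       else score
  check_range(s, "healthy_score", 0, 1)
  if (s < rule$threshold) "infected" else "healthy"
}

.score_values <- function(scores) {
  if (inherits(scores, "phyto_ensemble_score")) scores <- list(scores)
  if (is.numeric(scores)) return(list(s = scores, R = NULL))
  list(s = vapply(scores, function(x) x$healthy_score, 1.0),
       R = max(vapply(scores, function(x) as.integer(x$R), 1L)))
}

#' Calibrate the decision threshold on scored images with known labels
#'
#' Exhaustive search over the vote-fraction grid `{k/R, k = 1..R}` (scores
#' are vote fractions, so intermediate thresholds add nothing; k = 0 is
#' excluded because a zero threshold is outside the rule's valid domain).
#' Returns the accuracy-maximizing threshold; ties resolve to the smallest
#' threshold.
#'
#' @param scores list of `phyto_ensemble_score`.
#' @param truth character vector of true labels, both classes present.
#' @param R grid resolution; defaults to the replicate count of the scores.
#' @return a [decision_rule()].
#' @export
calibrate_threshold <- function(scores, truth, R = NULL) {
  sv <- .score_values(scores)
  if (length(sv$s) != length(truth))
    stop_validation("scores and truth have different lengths")
  if (length(unique(truth)) < 2)
    stop_validation("truth must contain both classes")
  R <- as.integer(R %||% sv$R %||% 32L)
  grid <- seq_len(R) / R
  acc <- vapply(grid, function(t)
    mean(ifelse(sv$s < t, "infected", "healthy") == truth), 1.0)
  decision_rule(grid[which.max(acc)])  # which.max takes the first (smallest) tie
}

#' Per-image classification report under a decision rule
#'
#' @param scores list of `phyto_ensemble_score` aligned with `truth`.
#' @param truth character vector of true labels.
#' @param rule a [decision_rule()].
#' @return a list: `table` (one row per image: score, truth, decision,
#'   correctness), `overall_accuracy` (= correct / total),
#'   `overall_accuracy_pct`, `per_mode` (accuracy aggregated by
#'   augmentation mode), `rule`.
#' @export
accuracy_report <- function(scores, truth, rule = decision_rule()) {
  if (inherits(scores, "phyto_ensemble_score")) scores <- list(scores)
  if (length(scores) != length(truth))
    stop_validation("scores and truth have different lengths")
  tab <- data.frame(
    id = vapply(scores, function(x) as.character(x$id), ""),
    mode = vapply(scores, function(x) x$mode, ""),
    R = vapply(scores, function(x) as.integer(x$R), 1L),
    healthy_votes = vapply(scores, function(x) as.integer(x$healthy_votes), 1L),
    healthy_score = vapply(scores, function(x) x$healthy_score, 1.0),
    truth = truth,
    stringsAsFactors = FALSE
  )
  tab$decision <- vapply(seq_len(nrow(tab)),
                         function(i) decide(tab$healthy_score[i], rule), "")
  tab$correct <- tab$decision == tab$truth
  per_mode <- stats::aggregate(correct ~ mode, data = tab, FUN = mean)
  names(per_mode)[2] <- "accuracy"
  acc <- mean(tab$correct)
  list(table = tab, overall_accuracy = acc,
       overall_accuracy_pct = 100 * acc, per_mode = per_mode, rule = rule)
}
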
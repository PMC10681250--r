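ERROR_KINDS <- c("true_positive", "false_positive", "true_negative",
                 "false_negative")

#' Classify predictions at a fixed review period into error sets
#'
#' Partitions the hard predictions made at review period `t` into true/false
#' positives/negatives, attaching each client's full total-score trajectory
#' and final change for downstream trajectory analysis.
#'
#' @param predictions Prediction-set tibble (hard `predicted` column).
#' @param cohort An `icbt_cohort` (source of the trajectories).
#' @param t Analysis review period (default 3, a typical time at which
#'   predictions become available to supporters).
#' @param target_instrument `"phq9"` or `"gad7"`.
#' @return Tibble with one row per evaluated client: `client_id`, `kind`
#'   (factor over the four cells), `score`, `trajectory` (list column of
#'   total scores by review), `review_index` (list column), `delta` (LOCF
#'   final minus baseline).
#' @export
classify_errors <- function(predictions, cohort, t = 3L,
                            target_instrument = "phq9") {
  target_instrument <- match_instrument(target_instrument)
  at_t <- predictions[predictions$t == t, , drop = FALSE]
  rows <- purrr::map_dfr(seq_len(nrow(at_t)), function(i) {
    rec <- cohort[[at_t$client_id[[i]]]]
    keep <- which(rec$review_index <= 8L)
    traj <- if (target_instrument == "phq9") rec$phq_total[keep] else rec$gad_total[keep]
    kind <- if (at_t$predicted[[i]] && at_t$label[[i]]) {
      "true_positive"
    } else if (at_t$predicted[[i]]) {
      "false_positive"
    } else if (at_t$label[[i]]) {
      "false_negative"
    } else {
      "true_negative"
    }
    tibble::tibble(
      client_id = at_t$client_id[[i]],
      kind = kind,
      score = at_t$score[[i]],
      trajectory = list(traj),
      review_index = list(rec$review_index[keep]),
      delta = traj[[length(traj)]] - traj[[1L]]
    )
  })
  rows$kind <- factor(rows$kind, levels = ERROR_KINDS)
  rows
}

#' Summarise the trajectories of one error set
#'
#' @param error_set Rows of a [classify_errors()] result (typically one
#'   `kind`).
#' @return List with `mean_trajectory` (tibble `review_index`, `mean_total`,
#'   `n`, averaging only the clients observed at each review) and `deltas`
#'   (the final-change distribution).
#' @export
trajectory_summary <- function(error_set) {
  if (nrow(error_set) == 0L) {
    return(list(mean_trajectory = NULL, deltas = numeric()))
  }
  long <- purrr::map_dfr(seq_len(nrow(error_set)), function(i) {
    tibble::tibble(review_index = error_set$review_index[[i]],
                   total = error_set$trajectory[[i]])
  })
  mean_traj <- long |>
    dplyr::group_by(.data$review_index) |>
    dplyr::summarise(mean_total = mean(.data$total), n = dplyr::n(),
                     .groups = "drop")
  list(mean_trajectory = mean_traj, deltas = error_set$delta)
}

#' Fraction of an error set with final change near the RI threshold
#'
#' Measures the clustering of true final changes around the
#' reliable-improvement threshold change (-6 for PHQ-9, -4 for GAD-7).
#'
#' @param error_set Rows of a [classify_errors()] result.
#' @param target_instrument `"phq9"` or `"gad7"`.
#' @param window Non-negative half-width of the proximity window in score
#'   points.
#' @return Fraction in `[0, 1]`, or `NA` for an empty set.
#' @export
threshold_proximity <- function(error_set, target_instrument = "phq9",
                                window = 2L) {
  if (window < 0) {
    abort("`window` must be non-negative.", class = "icbtri_domain_error")
  }
  if (nrow(error_set) == 0L) return(NA_real_)
  thr <- -RI_DECREASE[[match_instrument(target_instrument)]]
  mean(abs(error_set$delta - thr) <= window)
}
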
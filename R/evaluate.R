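#' Confusion-matrix metrics for a prediction set
#'
#' @param predictions Tibble with logical columns `label` and `predicted`.
#' @return List with `accuracy`, `sensitivity`, `specificity`; a rate whose
#'   denominator is empty (e.g. sensitivity with no positive labels) is `NA`
#'   rather than 0.
#' @export
#' @examples
#' confusion_metrics(tibble::tibble(label = c(TRUE, TRUE, FALSE, FALSE),
#'                                  predicted = c(TRUE, FALSE, FALSE, FALSE)))
confusion_metrics <- function(predictions) {
  if (nrow(predictions) == 0L) {
    abort("empty prediction set.", class = "icbtri_domain_error")
  }
  lab <- predictions$label
  pred <- predictions$predicted
  list(
    accuracy = mean(lab == pred),
    sensitivity = if (any(lab)) mean(pred[lab]) else NA_real_,
    specificity = if (any(!lab)) mean(!pred[!lab]) else NA_real_
  )
}

#' Area under the ROC curve
#'
#' Rank-statistic form: the probability that a uniformly chosen positive
#' outscores a uniformly chosen negative, counting ties as one half.
#'
#' @param labels Logical (or 0/1) outcome labels.
#' @param scores Numeric scores.
#' @return AUROC in `[0, 1]`; `NA` when one class is absent.
#' @export
auroc <- function(labels, scores) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity at fixed specificity operating points
#'
#' For each specificity target, chooses the score threshold attaining the
#' smallest specificity still at or above the target (the most sensitive
#' admissible operating point) and reports the sensitivity there. When only
#' the degenerate all-negative threshold attains the target (e.g. all scores
#' tied), the point is flagged unattainable and its sensitivity (0) is
#' still reported.
#'
#' @param labels Logical outcome labels (both classes present).
#' @param scores Numeric scores.
#' @param spec_targets Specificity floors.
#' @return Tibble with columns `target`, `sensitivity`, `specificity`,
#'   `threshold`, `attainable`.
#' @export
sensitivity_at_specificity <- function(labels, scores,
                                       spec_targets = c(0.90, 0.95, 0.97)) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    abort("both classes must be present.", class = "icbtri_domain_error")
  }
  thresholds <- c(sort(unique(scores)), Inf)
  op <- purrr::map_dfr(thresholds, function(thr) {
    pred <- scores >= thr
    tibble::tibble(
      threshold = thr,
      sensitivity = mean(pred[labels]),
      specificity = mean(!pred[!labels])
    )
  })
  purrr::map_dfr(spec_targets, function(target) {
    ok <- op[op$specificity >= target, , drop = FALSE]
    ok <- ok[order(ok$specificity, -ok$sensitivity), , drop = FALSE]
    best <- ok[1L, ]
    tibble::tibble(
      target = target,
      sensitivity = best$sensitivity,
      specificity = best$specificity,
      threshold = best$threshold,
      attainable = is.finite(best$threshold)
    )
  })
}

metric_row <- function(predictions, spec_targets = c(0.90, 0.95, 0.97)) {
  cm <- confusion_metrics(predictions)
  two_class <- length(unique(predictions$label)) == 2L
  sas <- if (two_class) {
    sensitivity_at_specificity(predictions$label, predictions$score,
                               spec_targets)
  } else {
    NULL
  }
  out <- tibble::tibble(
    n = nrow(predictions),
    n_clients = length(unique(predictions$client_id)),
    accuracy = cm$accuracy,
    sensitivity = cm$sensitivity,
    specificity = cm$specificity,
    auroc = if (two_class) auroc(predictions$label, predictions$score) else NA_real_
  )
  for (k in seq_along(spec_targets)) {
    out[[sprintf("sens_at_spec_%d", round(100 * spec_targets[[k]]))]] <-
      if (two_class) sas$sensitivity[[k]] else NA_real_
  }
  out
}

#' Stratified evaluation report
#'
#' Computes the full evaluation surface: metrics per review period `t`, per
#' baseline-severity band, per (t, band) cell, and pooled marginals. "All t"
#' rows pool the evaluated predictions across time points, so each client
#' contributes one prediction per observed review.
#'
#' @param predictions Prediction-set tibble from [prediction_set()].
#' @param labels Label tibble from [label_cohort()] (provides severity
#'   bands).
#' @param target_instrument `"phq9"` or `"gad7"` (selects the band column).
#' @param min_t Drop predictions with `t < min_t` (e.g. 3 for a
#'   three-measure minimum).
#' @param spec_targets Specificity floors for operating points.
#' @param per_client If `TRUE`, "all t" rows average per-client mean scores
#'   instead of pooling prediction-time points.
#' @return Tibble with one row per stratum: `stratum_t` (`"all"` or the
#'   review period) and `severity` (`"overall"` or a band), plus metrics.
#'   Empty strata are dropped.
#' @export
stratified_evaluation <- function(predictions, labels,
                                  target_instrument = "phq9", min_t = 1L,
                                  spec_targets = c(0.90, 0.95, 0.97),
                                  per_client = FALSE) {
  band_col <- if (match_instrument(target_instrument) == "phq9") {
    "severity_phq"
  } else {
    "severity_gad"
  }
  pred <- dplyr::inner_join(
    predictions,
    tibble::tibble(client_id = labels$client_id,
                   severity = as.character(labels[[band_col]])),
    by = "client_id"
  )
  pred <- pred[pred$t >= min_t, , drop = FALSE]
  if (nrow(pred) == 0L) {
    abort("no predictions left after `min_t` filtering.",
          class = "icbtri_domain_error")
  }
  if (per_client) {
    pred <- pred |>
      dplyr::group_by(.data$client_id, .data$severity) |>
      dplyr::summarise(score = mean(.data$score),
                       predicted = mean(.data$predicted) >= 0.5,
                       label = .data$label[[1L]], .groups = "drop") |>
      dplyr::mutate(t = NA_integer_)
  }
  cells <- list()
  add_cell <- function(stratum_t, severity, rows) {
    if (nrow(rows) == 0L) return()
    cells[[length(cells) + 1L]] <<- dplyr::bind_cols(
      tibble::tibble(stratum_t = stratum_t, severity = severity),
      metric_row(rows, spec_targets)
    )
  }
  add_cell("all", "overall", pred)
  for (band in unique(pred$severity)) {
    add_cell("all", band, pred[pred$severity == band, , drop = FALSE])
  }
  if (!per_client) {
    for (tv in sort(unique(pred$t))) {
      sub_t <- pred[pred$t == tv, , drop = FALSE]
      add_cell(as.character(tv), "overall", sub_t)
      for (band in unique(sub_t$severity)) {
        add_cell(as.character(tv), band,
                 sub_t[sub_t$severity == band, , drop = FALSE])
      }
    }
  }
  dplyr::bind_rows(cells)
}

#' Cluster-bootstrap confidence interval for a metric
#'
#' Resamples whole clients with replacement (respecting the within-client
#' correlation of repeated predictions) and returns the percentile interval
#' of the metric. Resamples where the metric is undefined (e.g. a single
#' class) are skipped and counted.
#'
#' @param metric Function mapping a prediction-set tibble to one number.
#' @param predictions Prediction-set tibble.
#' @param n_boot Number of resamples (at least 100).
#' @param level Interval coverage level.
#' @param seed Integer seed (interval is deterministic given it).
#' @return List with `lower`, `upper`, `estimate`, `n_boot`, `n_skipped`,
#'   `level`, `seed`.
#' @export
bootstrap_ci <- function(metric, predictions, n_boot = 500L, level = 0.95,
                         seed = 1L) {
  if (n_boot < 100L) {
    abort("`n_boot` must be at least 100.", class = "icbtri_config_error")
  }
  ids <- unique(predictions$client_id)
  by_client <- split(seq_len(nrow(predictions)), predictions$client_id)
  withr::local_seed(seed)
  stats_ <- numeric(n_boot)
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    draw <- sample(ids, length(ids), replace = TRUE)
    rows <- unlist(by_client[draw], use.names = FALSE)
    val <- tryCatch(metric(predictions[rows, , drop = FALSE]),
                    error = function(e) NA_real_)
    if (is.na(val)) {
      skipped <- skipped + 1L
      stats_[b] <- NA_real_
    } else {
      stats_[b] <- val
    }
  }
  qs <- quantile(stats_, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  list(lower = unname(qs[[1L]]), upper = unname(qs[[2L]]),
       estimate = metric(predictions), n_boot = n_boot, n_skipped = skipped,
       level = level, seed = seed)
}

#' Kaplan-Meier time to sustained reliable improvement
#'
#' For each client, the event is the first review period at which the
#' reliable-improvement criterion (versus baseline) holds and keeps holding
#' at every subsequently observed review ("sustained" improvement); clients
#' who never sustain improvement are censored at their last observed review.
#' Product-limit curves are estimated per baseline-severity band with
#' [survival::survfit()]. Survival probability is the probability that
#' sustained improvement has not yet been achieved.
#'
#' @param cohort An `icbt_cohort`.
#' @param labels Label tibble from [label_cohort()] (provides severity
#'   bands).
#' @param target_instrument `"phq9"` or `"gad7"`.
#' @return Tibble with columns `severity`, `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_time_to_improvement <- function(cohort, labels, target_instrument = "phq9") {
  target_instrument <- match_instrument(target_instrument)
  band_col <- if (target_instrument == "phq9") "severity_phq" else "severity_gad"
  events <- purrr::map_dfr(cohort, function(rec) {
    st <- sustained_improvement_time(rec, target_instrument)
    tibble::tibble(client_id = rec$client_id, time = st$time,
                   event = st$event)
  })
  events <- dplyr::inner_join(
    events,
    tibble::tibble(client_id = labels$client_id,
                   severity = as.character(labels[[band_col]])),
    by = "client_id"
  )
  fit <- survival::survfit(
    survival::Surv(time, event) ~ severity,
    data = events
  )
  s <- summary(fit)
  if (length(s$time) == 0L) {
    return(tibble::tibble(severity = character(), time = numeric(),
                          n_risk = numeric(), n_event = numeric(),
                          survival = numeric()))
  }
  strata <- if (is.null(s$strata)) {
    rep(unique(events$severity), length(s$time))
  } else {
    sub("^severity=", "", as.character(s$strata))
  }
  tibble::tibble(severity = strata, time = s$time, n_risk = s$n.risk,
                 n_event = s$n.event, survival = s$surv)
}

## First review index from which the RI criterion holds at every observed
## review; event = 0 (censored at last review) when there is none.
sustained_improvement_time <- function(record, target_instrument) {
  keep <- which(record$review_index <= 8L)
  base_phq <- record$phq_total[[1L]]
  base_gad <- record$gad_total[[1L]]
  ri <- label_reliable_improvement(
    rep(base_phq, length(keep)), record$phq_total[keep],
    rep(base_gad, length(keep)), record$gad_total[keep]
  )
  status <- if (target_instrument == "phq9") ri$ri_phq else ri$ri_gad
  holds_onward <- rev(cumprod(rev(status))) == 1
  if (any(holds_onward)) {
    first <- which(holds_onward)[[1L]]
    list(time = record$review_index[keep][first], event = 1L)
  } else {
    list(time = record$review_index[keep][length(keep)], event = 0L)
  }
}
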
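#' Stratified train/validation/test split
#'
#' Randomly partitions clients 70:20:10 (by default) into training,
#' validation and test sets, stratified jointly on the two outcome labels so
#' that each split preserves the reliable-improvement prevalence of both
#' instruments. Deterministic given the seed.
#'
#' @param cohort An `icbt_cohort`.
#' @param labels Label tibble from [label_cohort()].
#' @param fractions Named numeric vector `(train, validation, test)` summing
#'   to 1.
#' @param seed Integer seed.
#' @return Named list of three `icbt_cohort` objects.
#' @export
split_data <- function(cohort, labels,
                       fractions = c(train = 0.7, validation = 0.2, test = 0.1),
                       seed = 1L) {
  check_prob_vector(fractions, "fractions")
  missing <- setdiff(names(cohort), labels$client_id)
  if (length(missing) > 0L) {
    abort("`labels` must cover every client in the cohort.",
          class = "icbtri_config_error")
  }
  for (col in c("ri_phq", "ri_gad")) {
    if (length(unique(labels[[col]][labels$client_id %in% names(cohort)])) < 2L) {
      abort(sprintf("cannot stratify: `%s` has a single class.", col),
            class = "icbtri_stratification_error")
    }
  }
  lab <- labels[match(names(cohort), labels$client_id), ]
  stratum <- interaction(lab$ri_phq, lab$ri_gad, drop = TRUE)
  withr::local_seed(seed)
  assignment <- rep(NA_character_, length(cohort))
  for (s in levels(stratum)) {
    ids <- which(stratum == s)
    ids <- ids[sample.int(length(ids))]
    n <- length(ids)
    n_train <- round(n * fractions[["train"]])
    n_val <- round(n * fractions[["validation"]])
    n_train <- min(n_train, n)
    n_val <- min(n_val, n - n_train)
    assignment[ids[seq_len(n_train)]] <- "train"
    if (n_val > 0L) assignment[ids[n_train + seq_len(n_val)]] <- "validation"
    rest <- ids[setdiff(seq_len(n), seq_len(n_train + n_val))]
    assignment[rest] <- "test"
  }
  purrr::map(
    setNames(c("train", "validation", "test"), c("train", "validation", "test")),
    function(part) cohort_subset(cohort, names(cohort)[assignment == part])
  )
}

STATIC_KINDS <- c("logistic_regression", "random_forest", "gradient_boosting")

#' Train a static benchmark classifier
#'
#' Fits logistic regression, a random forest, or a gradient-boosting
#' classifier on the length-16 zero-filled benchmark encoding, with one
#' training row per (client, observed review), so a single model serves
#' every prediction time.
#'
#' @param kind One of `"logistic_regression"`, `"random_forest"`,
#'   `"gradient_boosting"`.
#' @param train An `icbt_cohort`.
#' @param labels Label tibble from [label_cohort()].
#' @param target_instrument `"phq9"` or `"gad7"`.
#' @param hyperparams Optional named list overriding engine defaults
#'   (`num.trees` for the forest; `nrounds`, `max_depth`, `learning_rate`
#'   for boosting).
#' @param seed Integer seed.
#' @return An object of class `icbt_static`.
#' @export
train_static_classifier <- function(kind, train, labels,
                                    target_instrument = "phq9",
                                    hyperparams = list(), seed = 1L) {
  if (!kind %in% STATIC_KINDS) {
    abort(sprintf("unknown classifier kind '%s'.", kind),
          class = "icbtri_config_error")
  }
  if (length(train) == 0L) {
    abort("empty training set.", class = "icbtri_config_error")
  }
  ds <- build_benchmark_dataset(train, labels, target_instrument)
  xcols <- paste0("v", 1:16)
  x <- as.matrix(ds[, xcols])
  y <- ds$y
  withr::local_seed(seed)
  fit <- switch(
    kind,
    logistic_regression = suppressWarnings(
      glm(y ~ ., data = data.frame(y = y, x), family = binomial())
    ),
    random_forest = ranger::ranger(
      x = x, y = factor(y, levels = c(0L, 1L)),
      probability = TRUE,
      num.trees = hyperparams$num.trees %||% 300L,
      seed = seed, num.threads = 1L
    ),
    gradient_boosting = xgboost::xgboost(
      x = x, y = factor(y, levels = c(0L, 1L)),
      nrounds = hyperparams$nrounds %||% 150L,
      max_depth = hyperparams$max_depth %||% 3L,
      learning_rate = hyperparams$learning_rate %||% 0.1,
      nthreads = 1L, verbosity = 0L, seed = seed
    )
  )
  structure(
    list(kind = kind, fit = fit,
         target_instrument = match_instrument(target_instrument),
         seed = as.integer(seed)),
    class = "icbt_static"
  )
}

#' @export
print.icbt_static <- function(x, ...) {
  cat(sprintf("<icbt_static %s/%s>\n", x$kind, x$target_instrument))
  invisible(x)
}

static_score <- function(model, vecs) {
  if (ncol(vecs) != 16L) {
    abort(sprintf("benchmark input must have 16 columns, got %d.", ncol(vecs)),
          class = "icbtri_dimension_error")
  }
  colnames(vecs) <- paste0("v", 1:16)
  switch(
    model$kind,
    ## suppressWarnings: unreached review slots can be all-zero in training,
    ## making the design rank-deficient without affecting the fitted scores
    logistic_regression = unname(suppressWarnings(
      predict(model$fit, newdata = as.data.frame(vecs), type = "response")
    )),
    random_forest = unname(predict(model$fit, data = vecs)$predictions[, "1"]),
    gradient_boosting = unname(predict(model$fit, vecs, type = "response"))
  )
}

#' Exponential moving average of observed totals
#'
#' Computes the recurrence `s_1 = x_1`, `s_k = alpha * x_k +
#' (1 - alpha) * s_{k-1}` and returns `s_t`, the one-step forecast of the
#' next measurement.
#'
#' @param scores Numeric vector of observed totals (at least one).
#' @param alpha Smoothing weight in `(0, 1]`.
#' @return The forecast, a single number.
#' @export
#' @examples
#' ema_forecast(c(10, 6), alpha = 0.5) # 8
ema_forecast <- function(scores, alpha) {
  if (alpha <= 0 || alpha > 1) {
    abort("`alpha` must lie in (0, 1].", class = "icbtri_domain_error")
  }
  if (length(scores) < 1L) {
    abort("`scores` must contain at least one value.",
          class = "icbtri_domain_error")
  }
  s <- scores[[1L]]
  for (k in seq_along(scores)[-1L]) {
    s <- alpha * scores[[k]] + (1 - alpha) * s
  }
  s
}

#' EMA trend-following outcome prediction
#'
#' Forecasts the final score of each instrument by exponential smoothing of
#' the totals observed up to review `t`, rounds to the nearest integer
#' (clipped to the instrument range), and applies the reliable-improvement
#' criterion to (baseline, forecast).
#'
#' @param record A [client_record()].
#' @param t Prediction review period (must not exceed the last observed
#'   review).
#' @param alpha Smoothing weight in `(0, 1]`.
#' @return List with logical `ri_phq_pred`, `ri_gad_pred` and the rounded
#'   forecasts.
#' @export
ema_classify <- function(record, t, alpha = 0.6) {
  obs <- which(record$review_index <= t)
  if (t < 1L || length(obs) == 0L ||
      t > max(record$review_index[record$review_index <= 8L])) {
    abort("`t` beyond the client's last observed review.",
          class = "icbtri_domain_error")
  }
  round_half_up <- function(x) floor(x + 0.5)
  f_phq <- ema_forecast(record$phq_total[obs], alpha)
  f_gad <- ema_forecast(record$gad_total[obs], alpha)
  f_phq <- min(max(round_half_up(f_phq), PHQ_RANGE[[1L]]), PHQ_RANGE[[2L]])
  f_gad <- min(max(round_half_up(f_gad), GAD_RANGE[[1L]]), GAD_RANGE[[2L]])
  ri <- label_reliable_improvement(record$phq_total[[1L]], f_phq,
                                   record$gad_total[[1L]], f_gad)
  list(ri_phq_pred = ri$ri_phq[[1L]], ri_gad_pred = ri$ri_gad[[1L]],
       forecast_phq = f_phq, forecast_gad = f_gad)
}

#' EMA baseline model handle
#'
#' @param target_instrument `"phq9"` or `"gad7"`.
#' @param alpha Smoothing weight in `(0, 1]`, reported in all outputs.
#' @return An object of class `icbt_ema`.
#' @export
ema_model <- function(target_instrument = "phq9", alpha = 0.6) {
  if (alpha <= 0 || alpha > 1) {
    abort("`alpha` must lie in (0, 1].", class = "icbtri_domain_error")
  }
  structure(list(target_instrument = match_instrument(target_instrument),
                 alpha = alpha),
            class = "icbt_ema")
}

#' Predict reliable improvement from a prefix of one client's record
#'
#' Returns the predicted probability of reliable improvement using only the
#' observations up to and including review `t` (no information from later
#' reviews can leak into the prediction).
#'
#' @param model A trained `icbt_rnn`, `icbt_static`, or `icbt_ema`.
#' @param record A [client_record()].
#' @param t Prediction review period, `1 <= t <=` last observed review.
#' @return Probability in `[0, 1]` (the EMA baseline returns 0 or 1).
#' @export
predict_at_time <- function(model, record, t) {
  UseMethod("predict_at_time")
}

check_prediction_time <- function(record, t) {
  last <- max(record$review_index[record$review_index <= 8L])
  if (t < 1L || t > last) {
    abort(sprintf("prediction time %d beyond last observed review %d.", t, last),
          class = "icbtri_domain_error")
  }
}

#' @export
predict_at_time.icbt_rnn <- function(model, record, t) {
  check_prediction_time(record, t)
  feats <- build_sequence_features(record, model$feature_set,
                                   model$target_instrument)
  pos <- sum(attr(feats, "review_index") <= t)
  feats <- truncate_to_prefix(feats, pos)
  x <- array(0, dim = c(1L, 8L, ncol(feats)))
  x[1L, seq_len(nrow(feats)), ] <- feats
  rnn_predict_batch(model, x, nrow(feats))
}

#' @export
predict_at_time.icbt_static <- function(model, record, t) {
  check_prediction_time(record, t)
  v <- build_benchmark_vector(record, t, model$target_instrument)
  static_score(model, matrix(v, nrow = 1L))
}

#' @export
predict_at_time.icbt_ema <- function(model, record, t) {
  check_prediction_time(record, t)
  pred <- ema_classify(record, t, model$alpha)
  as.numeric(if (model$target_instrument == "phq9") pred$ri_phq_pred else pred$ri_gad_pred)
}

#' Predictions for every valid (client, review) pair
#'
#' Evaluates the model at every observed review period of every client
#' (predictions are never produced past a client's last measurement) and
#' joins the end-of-treatment label.
#'
#' @param model A trained model handle.
#' @param cohort An `icbt_cohort`.
#' @param labels Label tibble from [label_cohort()].
#' @param threshold Score threshold for the hard `predicted` column.
#' @return A prediction-set tibble with columns `client_id`, `t`, `score`,
#'   `predicted`, `label`.
#' @export
prediction_set <- function(model, cohort, labels, threshold = 0.5) {
  UseMethod("prediction_set")
}

label_lookup <- function(model, labels) {
  col <- if (model$target_instrument == "phq9") "ri_phq" else "ri_gad"
  setNames(labels[[col]], labels$client_id)
}

#' @export
prediction_set.icbt_rnn <- function(model, cohort, labels, threshold = 0.5) {
  ds <- build_sequence_dataset(cohort, labels, model$feature_set,
                               model$target_instrument, prefixes = TRUE)
  score <- rnn_predict_batch(model, ds$x, ds$lengths)
  tibble::tibble(client_id = ds$client_id, t = ds$t, score = score,
                 predicted = score >= threshold, label = ds$y == 1L)
}

#' @export
prediction_set.default <- function(model, cohort, labels, threshold = 0.5) {
  lab <- label_lookup(model, labels)
  purrr::map_dfr(cohort, function(rec) {
    ts <- rec$review_index[rec$review_index <= 8L]
    score <- vapply(ts, function(t) predict_at_time(model, rec, t), numeric(1L))
    tibble::tibble(client_id = rep(rec$client_id, length(ts)), t = ts,
                   score = score, predicted = score >= threshold,
                   label = rep(unname(lab[[rec$client_id]]), length(ts)))
  })
}
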
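FEATURE_SETS <- c("Q", "Qc", "I", "I+Q")

#' Per-review sequence features for one client
#'
#' Builds the model-ready sequence for one of the four feature sets:
#' `"Q"` the total score of the target instrument (dimension 1, or 2 with
#' `include_companion`), `"Qc"` the individual item scores (dimension 9 for
#' PHQ-9, 7 for GAD-7), `"I"` the per-review interaction counts (dimension
#' `n_interaction_types`), and `"I+Q"` their combination (interaction counts
#' plus the target total). Interaction counts are per review period, not
#' cumulative.
#'
#' @param record A [client_record()].
#' @param feature_set One of `"Q"`, `"Qc"`, `"I"`, `"I+Q"`.
#' @param target_instrument `"phq9"` or `"gad7"`.
#' @param include_companion For `"Q"`/`"I+Q"`: also include the companion
#'   instrument's total (off by default, matching a one-dimensional `Q`).
#' @return An object of class `feature_sequence`: a numeric matrix with one
#'   row per observed review (at most 8) and constant column dimension, with
#'   attributes `client_id`, `feature_set`, `review_index`.
#' @export
#' @examples
#' rec <- client_record("a", 1:3, matrix(2L, 3, 9), matrix(1L, 3, 7))
#' build_sequence_features(rec, "Q", "phq9")
build_sequence_features <- function(record, feature_set, target_instrument,
                                    include_companion = FALSE) {
  if (!feature_set %in% FEATURE_SETS) {
    abort(sprintf("unknown feature set '%s' (expected one of %s).",
                  feature_set, paste(FEATURE_SETS, collapse = ", ")),
          class = "icbtri_config_error")
  }
  target_instrument <- match_instrument(target_instrument)
  keep <- which(record$review_index <= 8L)
  tot <- function(instr) {
    if (instr == "phq9") record$phq_total[keep] else record$gad_total[keep]
  }
  target_total <- tot(target_instrument)
  companion <- setdiff(c("phq9", "gad7"), target_instrument)
  mat <- switch(
    feature_set,
    Q = {
      m <- cbind(target = target_total)
      if (include_companion) m <- cbind(m, companion = tot(companion))
      m
    },
    Qc = {
      if (target_instrument == "phq9") {
        record$phq_items[keep, , drop = FALSE]
      } else {
        record$gad_items[keep, , drop = FALSE]
      }
    },
    I = interaction_matrix(record, keep),
    `I+Q` = {
      m <- cbind(interaction_matrix(record, keep), target_total)
      if (include_companion) m <- cbind(m, tot(companion))
      m
    }
  )
  mat <- unname(matrix(as.numeric(mat), nrow = length(keep)))
  structure(mat,
            client_id = record$client_id,
            feature_set = feature_set,
            review_index = record$review_index[keep],
            class = c("feature_sequence", "matrix", "array"))
}

interaction_matrix <- function(record, keep) {
  p <- record$n_interaction_types
  if (p < 1L) {
    abort("record has no interaction taxonomy (`n_interaction_types` = 0).",
          class = "icbtri_config_error")
  }
  m <- matrix(0, nrow = length(keep), ncol = p)
  tri <- record$interactions
  if (!is.null(tri) && nrow(tri) > 0L) {
    row_of <- match(tri$review_index, record$review_index[keep])
    ok <- !is.na(row_of)
    m[cbind(row_of[ok], tri$type_id[ok])] <- tri$count[ok]
  }
  m
}

#' Fixed-length benchmark vector for static classifiers
#'
#' Encodes the totals observed up to review `t` into a length-16 vector:
#' eight slots holding the target instrument's total score at reviews 1-8
#' (0 where no measure is available, avoiding imputation bias) followed by
#' eight availability indicators.
#'
#' @param record A [client_record()].
#' @param t Prediction review period, 1-8.
#' @param target_instrument `"phq9"` or `"gad7"`.
#' @return Numeric vector of length 16.
#' @export
#' @examples
#' rec <- client_record("a", 1:3, matrix(2L, 3, 9), matrix(1L, 3, 7))
#' build_benchmark_vector(rec, 3, "phq9")
build_benchmark_vector <- function(record, t, target_instrument) {
  if (t < 1L || t > 8L) {
    abort("`t` must lie in 1..8.", class = "icbtri_domain_error")
  }
  target_instrument <- match_instrument(target_instrument)
  totals <- numeric(8L)
  avail <- numeric(8L)
  obs <- which(record$review_index <= t)
  ri <- record$review_index[obs]
  vals <- if (target_instrument == "phq9") record$phq_total[obs] else record$gad_total[obs]
  totals[ri] <- vals
  avail[ri] <- 1
  c(totals, avail)
}

#' Truncate a feature sequence to its first t reviews
#'
#' Predictions are only defined up to a client's last available measurement,
#' so requesting a prefix longer than the sequence is an error.
#'
#' @param features A `feature_sequence` from [build_sequence_features()].
#' @param t Prefix length, `1 <= t <= nrow(features)`.
#' @return A `feature_sequence` with the first `t` rows.
#' @export
truncate_to_prefix <- function(features, t) {
  stopifnot(inherits(features, "feature_sequence"))
  if (t < 1L || t > nrow(features)) {
    abort(sprintf("prefix length %d outside available reviews (1..%d).",
                  t, nrow(features)),
          class = "icbtri_domain_error")
  }
  out <- features[seq_len(t), , drop = FALSE]
  attributes(out) <- c(attributes(out)[c("dim")],
                       attributes(features)[c("client_id", "feature_set")],
                       list(review_index = attr(features, "review_index")[seq_len(t)],
                            class = c("feature_sequence", "matrix", "array")))
  out
}

#' Sequence dataset with prefix augmentation
#'
#' Expands a cohort into one training example per (client, observed prefix):
#' a client observed at reviews 1..n contributes n sequences of lengths
#' 1..n, all sharing the client's end-of-treatment label. This is what lets
#' a single many-to-one model answer at every review period.
#'
#' @param cohort An `icbt_cohort`.
#' @param labels Label tibble from [label_cohort()].
#' @param feature_set,target_instrument See [build_sequence_features()].
#' @param prefixes If `FALSE`, only the full observed sequence per client.
#' @return List with `x` (array n_seq x 8 x d, zero-padded), `lengths`,
#'   `y` (0/1), `client_id`, `t`.
#' @export
build_sequence_dataset <- function(cohort, labels, feature_set = "Q",
                                   target_instrument = "phq9",
                                   prefixes = TRUE) {
  label_col <- if (match_instrument(target_instrument) == "phq9") "ri_phq" else "ri_gad"
  lab <- setNames(labels[[label_col]], labels$client_id)
  seqs <- purrr::map(cohort, build_sequence_features,
                     feature_set = feature_set,
                     target_instrument = target_instrument)
  d <- ncol(seqs[[1L]])
  rows <- purrr::map(seq_along(seqs), function(i) {
    n <- nrow(seqs[[i]])
    ts <- if (prefixes) seq_len(n) else n
    list(id = attr(seqs[[i]], "client_id"), t = ts)
  })
  n_seq <- sum(vapply(rows, function(r) length(r$t), integer(1)))
  x <- array(0, dim = c(n_seq, 8L, d))
  lengths <- integer(n_seq)
  y <- integer(n_seq)
  ids <- character(n_seq)
  ts <- integer(n_seq)
  k <- 0L
  for (i in seq_along(seqs)) {
    m <- seqs[[i]]
    id <- attr(m, "client_id")
    for (t in rows[[i]]$t) {
      k <- k + 1L
      x[k, seq_len(t), ] <- m[seq_len(t), , drop = FALSE]
      lengths[k] <- t
      y[k] <- as.integer(lab[[id]])
      ids[k] <- id
      ts[k] <- t
    }
  }
  list(x = x, lengths = lengths, y = y, client_id = ids, t = ts, dim = d)
}

#' Benchmark-vector dataset with prefix augmentation
#'
#' One row per (client, observed review): the length-16 zero-filled encoding
#' at that prediction time plus the end-of-treatment label.
#'
#' @inheritParams build_sequence_dataset
#' @return Tibble with columns `client_id`, `t`, `y` and `v1`..`v16`.
#' @export
build_benchmark_dataset <- function(cohort, labels, target_instrument = "phq9") {
  label_col <- if (match_instrument(target_instrument) == "phq9") "ri_phq" else "ri_gad"
  lab <- setNames(labels[[label_col]], labels$client_id)
  purrr::map_dfr(cohort, function(rec) {
    ts <- rec$review_index[rec$review_index <= 8L]
    vecs <- t(vapply(ts, build_benchmark_vector, numeric(16L),
                     record = rec, target_instrument = target_instrument))
    colnames(vecs) <- paste0("v", seq_len(16L))
    dplyr::bind_cols(
      tibble::tibble(client_id = rep(rec$client_id, length(ts)), t = ts,
                     y = as.integer(lab[[rec$client_id]])),
      tibble::as_tibble(vecs)
    )
  })
}
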
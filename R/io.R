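#' Write a cohort to CSV tables
#'
#' Emits `observations.csv` (one row per client-review: id, review index,
#' week, the nine PHQ-9 and seven GAD-7 item scores, totals, censoring flag)
#' and `interactions.csv` (sparse triples `client_id`, `review_index`,
#' `interaction_type_id`, `count`).
#'
#' @param cohort An `icbt_cohort`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- cohort_observations(cohort)
  readr::write_csv(obs, file.path(dir, "observations.csv"))
  inter <- purrr::map_dfr(cohort, function(rec) {
    if (is.null(rec$interactions) || nrow(rec$interactions) == 0L) {
      return(NULL)
    }
    tibble::tibble(
      client_id = rec$client_id,
      review_index = rec$interactions$review_index,
      interaction_type_id = rec$interactions$type_id,
      count = rec$interactions$count
    )
  })
  if (nrow(inter) == 0L) {
    inter <- tibble::tibble(client_id = character(), review_index = integer(),
                            interaction_type_id = integer(), count = integer())
  }
  readr::write_csv(inter, file.path(dir, "interactions.csv"))
  invisible(dir)
}

#' Long-format observation table for a cohort
#'
#' @param cohort An `icbt_cohort`.
#' @return A tibble, one row per client-review.
#' @export
cohort_observations <- function(cohort) {
  purrr::map_dfr(cohort, function(rec) {
    n <- n_reviews(rec)
    phq <- as.data.frame(rec$phq_items)
    names(phq) <- paste0("phq_item_", seq_len(PHQ_N_ITEMS))
    gad <- as.data.frame(rec$gad_items)
    names(gad) <- paste0("gad_item_", seq_len(GAD_N_ITEMS))
    dplyr::bind_cols(
      tibble::tibble(client_id = rep(rec$client_id, n),
                     review_index = rec$review_index,
                     week = rec$week),
      phq, gad,
      tibble::tibble(phq_total = rec$phq_total, gad_total = rec$gad_total,
                     censored = rep(rec$censored, n))
    )
  })
}

#' Read a cohort from CSV tables
#'
#' Inverse of [write_cohort_csv()]. `interactions.csv` is optional.
#'
#' @param dir Directory holding `observations.csv` (and optionally
#'   `interactions.csv`).
#' @param n_interaction_types Taxonomy size recorded on each record.
#' @return An `icbt_cohort`.
#' @export
read_cohort_csv <- function(dir, n_interaction_types = 1133L) {
  obs <- readr::read_csv(file.path(dir, "observations.csv"),
                         show_col_types = FALSE)
  inter_path <- file.path(dir, "interactions.csv")
  inter <- if (file.exists(inter_path)) {
    readr::read_csv(inter_path, show_col_types = FALSE)
  } else {
    NULL
  }
  ids <- unique(obs$client_id)
  records <- purrr::map(ids, function(id) {
    o <- obs[obs$client_id == id, , drop = FALSE]
    o <- o[order(o$review_index), , drop = FALSE]
    tri <- NULL
    if (!is.null(inter)) {
      t0 <- inter[inter$client_id == id, , drop = FALSE]
      tri <- tibble::tibble(review_index = as.integer(t0$review_index),
                            type_id = as.integer(t0$interaction_type_id),
                            count = as.integer(t0$count))
    }
    client_record(
      client_id = id,
      review_index = o$review_index,
      week = o$week,
      phq_items = as.matrix(o[, paste0("phq_item_", seq_len(PHQ_N_ITEMS))]),
      gad_items = as.matrix(o[, paste0("gad_item_", seq_len(GAD_N_ITEMS))]),
      interactions = tri,
      n_interaction_types = n_interaction_types,
      censored = isTRUE(o$censored[[1L]])
    )
  })
  new_cohort(records, config = NULL) |>
    structure(n_interaction_types = as.integer(n_interaction_types))
}
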
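# Deterministic item allocation used to build hand-constructed records:
# fill items left to right at the cap (3, 3, ..., remainder, 0, ...).
greedy_items <- function(total, n_items) {
  q <- total %/% 3L
  r <- total %% 3L
  out <- c(rep(3L, q), if (r > 0L) r, integer(n_items))[seq_len(n_items)]
  stopifnot(sum(out) == total)
  out
}

# A client record with prescribed total-score trajectories.
make_record <- function(id, phq_totals, gad_totals = rep(10L, length(phq_totals)),
                        review_index = seq_along(phq_totals), censored = FALSE,
                        n_interaction_types = 0L, interactions = NULL) {
  client_record(
    client_id = id,
    review_index = review_index,
    phq_items = t(vapply(phq_totals, greedy_items, integer(9L), n_items = 9L)),
    gad_items = t(vapply(gad_totals, greedy_items, integer(7L), n_items = 7L)),
    censored = censored,
    n_interaction_types = n_interaction_types,
    interactions = interactions
  )
}

make_cohort <- function(records) {
  icbtri:::new_cohort(records)
}

# A small labeled cohort with both classes present, for model tests.
small_labeled_cohort <- function(n = 60L, seed = 123L) {
  cfg <- generator_config(n_clients = n, seed = seed, dropout_hazard = 0.3)
  cohort <- sample_cohort(cfg, include_interactions = FALSE)
  labels <- label_cohort(cohort, quiet = TRUE)
  list(cohort = cohort, labels = labels)
}
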
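#' LOCF final scores for a client record
#'
#' Returns the totals at the last available observation at or before the
#' eighth review period (last observation carried forward; reviews past the
#' eighth are never used for labeling).
#'
#' @param record A [client_record()].
#' @return A list with `final_phq`, `final_gad`, `last_observed_index`.
#' @export
#' @examples
#' rec <- client_record("a", 1:3,
#'   phq_items = matrix(rep(2:0, each = 9), 3, 9, byrow = FALSE),
#'   gad_items = matrix(1L, 3, 7))
#' locf_final_scores(rec)
locf_final_scores <- function(record) {
  stopifnot(inherits(record, "client_record"))
  keep <- which(record$review_index <= 8L)
  if (length(keep) < 2L) {
    abort(sprintf("client %s: fewer than 2 observations within 8 review periods.",
                  record$client_id),
          class = "icbtri_inclusion_error")
  }
  last <- keep[[length(keep)]]
  list(
    final_phq = record$phq_total[[last]],
    final_gad = record$gad_total[[last]],
    last_observed_index = record$review_index[[last]]
  )
}

#' Reliable-improvement labels from baseline and final scores
#'
#' Applies the reliable change criterion used for routine outcome monitoring
#' with PHQ-9 and GAD-7: reliable improvement in depression is a decrease of
#' at least 6 PHQ-9 points with no increase of 4 or more GAD-7 points;
#' reliable improvement in anxiety is a decrease of at least 4 GAD-7 points
#' with no increase of 6 or more PHQ-9 points. All arguments are vectorized.
#'
#' @param baseline_phq,final_phq Integer PHQ-9 totals in 0-27.
#' @param baseline_gad,final_gad Integer GAD-7 totals in 0-21.
#' @return A tibble with logical columns `ri_phq`, `ri_gad`.
#' @export
#' @examples
#' label_reliable_improvement(20, 14, 10, 10) # depression improvement only
label_reliable_improvement <- function(baseline_phq, final_phq,
                                       baseline_gad, final_gad) {
  n <- length(baseline_phq)
  stopifnot(length(final_phq) == n, length(baseline_gad) == n,
            length(final_gad) == n)
  if (any(baseline_phq < 0 | baseline_phq > 27 | final_phq < 0 | final_phq > 27 |
          baseline_gad < 0 | baseline_gad > 21 | final_gad < 0 | final_gad > 21)) {
    abort("scores out of instrument range (PHQ-9 0-27, GAD-7 0-21).",
          class = "icbtri_domain_error")
  }
  ri_phq <- (baseline_phq - final_phq >= RI_DECREASE[["phq9"]]) &
    (final_gad - baseline_gad < RI_DISQUALIFY[["gad7"]])
  ri_gad <- (baseline_gad - final_gad >= RI_DECREASE[["gad7"]]) &
    (final_phq - baseline_phq < RI_DISQUALIFY[["phq9"]])
  tibble::tibble(ri_phq = ri_phq, ri_gad = ri_gad)
}

#' Assign a baseline severity band
#'
#' Mild is PHQ-9 0-8 or GAD-7 0-6; the moderate/severe boundary defaults to
#' conventional instrument banding (PHQ-9 moderate 9-16, severe 17-27;
#' GAD-7 moderate 7-14, severe 15-21) and can be overridden.
#'
#' @param baseline Integer baseline total (vectorized).
#' @param instrument `"phq9"` or `"gad7"`.
#' @param bounds Named list of `c(lower, upper)` bounds per band, partitioning
#'   the instrument range.
#' @return Factor with levels `mild`, `moderate`, `severe`.
#' @export
#' @examples
#' assign_severity_band(c(8, 9, 27), "phq9")
assign_severity_band <- function(baseline, instrument,
                                 bounds = severity_band_bounds(instrument)) {
  rng <- instrument_range(instrument)
  if (any(baseline < rng[[1L]] | baseline > rng[[2L]])) {
    abort("baseline out of instrument range.", class = "icbtri_domain_error")
  }
  covered <- sort(unlist(lapply(bounds, function(b) b[[1L]]:b[[2L]])))
  if (!identical(as.integer(covered), rng[[1L]]:rng[[2L]])) {
    abort("severity bands must partition the instrument range.",
          class = "icbtri_config_error")
  }
  band <- character(length(baseline))
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    band[baseline >= b[[1L]] & baseline <= b[[2L]]] <- nm
  }
  factor(band, levels = c("mild", "moderate", "severe"))
}

#' Label a whole cohort
#'
#' Computes, per client, the baseline (first observation) and LOCF final
#' totals, the reliable-improvement labels for both instruments, and the
#' baseline severity bands.
#'
#' @param cohort An `icbt_cohort` or list of [client_record()]s.
#' @param quiet Suppress the prevalence summary message?
#' @return A tibble with one row per client: `client_id`, baselines, finals,
#'   `last_observed_index`, `ri_phq`, `ri_gad`, `severity_phq`,
#'   `severity_gad`, `censored`, `n_reviews`.
#' @export
label_cohort <- function(cohort, quiet = FALSE) {
  if (length(cohort) == 0L) {
    return(tibble::tibble(
      client_id = character(), baseline_phq = integer(), final_phq = integer(),
      baseline_gad = integer(), final_gad = integer(),
      last_observed_index = integer(), ri_phq = logical(), ri_gad = logical(),
      severity_phq = factor(character(), levels = c("mild", "moderate", "severe")),
      severity_gad = factor(character(), levels = c("mild", "moderate", "severe")),
      censored = logical(), n_reviews = integer()
    ))
  }
  fins <- vapply(cohort, function(rec) {
    fin <- locf_final_scores(rec)
    c(fin$final_phq, fin$final_gad, fin$last_observed_index)
  }, numeric(3L))
  out <- tibble::tibble(
    client_id = vapply(cohort, `[[`, character(1L), "client_id"),
    baseline_phq = vapply(cohort, function(r) r$phq_total[[1L]], integer(1L)),
    final_phq = as.integer(fins[1L, ]),
    baseline_gad = vapply(cohort, function(r) r$gad_total[[1L]], integer(1L)),
    final_gad = as.integer(fins[2L, ]),
    last_observed_index = as.integer(fins[3L, ]),
    censored = vapply(cohort, `[[`, logical(1L), "censored"),
    n_reviews = vapply(cohort, n_reviews, integer(1L))
  )
  ri <- label_reliable_improvement(out$baseline_phq, out$final_phq,
                                   out$baseline_gad, out$final_gad)
  out$ri_phq <- ri$ri_phq
  out$ri_gad <- ri$ri_gad
  out$severity_phq <- assign_severity_band(out$baseline_phq, "phq9")
  out$severity_gad <- assign_severity_band(out$baseline_gad, "gad7")
  if (!quiet) {
    message(sprintf(
      "labeled %d clients: RI prevalence %.3f (PHQ-9), %.3f (GAD-7)",
      nrow(out), mean(out$ri_phq), mean(out$ri_gad)
    ))
  }
  out[, c("client_id", "baseline_phq", "final_phq", "baseline_gad",
          "final_gad", "last_observed_index", "ri_phq", "ri_gad",
          "severity_phq", "severity_gad", "censored", "n_reviews")]
}
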
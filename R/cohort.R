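#' Client record
#'
#' A client record is the ordered, variable-length sequence of review-period
#' observations for one client: item-level PHQ-9 and GAD-7 scores, their
#' totals, the week of each review, sparse interaction counts, and a
#' censoring flag set when the client dropped out before the full program.
#'
#' @param client_id Identifier.
#' @param review_index Strictly increasing integer vector starting at 1.
#' @param week Numeric vector of weeks since first review.
#' @param phq_items Integer matrix (reviews x 9), entries in 0-3.
#' @param gad_items Integer matrix (reviews x 7), entries in 0-3.
#' @param interactions Tibble with columns `review_index`, `type_id`,
#'   `count` (sparse triples), or `NULL` for none.
#' @param n_interaction_types Length of the (implicit) dense count vector.
#' @param censored Logical: did the record end by dropout before
#'   `max_reviews`?
#' @param archetype Optional archetype name (simulation metadata).
#' @return An object of class `client_record`.
#' @export
client_record <- function(client_id, review_index, phq_items, gad_items,
                          week = NULL, interactions = NULL,
                          n_interaction_types = 0L, censored = FALSE,
                          archetype = NA_character_) {
  review_index <- as.integer(review_index)
  n <- length(review_index)
  if (n < 1L) {
    abort(sprintf("client %s: record has no observations.", client_id),
          class = "icbtri_domain_error")
  }
  ## study inclusion (>= 2 completed measures) is enforced at labeling time,
  ## so raw records with a single review can still be represented
  if (any(diff(review_index) <= 0L) || review_index[[1L]] < 1L) {
    abort("`review_index` must be strictly increasing and start at >= 1.",
          class = "icbtri_domain_error")
  }
  phq_items <- matrix(as.integer(phq_items), nrow = n, ncol = PHQ_N_ITEMS)
  gad_items <- matrix(as.integer(gad_items), nrow = n, ncol = GAD_N_ITEMS)
  if (any(phq_items < 0L | phq_items > ITEM_CAP) ||
      any(gad_items < 0L | gad_items > ITEM_CAP)) {
    abort("item scores must lie in [0, 3].", class = "icbtri_domain_error")
  }
  structure(
    list(
      client_id = as.character(client_id),
      review_index = review_index,
      week = if (is.null(week)) as.numeric(review_index - 1L) * 1.8 else as.numeric(week),
      phq_items = phq_items,
      gad_items = gad_items,
      phq_total = as.integer(rowSums(phq_items)),
      gad_total = as.integer(rowSums(gad_items)),
      interactions = interactions,
      n_interaction_types = as.integer(n_interaction_types),
      censored = isTRUE(censored),
      archetype = archetype
    ),
    class = "client_record"
  )
}

#' @export
print.client_record <- function(x, ...) {
  cat(sprintf(
    "<client_record %s: %d reviews%s, PHQ-9 %s, GAD-7 %s>\n",
    x$client_id, length(x$review_index), if (x$censored) " (censored)" else "",
    paste(x$phq_total, collapse = ","), paste(x$gad_total, collapse = ",")
  ))
  invisible(x)
}

n_reviews <- function(record) length(record$review_index)

#' @export
print.icbt_cohort <- function(x, ...) {
  cat(sprintf("<icbt_cohort: %d clients, %d interaction types>\n",
              length(x), attr(x, "n_interaction_types") %||% 0L))
  invisible(x)
}

new_cohort <- function(records, config = NULL) {
  structure(records,
            names = vapply(records, `[[`, character(1), "client_id"),
            n_interaction_types = if (is.null(config)) 0L else config$n_interaction_types,
            config = config,
            class = "icbt_cohort")
}

#' Subset a cohort by client id
#'
#' @param cohort An `icbt_cohort`.
#' @param client_ids Character vector of client ids to keep.
#' @return An `icbt_cohort` with the selected clients, in the given order.
#' @export
cohort_subset <- function(cohort, client_ids) {
  missing <- setdiff(client_ids, names(cohort))
  if (length(missing) > 0L) {
    abort(sprintf("unknown client ids: %s", paste(head(missing, 3), collapse = ", ")),
          class = "icbtri_domain_error")
  }
  out <- cohort[client_ids]
  attributes(out) <- attributes(cohort)[c("n_interaction_types", "config", "class")]
  names(out) <- client_ids
  out
}

#' Sample a total-score trajectory for one client
#'
#' Adds the archetype's cumulative mean change curve to the baseline, plus
#' per-review Gaussian noise (`curve_sd`), rounds to integers and clips to
#' the instrument range. The first value always equals the baseline.
#'
#' @param archetype A [trajectory_archetype()].
#' @param baseline Integer baseline total within the instrument range.
#' @param n_periods Number of review periods to emit.
#' @param range Instrument range, e.g. `c(0, 27)` for PHQ-9.
#' @param change_scale Multiplier applied to the mean change curve (used to
#'   map the latent PHQ-scale curve onto the GAD-7 scale).
#' @param noise Optional pre-sampled noise vector of length `n_periods`
#'   (first entry ignored); when `NULL`, drawn as iid N(0, `curve_sd`).
#' @return Integer vector of length `n_periods`.
#' @export
#' @examples
#' arch <- trajectory_archetype("steady_improver", c(0, -2, -4, -6), curve_sd = 0)
#' set.seed(1)
#' sample_total_trajectory(arch, baseline = 20, n_periods = 4)
sample_total_trajectory <- function(archetype, baseline, n_periods,
                                    range = PHQ_RANGE, change_scale = 1,
                                    noise = NULL) {
  stopifnot(inherits(archetype, "trajectory_archetype"))
  if (baseline < range[[1L]] || baseline > range[[2L]]) {
    abort("`baseline` out of instrument range.", class = "icbtri_domain_error")
  }
  if (n_periods > length(archetype$mean_change_curve)) {
    abort("archetype curve shorter than `n_periods`.", class = "icbtri_domain_error")
  }
  curve <- archetype$mean_change_curve[seq_len(n_periods)] * change_scale
  if (is.null(noise)) {
    noise <- rnorm(n_periods, 0, archetype$curve_sd)
  }
  noise[1L] <- 0
  vals <- round(baseline + curve + noise)
  vals[1L] <- baseline
  as.integer(pmin(pmax(vals, range[[1L]]), range[[2L]]))
}

#' Allocate a total score across ordinal items
#'
#' Draws a uniformly random feasible allocation of `total` points over
#' `n_items` items capped at `item_cap`, by sampling `total` of the
#' `n_items * item_cap` unit "slots" without replacement.
#'
#' @param total Integer total, `0 <= total <= n_items * item_cap`.
#' @param n_items Number of items.
#' @param item_cap Maximum per-item score (3 for PHQ-9/GAD-7 items).
#' @return Integer vector of length `n_items` summing to `total`.
#' @export
#' @examples
#' set.seed(1)
#' allocate_items(13, 9)
allocate_items <- function(total, n_items, item_cap = ITEM_CAP) {
  if (total < 0L || total > n_items * item_cap) {
    abort(sprintf("infeasible total %d for %d items capped at %d.",
                  total, n_items, item_cap),
          class = "icbtri_domain_error")
  }
  if (total == 0L) return(integer(n_items))
  slots <- sample.int(n_items * item_cap, total)
  tabulate((slots - 1L) %/% item_cap + 1L, nbins = n_items)
}

#' Sample interaction counts for one review period
#'
#' Total events follow a negative binomial with mean
#' `engagement_level * rate` (overdispersed, matching platform count data),
#' thinned by a multinomial draw over a small active subset of the
#' interaction taxonomy, so counts are sparse across the `n_types` types.
#'
#' @param engagement_level Non-negative engagement multiplier.
#' @param n_types Taxonomy size.
#' @param rate Mean events per review at engagement level 1.
#' @param active_types Optional integer vector of the client's active type
#'   ids; defaults to a fresh random subset.
#' @param dispersion Negative-binomial size parameter.
#' @return Tibble of sparse triples `type_id`, `count` (zero rows possible).
#' @export
sample_interactions <- function(engagement_level, n_types, rate = 20,
                                active_types = NULL, dispersion = 1.5) {
  if (engagement_level < 0) {
    abort("`engagement_level` must be non-negative.", class = "icbtri_domain_error")
  }
  total <- if (engagement_level == 0) 0L else {
    rnbinom(1L, mu = engagement_level * rate, size = dispersion)
  }
  if (total == 0L) {
    return(tibble::new_tibble(list(type_id = integer(), count = integer()),
                              nrow = 0L))
  }
  if (is.null(active_types)) {
    active_types <- sample.int(n_types, min(n_types, 30L))
  }
  ## heavier weight on low-rank types gives the zipf-like sparsity of real logs
  w <- 1 / seq_along(active_types)
  counts <- as.integer(rmultinom(1L, total, w))
  keep <- counts > 0L
  tibble::new_tibble(list(type_id = as.integer(active_types[keep]),
                          count = counts[keep]),
                     nrow = sum(keep))
}

#' Truncate a full-length record at a sampled dropout event
#'
#' Dropout follows a geometric per-review hazard: after each review from
#' `min_reviews` onwards the client drops out with probability `hazard`
#' (optionally tilted by the improvement achieved so far via a logistic
#' link). The record is cut at the first event, never below `min_reviews`;
#' the censored flag records whether truncation occurred.
#'
#' @param full_record A `client_record` with the full `max_reviews`
#'   observations.
#' @param hazard Per-review dropout probability in `[0, 1]`.
#' @param min_reviews Minimum retained observations.
#' @param improvement_beta Logistic-link coefficient on (improvement so
#'   far)/5; positive values make improved clients more likely to leave.
#' @return A `client_record`, possibly truncated with `censored = TRUE`.
#' @export
apply_dropout <- function(full_record, hazard, min_reviews = 2L,
                          improvement_beta = 0) {
  n <- n_reviews(full_record)
  if (hazard == 0) return(full_record)
  keep <- sample_dropout_length(full_record$phq_total, hazard, min_reviews, n,
                                improvement_beta)
  if (keep == n) return(full_record)
  truncate_record(full_record, keep, censored = TRUE)
}

## Geometric dropout time on a total-score trajectory (the mechanism behind
## apply_dropout, usable before a record object exists).
sample_dropout_length <- function(phq_tot, hazard, min_reviews, n_max,
                                  improvement_beta = 0) {
  if (hazard == 0 || n_max <= min_reviews) return(n_max)
  for (j in seq(min_reviews, n_max - 1L)) {
    h <- hazard
    if (improvement_beta != 0) {
      drop0 <- phq_tot[[1L]] - phq_tot[[j]]
      h <- plogis(qlogis(hazard) + improvement_beta * drop0 / 5)
    }
    if (runif(1L) < h) return(j)
  }
  n_max
}

truncate_record <- function(record, keep, censored = record$censored) {
  idx <- seq_len(keep)
  inter <- record$interactions
  if (!is.null(inter)) {
    inter <- inter[inter$review_index <= record$review_index[[keep]], , drop = FALSE]
  }
  client_record(
    client_id = record$client_id,
    review_index = record$review_index[idx],
    week = record$week[idx],
    phq_items = record$phq_items[idx, , drop = FALSE],
    gad_items = record$gad_items[idx, , drop = FALSE],
    interactions = inter,
    n_interaction_types = record$n_interaction_types,
    censored = censored,
    archetype = record$archetype
  )
}

severity_band_bounds <- function(instrument) {
  if (match_instrument(instrument) == "phq9") {
    list(mild = c(0L, 8L), moderate = c(9L, 16L), severe = c(17L, 27L))
  } else {
    list(mild = c(0L, 6L), moderate = c(7L, 14L), severe = c(15L, 21L))
  }
}

#' Generate a synthetic iCBT cohort
#'
#' Draws, per client: a baseline severity band and integer baselines for both
#' instruments; a latent trajectory archetype shared by the two instruments;
#' total-score trajectories (GAD-7 scaled by `gad_change_scale`) with
#' correlated observation noise; item allocations consistent with every
#' total; review weeks with Gaussian intervals; sparse interaction counts;
#' and a geometric dropout time. The result is a deterministic function of
#' the configuration (including its seed).
#'
#' @param config A [generator_config()].
#' @param include_interactions Generate interaction-count streams? Skipping
#'   them speeds up score-only work such as prevalence calibration.
#' @return An `icbt_cohort` (list of [client_record()] objects).
#' @export
#' @examples
#' cohort <- sample_cohort(generator_config(n_clients = 20, seed = 42))
#' cohort[[1]]
sample_cohort <- function(config, include_interactions = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  withr::local_seed(config$seed)
  archetypes <- default_archetypes(config$max_reviews)
  if (!is.null(config$curve_sd)) {
    archetypes <- purrr::map(archetypes, function(a) {
      a$curve_sd <- config$curve_sd
      a
    })
  }
  w <- config$archetype_weights[names(archetypes)]
  if (anyNA(w)) {
    abort("`archetype_weights` must name the five shipped archetypes.",
          class = "icbtri_config_error")
  }
  bands_phq <- severity_band_bounds("phq9")
  bands_gad <- severity_band_bounds("gad7")
  rho <- config$score_correlation
  n_max <- config$max_reviews

  records <- vector("list", config$n_clients)
  for (i in seq_len(config$n_clients)) {
    band <- sample(names(config$severity_mixture), 1L,
                   prob = config$severity_mixture)
    base_phq <- sample(bands_phq[[band]][1L]:bands_phq[[band]][2L], 1L)
    base_gad <- sample(bands_gad[[band]][1L]:bands_gad[[band]][2L], 1L)
    arch <- archetypes[[sample(names(archetypes), 1L, prob = w)]]

    ## correlated noise: one shared latent stream plus instrument-specific ones
    sd_tot <- sqrt(arch$curve_sd^2 + config$noise_sd^2)
    z0 <- rnorm(n_max); z1 <- rnorm(n_max); z2 <- rnorm(n_max)
    eps_phq <- sd_tot * (sqrt(rho) * z0 + sqrt(1 - rho) * z1)
    eps_gad <- sd_tot * (sqrt(rho) * z0 + sqrt(1 - rho) * z2)

    phq_tot <- sample_total_trajectory(arch, base_phq, n_max,
                                       range = PHQ_RANGE, noise = eps_phq)
    gad_tot <- sample_total_trajectory(arch, base_gad, n_max,
                                       range = GAD_RANGE,
                                       change_scale = config$gad_change_scale,
                                       noise = eps_gad)

    ## dropout time is sampled first so item allocation is only done for
    ## retained reviews (same geometric mechanism as apply_dropout)
    keep_n <- sample_dropout_length(phq_tot, config$dropout_hazard,
                                    config$min_reviews, n_max,
                                    config$dropout_improvement_beta)
    kept <- seq_len(keep_n)
    phq_items <- t(vapply(phq_tot[kept], allocate_items, integer(PHQ_N_ITEMS),
                          n_items = PHQ_N_ITEMS))
    gad_items <- t(vapply(gad_tot[kept], allocate_items, integer(GAD_N_ITEMS),
                          n_items = GAD_N_ITEMS))

    gaps <- pmax(0.5, rnorm(keep_n - 1L, config$review_interval_mean_weeks,
                            config$review_interval_sd_weeks))
    week <- c(0, cumsum(gaps))

    rec <- client_record(
      client_id = sprintf("c%05d", i),
      review_index = kept,
      week = week,
      phq_items = phq_items,
      gad_items = gad_items,
      interactions = NULL,
      n_interaction_types = config$n_interaction_types,
      censored = keep_n < n_max,
      archetype = arch$name
    )

    ## interaction streams are drawn only for retained reviews
    if (include_interactions) {
      engagement <- exp(rnorm(1L, 0, 0.5))
      active <- sample.int(config$n_interaction_types,
                           min(config$n_interaction_types, 30L))
      inter <- purrr::map_dfr(seq_len(n_reviews(rec)), function(j) {
        trip <- sample_interactions(engagement, config$n_interaction_types,
                                    rate = config$engagement_rate,
                                    active_types = active)
        trip$review_index <- rep(rec$review_index[[j]], nrow(trip))
        trip
      })
      rec$interactions <- inter[, c("review_index", "type_id", "count")]
    }
    records[[i]] <- rec
  }
  new_cohort(records, config)
}
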
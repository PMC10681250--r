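test_that("generator configuration rejects degenerate input", {
  expect_error(generator_config(n_clients = 0), class = "icbtri_config_error")
  expect_error(generator_config(archetype_weights = c(steady_improver = 0.7,
                                                      non_responder = 0.7)),
               class = "icbtri_config_error")
  expect_error(generator_config(min_reviews = 5L, max_reviews = 4L),
               class = "icbtri_config_error")
  expect_error(generator_config(dropout_hazard = 1),
               class = "icbtri_config_error")
})

test_that("cohorts are a deterministic function of config and seed", {
  cfg <- generator_config(n_clients = 40L, seed = 7L)
  a <- sample_cohort(cfg)
  b <- sample_cohort(cfg)
  expect_identical(cohort_observations(a), cohort_observations(b))
  expect_identical(purrr::map(a, "interactions"), purrr::map(b, "interactions"))
  c2 <- sample_cohort(generator_config(n_clients = 40L, seed = 8L))
  expect_false(identical(cohort_observations(a), cohort_observations(c2)))
})

test_that("generated observations respect all score-range invariants", {
  cfg <- generator_config(n_clients = 300L, seed = 3L)
  cohort <- sample_cohort(cfg, include_interactions = FALSE)
  for (rec in cohort) {
    expect_true(all(rec$phq_items >= 0L & rec$phq_items <= 3L))
    expect_true(all(rec$gad_items >= 0L & rec$gad_items <= 3L))
    expect_identical(rec$phq_total, as.integer(rowSums(rec$phq_items)))
    expect_identical(rec$gad_total, as.integer(rowSums(rec$gad_items)))
    expect_true(all(rec$phq_total >= 0L & rec$phq_total <= 27L))
    expect_true(all(rec$gad_total >= 0L & rec$gad_total <= 21L))
    expect_true(dplyr::between(length(rec$review_index), cfg$min_reviews,
                               cfg$max_reviews))
  }
})

test_that("review intervals and severity mixture match their configuration", {
  cfg <- generator_config(n_clients = 2000L, seed = 13L)
  cohort <- sample_cohort(cfg, include_interactions = FALSE)
  gaps <- unlist(purrr::map(cohort, ~ diff(.x$week)))
  se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 1.8), 3 * se)

  labels <- label_cohort(cohort, quiet = TRUE)
  bands <- table(labels$severity_phq) / nrow(labels)
  for (nm in names(cfg$severity_mixture)) {
    p <- cfg$severity_mixture[[nm]]
    se_b <- sqrt(p * (1 - p) / nrow(labels))
    expect_lt(abs(bands[[nm]] - p), 3 * se_b + 1e-12)
  }
})

test_that("sample_total_trajectory applies the change curve and clips to range", {
  flat <- trajectory_archetype("non_responder", rep(0, 8), curve_sd = 0)
  expect_identical(sample_total_trajectory(flat, 12L, 8L), rep(12L, 8L))

  steady <- trajectory_archetype("steady_improver",
                                 c(0, -2, -4, -6, -8, -10, -12, -14),
                                 curve_sd = 0)
  expect_identical(sample_total_trajectory(steady, 20L, 8L),
                   as.integer(seq(20, 6, by = -2)))

  det <- trajectory_archetype("deteriorator", c(0, 2, 4, 6, 8, 10, 12, 14),
                              curve_sd = 5)
  set.seed(99)
  for (i in 1:1000) {
    vals <- sample_total_trajectory(det, 2L, 8L)
    expect_true(all(vals >= 0L & vals <= 27L))
    expect_equal(vals[[1L]], 2L)
  }
  expect_error(sample_total_trajectory(det, 30L, 8L),
               class = "icbtri_domain_error")
})

test_that("archetype constructor enforces curve shape constraints", {
  expect_error(trajectory_archetype("steady_improver", c(1, -2)),
               class = "icbtri_config_error")
  expect_error(trajectory_archetype("deteriorator", c(0, 2, 1)),
               class = "icbtri_config_error")
  expect_error(trajectory_archetype("late_improver", c(0, -1, 1)),
               class = "icbtri_config_error")
  expect_silent(trajectory_archetype("non_responder", c(0, -1, 1)))
})

test_that("allocate_items produces exact sums within the item cap", {
  expect_identical(allocate_items(0L, 9L), integer(9L))
  expect_identical(allocate_items(27L, 9L), rep(3L, 9L))
  expect_error(allocate_items(28L, 9L), class = "icbtri_domain_error")
  set.seed(5)
  for (i in 1:1000) {
    v <- allocate_items(13L, 7L)
    expect_equal(sum(v), 13L)
    expect_true(all(v >= 0L & v <= 3L))
  }
})

test_that("interaction totals grow with engagement and stay sparse", {
  set.seed(11)
  expect_equal(nrow(sample_interactions(0, 1133L)), 0L)
  totals <- function(level) {
    replicate(500, sum(sample_interactions(level, 1133L)$count))
  }
  lo <- totals(1.0)
  hi <- totals(5.0)
  expect_gt(mean(hi), mean(lo))
  one <- sample_interactions(3, 50L)
  expect_true(all(one$type_id >= 1L & one$type_id <= 50L))
  expect_true(all(one$count > 0L))
  expect_error(sample_interactions(-1, 10L), class = "icbtri_domain_error")
})

test_that("dropout truncates at the sampled event and hits its target rate", {
  full <- make_record("f", c(20L, 19L, 18L, 17L, 16L, 15L, 14L, 13L))
  expect_identical(apply_dropout(full, 0), full)
  set.seed(2)
  forced <- apply_dropout(full, 1)
  expect_equal(length(forced$review_index), 2L)
  expect_true(forced$censored)

  cfg <- generator_config(n_clients = 5000L, seed = 31L)
  labels <- label_cohort(sample_cohort(cfg, include_interactions = FALSE),
                         quiet = TRUE)
  expect_lt(abs(mean(labels$n_reviews < 3L) - 0.60), 0.05)
})

test_that("cohort CSV round trip preserves observations and interactions", {
  cfg <- generator_config(n_clients = 12L, seed = 9L, n_interaction_types = 40L)
  cohort <- sample_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort_csv(cohort, dir)
  back <- read_cohort_csv(dir, n_interaction_types = 40L)
  # weeks survive only to CSV printed precision; everything else is exact
  expect_equal(cohort_observations(back), cohort_observations(cohort),
               tolerance = 1e-9)
  orig <- purrr::map(cohort, ~ dplyr::arrange(.x$interactions, review_index, type_id))
  got <- purrr::map(back, ~ dplyr::arrange(.x$interactions, review_index, type_id))
  for (id in names(orig)) {
    expect_equal(as.data.frame(got[[id]]), as.data.frame(orig[[id]]))
  }
})

test_that("generator config YAML round trip reproduces the cohort", {
  cfg <- generator_config(n_clients = 15L, seed = 4L, dropout_hazard = 0.4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  cfg2 <- read_generator_config(path)
  expect_identical(cohort_observations(sample_cohort(cfg2, FALSE)),
                   cohort_observations(sample_cohort(cfg, FALSE)))
})
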
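#' Calibrate generator archetype weights to target prevalences
#'
#' Finds a configuration whose labeled reliable-improvement prevalences match
#' the configured targets on pilot cohorts. Two monotone one-dimensional
#' searches are run in turn: (i) the total probability mass on the improver
#' archetypes (relative shape within the improver and non-improver groups is
#' preserved) is bisected against the PHQ-9 target; (ii) the GAD-7 change
#' scale is bisected against the GAD-7 target. The procedure is a
#' deterministic function of the configuration seed.
#'
#' @param config A [generator_config()] holding the targets.
#' @param tolerance Acceptable absolute deviation of each prevalence.
#' @param pilot_n Pilot cohort size per evaluation.
#' @param max_rounds Outer rounds alternating the two searches.
#' @return A calibrated `generator_config`.
#' @export
calibrate_prevalence <- function(config, tolerance = 0.03, pilot_n = 2000L,
                                 max_rounds = 3L) {
  stopifnot(inherits(config, "generator_config"))
  if (tolerance <= 0) {
    abort("`tolerance` must be positive.", class = "icbtri_config_error")
  }
  improvers <- c("steady_improver", "sudden_gain_improver", "late_improver")
  others <- c("non_responder", "deteriorator")
  w0 <- config$archetype_weights
  rel_imp <- normalize_or_uniform(w0[improvers])
  rel_oth <- normalize_or_uniform(w0[others])

  weights_at <- function(mass) {
    w <- c(mass * rel_imp, (1 - mass) * rel_oth)
    w[w < 0] <- 0
    w / sum(w)
  }
  prevalence_at <- function(cfg, which_seed) {
    cfg$n_clients <- as.integer(pilot_n)
    cfg$seed <- stage_seed(config$seed, paste0("calibration-pilot-", which_seed))
    lab <- label_cohort(sample_cohort(cfg, include_interactions = FALSE),
                        quiet = TRUE)
    c(phq = mean(lab$ri_phq), gad = mean(lab$ri_gad))
  }

  cfg <- config
  mass <- sum(w0[improvers])
  scale_gad <- cfg$gad_change_scale
  for (round in seq_len(max_rounds)) {
    ## (i) improver mass vs PHQ-9 target (prevalence increases with mass)
    lo <- 0; hi <- 1
    for (it in seq_len(8L)) {
      mass <- (lo + hi) / 2
      cfg$archetype_weights <- weights_at(mass)
      p <- prevalence_at(cfg, sprintf("mass-%d-%d", round, it))[["phq"]]
      if (p < cfg$target_prevalence_phq) lo <- mass else hi <- mass
    }
    ## (ii) GAD change scale vs GAD-7 target (prevalence increases with scale)
    lo2 <- 0.2; hi2 <- 2.0
    for (it in seq_len(8L)) {
      scale_gad <- (lo2 + hi2) / 2
      cfg$gad_change_scale <- scale_gad
      p <- prevalence_at(cfg, sprintf("scale-%d-%d", round, it))[["gad"]]
      if (p < cfg$target_prevalence_gad) lo2 <- scale_gad else hi2 <- scale_gad
    }
    check <- prevalence_at(cfg, paste0("check-", round))
    ok <- abs(check[["phq"]] - cfg$target_prevalence_phq) <= tolerance &&
      abs(check[["gad"]] - cfg$target_prevalence_gad) <= tolerance
    if (ok) {
      cfg$n_clients <- config$n_clients
      cfg$seed <- config$seed
      return(cfg)
    }
  }
  abort(
    sprintf(
      paste0("calibration failed: best achieved prevalences %.3f (PHQ-9, ",
             "target %.3f) and %.3f (GAD-7, target %.3f) at tolerance %.3f."),
      check[["phq"]], cfg$target_prevalence_phq,
      check[["gad"]], cfg$target_prevalence_gad, tolerance
    ),
    class = "icbtri_calibration_error",
    achieved_phq = unname(check[["phq"]]),
    achieved_gad = unname(check[["gad"]])
  )
}

normalize_or_uniform <- function(w) {
  w[is.na(w)] <- 0
  if (sum(w) <= 0) {
    setNames(rep(1 / length(w), length(w)), names(w))
  } else {
    w / sum(w)
  }
}
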
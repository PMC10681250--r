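#' Experiment configuration
#'
#' One configuration object driving the full study: simulate a cohort, label
#' it, split it, train the selected models on the selected feature sets for
#' the selected target instruments, evaluate dynamically, and run the error
#' analysis. Every stage seed is derived from the global seed by hashing
#' (seed, stage name), so adding a stage never perturbs the others.
#'
#' @param generator A [generator_config()] (its seed is overridden by the
#'   derived stage seed).
#' @param models Character subset of `"rnn"`, `"logistic_regression"`,
#'   `"random_forest"`, `"gradient_boosting"`, `"ema"`.
#' @param feature_sets Feature sets for the recurrent model.
#' @param targets Instruments to model (each gets its own models).
#' @param rnn An [rnn_config()] (its seed is overridden per stage).
#' @param ema_alpha EMA smoothing weight.
#' @param split_fractions Train/validation/test fractions.
#' @param min_t Minimum review period for the headline evaluation rows.
#' @param error_t Review period of the error analysis.
#' @param seed Global experiment seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(n_clients = 600L),
                              models = c("rnn", "logistic_regression", "ema"),
                              feature_sets = "Q",
                              targets = c("phq9", "gad7"),
                              rnn = rnn_config(max_epochs = 30L),
                              ema_alpha = 0.6,
                              split_fractions = c(train = 0.7,
                                                  validation = 0.2,
                                                  test = 0.1),
                              min_t = 3L,
                              error_t = 3L,
                              seed = 1L) {
  stopifnot(inherits(generator, "generator_config"), inherits(rnn, "rnn_config"))
  known <- c("rnn", STATIC_KINDS, "ema")
  if (!all(models %in% known)) {
    abort(sprintf("unknown model kinds: %s",
                  paste(setdiff(models, known), collapse = ", ")),
          class = "icbtri_config_error")
  }
  if (!all(feature_sets %in% FEATURE_SETS)) {
    abort("unknown feature set.", class = "icbtri_config_error")
  }
  targets <- vapply(targets, match_instrument, character(1L))
  structure(
    list(generator = generator, models = models, feature_sets = feature_sets,
         targets = unname(targets), rnn = rnn, ema_alpha = ema_alpha,
         split_fractions = split_fractions, min_t = as.integer(min_t),
         error_t = as.integer(error_t), seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run the full dynamic-prediction experiment
#'
#' Executes simulate, label, split, featurize/train, evaluate and
#' error-analysis stages from one configuration, returning a manifest with
#' every artifact and a content hash per deterministic stage.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress stage progress messages?
#' @return A list (class `experiment_manifest`) with elements `config`,
#'   `stage_seeds`, `labels`, `splits` (client ids per split), `models`
#'   (per target/model: handle and evaluation report), `reports` (tibble of
#'   evaluation rows across models), `errors` (error-analysis tables),
#'   `hashes`.
#' @export
run_experiment <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage_seeds <- purrr::map(
    setNames(nm = c("simulate", "split", "train", "evaluate")),
    ~ stage_seed(config$seed, .x)
  )

  say("stage simulate")
  gen <- config$generator
  gen$seed <- stage_seeds$simulate
  needs_interactions <- any(config$feature_sets %in% c("I", "I+Q"))
  cohort <- sample_cohort(gen, include_interactions = needs_interactions)
  labels <- label_cohort(cohort, quiet = quiet)

  say("stage split")
  splits <- split_data(cohort, labels, config$split_fractions,
                       seed = stage_seeds$split)

  say("stage train/evaluate")
  model_entries <- list()
  report_rows <- list()
  error_tables <- list()
  for (target in config$targets) {
    for (kind in config$models) {
      fsets <- if (kind == "rnn") config$feature_sets else "benchmark16"
      for (fs in fsets) {
        key <- paste(target, kind, fs, sep = "/")
        seed_k <- stage_seed(stage_seeds$train, key)
        model <- switch(
          kind,
          rnn = {
            cfg <- config$rnn
            cfg$seed <- seed_k
            train_rnn(splits$train, splits$validation, labels,
                      feature_set = fs, target_instrument = target,
                      config = cfg)
          },
          ema = ema_model(target, config$ema_alpha),
          train_static_classifier(kind, splits$train, labels,
                                  target_instrument = target, seed = seed_k)
        )
        preds <- prediction_set(model, splits$test, labels)
        report <- stratified_evaluation(preds, labels,
                                        target_instrument = target)
        report$target <- target
        report$model <- kind
        report$feature_set <- fs
        model_entries[[key]] <- list(model = model, predictions = preds,
                                     report = report)
        report_rows[[key]] <- report
        if (kind == "rnn" && fs == config$feature_sets[[1L]]) {
          val_preds <- prediction_set(model, splits$validation, labels)
          if (any(val_preds$t == config$error_t)) {
            error_tables[[target]] <- classify_errors(
              val_preds, splits$validation, t = config$error_t,
              target_instrument = target
            )
          }
        }
      }
    }
  }
  reports <- dplyr::bind_rows(report_rows)

  manifest <- list(
    config = config,
    stage_seeds = stage_seeds,
    n_clients = length(cohort),
    prevalence = c(phq = mean(labels$ri_phq), gad = mean(labels$ri_gad)),
    labels = labels,
    splits = purrr::map(splits, names),
    models = model_entries,
    reports = reports,
    errors = error_tables,
    hashes = list(
      cohort = rlang::hash(cohort_observations(cohort)),
      labels = rlang::hash(labels),
      splits = rlang::hash(purrr::map(splits, names)),
      reports = rlang::hash(reports)
    )
  )
  class(manifest) <- "experiment_manifest"
  manifest
}

#' @export
print.experiment_manifest <- function(x, ...) {
  cat(sprintf(
    "<experiment_manifest: %d clients, models %s, targets %s>\n",
    x$n_clients, paste(x$config$models, collapse = "/"),
    paste(x$config$targets, collapse = "/")
  ))
  invisible(x)
}

#' Align per-model evaluation reports into a ranked per-t table
#'
#' @param reports Named list of evaluation-report tibbles (one per model)
#'   sharing the same strata, or the `reports` tibble of a manifest.
#' @return Tibble with one row per (stratum_t, model), ranked by accuracy
#'   within each review period (`rank` 1 = most accurate).
#' @export
compare_models <- function(reports) {
  tbl <- if (is.data.frame(reports)) {
    reports
  } else {
    dplyr::bind_rows(purrr::imap(reports, function(r, nm) {
      if (!"model" %in% names(r)) r$model <- nm
      r
    }))
  }
  tbl <- tbl[tbl$severity == "overall", , drop = FALSE]
  strata_by_model <- split(tbl$stratum_t, tbl$model)
  ref <- sort(unique(strata_by_model[[1L]]))
  same <- all(vapply(strata_by_model,
                     function(s) identical(sort(unique(s)), ref), logical(1L)))
  if (!same) {
    abort("models do not share evaluation strata.",
          class = "icbtri_alignment_error")
  }
  tbl |>
    dplyr::group_by(.data$stratum_t) |>
    dplyr::mutate(rank = rank(-.data$accuracy, ties.method = "min")) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$stratum_t, .data$rank)
}
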
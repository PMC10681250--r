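pred_tbl <- function(labels, scores, threshold = 0.5,
                     client_id = paste0("c", seq_along(labels)),
                     t = rep(1L, length(labels))) {
  tibble::tibble(client_id = client_id, t = t, score = scores,
                 predicted = scores >= threshold, label = as.logical(labels))
}

test_that("confusion metrics match a hand-counted table", {
  p <- tibble::tibble(label = c(TRUE, TRUE, FALSE, FALSE),
                      predicted = c(TRUE, FALSE, FALSE, FALSE),
                      client_id = paste0("c", 1:4))
  cm <- confusion_metrics(p)
  expect_equal(cm$accuracy, 0.75)
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$specificity, 1.0)

  perfect <- tibble::tibble(label = c(TRUE, FALSE), predicted = c(TRUE, FALSE))
  expect_equal(unlist(confusion_metrics(perfect)),
               c(accuracy = 1, sensitivity = 1, specificity = 1))

  all_neg <- tibble::tibble(label = c(TRUE, FALSE), predicted = c(FALSE, FALSE))
  cm2 <- confusion_metrics(all_neg)
  expect_equal(cm2$sensitivity, 0)
  expect_equal(cm2$specificity, 1)

  no_pos <- tibble::tibble(label = c(FALSE, FALSE), predicted = c(FALSE, TRUE))
  expect_true(is.na(confusion_metrics(no_pos)$sensitivity))
})

test_that("AUROC equals the exhaustive pairwise-comparison oracle", {
  pairwise_auroc <- function(labels, scores) {
    pos <- scores[as.logical(labels)]
    neg <- scores[!as.logical(labels)]
    total <- 0
    for (p in pos) {
      for (q in neg) {
        total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
      }
    }
    total / (length(pos) * length(neg))
  }
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_true(is.na(auroc(c(1, 1), c(0.2, 0.3))))
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:50, 1L)
    labels <- c(0L, 1L, rbinom(n - 2L, 1L, 0.4))
    scores <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auroc(labels, scores), pairwise_auroc(labels, scores))
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  labels <- rbinom(200, 1, 0.3)
  labels[1:2] <- c(0L, 1L)
  scores <- round(runif(200), 2)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(labels, scores), ref, tolerance = 1e-12)
})

test_that("sensitivity at fixed specificity matches a threshold-sweep oracle", {
  sweep_oracle <- function(labels, scores, target) {
    labels <- as.logical(labels)
    cands <- c(sort(unique(scores)), Inf)
    best <- NULL
    for (thr in cands) {
      pred <- scores >= thr
      spec <- mean(!pred[!labels])
      sens <- mean(pred[labels])
      if (spec >= target &&
          (is.null(best) || spec < best$spec ||
           (spec == best$spec && sens > best$sens))) {
        best <- list(spec = spec, sens = sens)
      }
    }
    best$sens
  }
  sep <- pred_tbl(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  out <- sensitivity_at_specificity(sep$label, sep$score)
  expect_equal(out$sensitivity, rep(1, 3))
  expect_true(all(out$attainable))

  set.seed(17)
  for (i in 1:25) {
    n <- sample(10:50, 1L)
    labels <- c(0L, 1L, rbinom(n - 2L, 1L, 0.35))
    scores <- round(runif(n), 1)
    got <- sensitivity_at_specificity(labels, scores, c(0.5, 0.9, 0.95, 0.97))
    for (k in seq_len(nrow(got))) {
      expect_equal(got$sensitivity[[k]],
                   sweep_oracle(labels, scores, got$target[[k]]))
    }
    # monotone non-increasing in the target
    expect_true(all(diff(got$sensitivity) <= 1e-12))
  }

  tied <- sensitivity_at_specificity(c(1, 0, 1, 0), rep(0.5, 4), 0.9)
  expect_false(tied$attainable)
  expect_equal(tied$sensitivity, 0)

  # target 0 reproduces overall sensitivity at the all-positive threshold
  lab0 <- c(1, 0, 1, 0, 0, 1)
  sc0 <- c(0.9, 0.7, 0.6, 0.4, 0.2, 0.1)
  at0 <- sensitivity_at_specificity(lab0, sc0, 0)
  expect_equal(at0$sensitivity, 1)
})

test_that("stratified evaluation reduces to pooled metrics and respects min_t", {
  labels <- tibble::tibble(
    client_id = paste0("c", 1:8),
    severity_phq = factor(rep(c("mild", "severe"), each = 4L),
                          levels = c("mild", "moderate", "severe")),
    severity_gad = factor(rep("moderate", 8L),
                          levels = c("mild", "moderate", "severe"))
  )
  preds <- pred_tbl(labels = c(1, 0, 1, 0, 1, 0, 1, 0),
                    scores = c(0.9, 0.4, 0.3, 0.2, 0.8, 0.6, 0.7, 0.1),
                    client_id = paste0("c", 1:8),
                    t = rep(c(1L, 3L), 4L))
  rep_all <- stratified_evaluation(preds, labels, "phq9")
  overall <- rep_all[rep_all$stratum_t == "all" & rep_all$severity == "overall", ]
  expect_equal(overall$accuracy, mean(preds$predicted == preds$label))
  expect_equal(overall$n, 8L)

  # pooled accuracy is the prediction-count-weighted mean of stratum accuracies
  bands <- rep_all[rep_all$stratum_t == "all" & rep_all$severity != "overall", ]
  expect_equal(sum(bands$accuracy * bands$n) / sum(bands$n), overall$accuracy)
  expect_equal(sum(bands$n), overall$n)

  rep_t3 <- stratified_evaluation(preds, labels, "phq9", min_t = 3L)
  ov3 <- rep_t3[rep_t3$stratum_t == "all" & rep_t3$severity == "overall", ]
  keep <- preds$t >= 3L
  expect_equal(ov3$n, sum(keep))
  expect_equal(ov3$accuracy, mean(preds$predicted[keep] == preds$label[keep]))
})

test_that("cluster bootstrap is deterministic, collapses on zero variance, and shrinks with n", {
  acc <- function(p) mean(p$predicted == p$label)
  perfect <- pred_tbl(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2))
  ci <- bootstrap_ci(acc, perfect, n_boot = 200L, seed = 4L)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)

  set.seed(6)
  make_preds <- function(n) {
    pred_tbl(rbinom(n, 1, 0.5), runif(n), client_id = paste0("c", seq_len(n)))
  }
  p200 <- make_preds(200L)
  ci1 <- bootstrap_ci(acc, p200, n_boot = 300L, seed = 9L)
  ci2 <- bootstrap_ci(acc, p200, n_boot = 300L, seed = 9L)
  expect_identical(ci1, ci2)
  expect_true(ci1$lower <= ci1$estimate && ci1$estimate <= ci1$upper)

  p800 <- make_preds(800L)
  ci_big <- bootstrap_ci(acc, p800, n_boot = 300L, seed = 9L)
  w1 <- ci1$upper - ci1$lower
  w2 <- ci_big$upper - ci_big$lower
  # quadrupling n should roughly halve the width
  expect_lt(w2, 0.8 * w1)
  expect_gt(w2, 0.2 * w1)

  expect_error(bootstrap_ci(acc, p200, n_boot = 50L),
               class = "icbtri_config_error")
})

test_that("Kaplan-Meier estimates match a hand-computed product-limit table", {
  # six clients, all moderate baseline (PHQ-9 15): events at reviews 2, 2, 3,
  # 4; censored at 2 and 3. Hand product-limit: S(2) = 1 * (1 - 2/6) = 2/3;
  # S(3) = 2/3 * (1 - 1/3) = 4/9; S(4) = 4/9 * (1 - 1/1) = 0.
  recs <- list(
    make_record("A", c(15L, 8L)),                  # event at 2
    make_record("B", c(15L, 7L)),                  # event at 2
    make_record("C", c(15L, 14L)),                 # censored at 2
    make_record("D", c(15L, 14L, 8L)),             # event at 3
    make_record("E", c(15L, 13L, 12L)),            # censored at 3
    make_record("F", c(15L, 14L, 13L, 9L))         # event at 4
  )
  cohort <- make_cohort(recs)
  labels <- label_cohort(cohort, quiet = TRUE)
  km <- km_time_to_improvement(cohort, labels, "phq9")
  expect_equal(km$time, c(2, 3, 4))
  expect_equal(km$n_risk, c(6, 3, 1))
  expect_equal(km$n_event, c(2, 1, 1))
  expect_equal(km$survival, c(2 / 3, 4 / 9, 0), tolerance = 1e-12)
})

test_that("sustained improvement requires the criterion to hold through the last review", {
  # drops below threshold at review 2 but relapses at 3: event only if the
  # criterion holds at every later observed review
  relapse <- make_record("r", c(20L, 12L, 19L))
  st <- icbtri:::sustained_improvement_time(relapse, "phq9")
  expect_equal(st$event, 0L)
  regain <- make_record("g", c(20L, 12L, 19L, 13L))
  st2 <- icbtri:::sustained_improvement_time(regain, "phq9")
  expect_equal(st2$event, 1L)
  expect_equal(st2$time, 4L)
})

test_that("survival curves are flat at 1 when nobody improves and drop to 0 when all do", {
  flat <- make_cohort(list(make_record("x", c(15L, 15L, 15L)),
                           make_record("y", c(12L, 12L, 12L))))
  lab_flat <- label_cohort(flat, quiet = TRUE)
  km_flat <- km_time_to_improvement(flat, lab_flat, "phq9")
  expect_true(all(km_flat$n_event == 0))

  all_imp <- make_cohort(list(make_record("x", c(20L, 10L)),
                              make_record("y", c(18L, 9L))))
  lab_imp <- label_cohort(all_imp, quiet = TRUE)
  km_imp <- km_time_to_improvement(all_imp, lab_imp, "phq9")
  expect_equal(km_imp$survival[km_imp$time == 2], 0)
  # survival is non-increasing within each band
  for (b in unique(km_imp$severity)) {
    expect_true(all(diff(km_imp$survival[km_imp$severity == b]) <= 1e-12))
  }
})
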
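test_that("confusion matrix counts frames by true and predicted phase", {
  truth <- c("Marking", "Marking", "Injection", "Dissection")
  pred <- c("Marking", "Injection", "Injection", "Dissection")
  cm <- confusion_matrix(pred, truth)
  expect_identical(sum(cm), 4L)
  expect_identical(cm["Marking", "Marking"], 1L)
  expect_identical(cm["Marking", "Injection"], 1L)
  expect_identical(cm["Injection", "Injection"], 1L)
  expect_identical(cm["Dissection", "Dissection"], 1L)
  expect_equal(rowSums(cm)[["Marking"]], 2)
  expect_error(confusion_matrix(pred[1:3], truth), "length")
})

test_that("overall metrics match hand counts and degenerate cases", {
  truth <- c("Marking", "Marking", "Injection", "Dissection")
  pred <- c("Marking", "Injection", "Injection", "Dissection")
  om <- overall_metrics(confusion_matrix(pred, truth))
  expect_equal(om$accuracy, 0.75)
  # per-phase (present): M: tp1 fp0 fn1; Inj: tp1 fp1 fn0; D: tp1 fp0 fn0
  expect_equal(om$precision, mean(c(1, 0.5, 1)))
  expect_equal(om$recall, mean(c(0.5, 1, 1)))

  perfect <- confusion_matrix(truth, truth)
  omp <- overall_metrics(perfect)
  expect_equal(c(omp$accuracy, omp$precision, omp$recall), c(1, 1, 1))

  all_wrong <- confusion_matrix(rep("Idle", 3), rep("Marking", 3))
  expect_equal(overall_metrics(all_wrong)$accuracy, 0)
  expect_error(overall_metrics(matrix(0L, 4, 4)), "empty")

  # micro averaging pools counts: equals accuracy for single-label data
  omm <- overall_metrics(confusion_matrix(pred, truth), average = "micro")
  expect_equal(omm$precision, omm$accuracy)
  expect_equal(omm$recall, omm$accuracy)

  # accuracy from the matrix equals the direct frame-agreement fraction
  withr::with_seed(4, {
    t2 <- sample(esd_phases(), 500, replace = TRUE)
    p2 <- ifelse(stats::runif(500) < 0.3, sample(esd_phases(), 500, replace = TRUE), t2)
    expect_equal(overall_metrics(confusion_matrix(p2, t2))$accuracy,
                 mean(p2 == t2))
  })
})

test_that("ROC endpoints, tie handling and separability limits are exact", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$fpr[1], 0)
  expect_equal(perfect$tpr[length(perfect$tpr)], 1)
  expect_true(all(diff(perfect$fpr) >= 0) && all(diff(perfect$tpr) >= 0))

  tied <- roc_curve(rep(0.5, 10), c(1, 1, 1, 0, 0, 0, 0, 1, 0, 1))
  expect_identical(tied$auroc, 0.5)

  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")

  withr::with_seed(99, {
    scores <- stats::runif(10000)
    labels <- stats::rbinom(10000, 1, 0.5)
    a <- roc_curve(scores, labels)$auroc
    expect_gt(a, 0.49)
    expect_lt(a, 0.51)
  })
})

test_that("trapezoidal AUROC equals the Mann-Whitney rank formulation", {
  withr::with_seed(7, {
    for (rep in 1:200) {
      n <- sample(10:80, 1)
      # mix continuous and heavily tied score sets
      scores <- if (rep %% 2) stats::rnorm(n) else sample(seq(0, 1, 0.1), n, TRUE)
      labels <- stats::rbinom(n, 1, 0.4)
      if (sum(labels) %in% c(0, n)) next
      expect_equal(roc_curve(scores, labels)$auroc,
                   auroc_rank(scores, labels), tolerance = 1e-9)
    }
  })
})

test_that("AUROC agrees with an independent ROC implementation", {
  withr::with_seed(12, {
    scores <- c(stats::rnorm(60, 1), stats::rnorm(90))
    labels <- rep(c(1, 0), c(60, 90))
  })
  expect_equal(roc_curve(scores, labels)$auroc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-9)
})

test_that("Youden threshold maximises J with the high-threshold tie-break", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  labels <- c(1, 1, 0, 1, 0, 0)
  got <- youden_threshold(roc_curve(scores, labels))
  want <- brute_force_youden(scores, labels)
  expect_equal(got$threshold, want$threshold)
  expect_equal(got$j, want$j)

  withr::with_seed(8, {
    for (rep in 1:100) {
      n <- sample(8:60, 1)
      scores <- round(stats::runif(n), 2)
      labels <- stats::rbinom(n, 1, 0.5)
      if (sum(labels) %in% c(0, n)) next
      got <- youden_threshold(roc_curve(scores, labels))
      want <- brute_force_youden(scores, labels)
      expect_identical(got$threshold, want$threshold)
      expect_equal(got$j, want$j, tolerance = 1e-12)
    }
  })

  sep <- youden_threshold(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)))
  expect_equal(sep$j, 1)
})

test_that("per-phase metrics implement the printed ratios", {
  # synthetic counts: tp 8, tn 90, fp 1, fn 1
  scores <- c(rep(0.9, 8), rep(0.1, 90), 0.9, 0.1)
  truth <- c(rep("Marking", 8), rep("Idle", 90), "Idle", "Marking")
  pm <- phase_metrics(scores, truth, "Marking")
  expect_true(pm$available)
  expect_equal(pm$sensitivity, 8 / 9)
  expect_equal(pm$specificity, 90 / 91)
  expect_equal(pm$orderliness, 0.98)
  expect_identical(unname(pm$counts), c(8L, 90L, 1L, 1L))

  # perfect classifier
  pm2 <- phase_metrics(c(1, 1, 0, 0) * 0.9 + 0.05,
                       c("Idle", "Idle", "Marking", "Marking"), "Idle")
  expect_equal(c(pm2$sensitivity, pm2$specificity, pm2$orderliness), c(1, 1, 1))
  expect_equal(pm2$auroc, 1)

  # absent phase -> unavailable, no error
  pm3 <- phase_metrics(c(0.1, 0.2), c("Idle", "Idle"), "Marking")
  expect_false(pm3$available)
  expect_true(is.na(pm3$auroc))

  # random scores: orderliness at the Youden point is at least the majority rate
  withr::with_seed(21, {
    truth_r <- sample(c("Idle", "Dissection"), 4000, TRUE, prob = c(0.3, 0.7))
    pm4 <- phase_metrics(stats::runif(4000), truth_r, "Idle")
    expect_lt(pm4$orderliness, 0.78)
    expect_gt(pm4$auroc, 0.45)
    expect_lt(pm4$auroc, 0.55)
  })
})

test_that("Student-t intervals match the closed form", {
  ci <- t_confidence_interval(c(1, 2, 3, 4, 5))
  expect_equal(unname(ci), c(3, 1.036757, 4.963243), tolerance = 1e-6)
  same <- t_confidence_interval(rep(0.7, 4))
  expect_equal(unname(same), c(0.7, 0.7, 0.7))
  expect_error(t_confidence_interval(0.5), "at least 2")
})

test_that("paired t-test matches the closed form and is symmetric", {
  a <- c(1, 2, 3)
  b <- c(2, 3, 5)
  expect_equal(paired_t_test(a, b), 0.0571909584, tolerance = 1e-9)
  expect_equal(paired_t_test(b, a), paired_t_test(a, b))
  expect_error(paired_t_test(a, a), "zero variance")
  expect_error(paired_t_test(a, b[1:2]), "length")
})

test_that("pooled case evaluation aggregates frames and cases", {
  withr::with_seed(3, {
    mk <- function(id, n, acc) {
      truth <- annotation_track(id, 1, sample(esd_phases(), n, TRUE))
      good <- stats::runif(n) < acc
      lab <- ifelse(good, truth$labels, sample(esd_phases(), n, TRUE))
      probs <- matrix(0.02, n, 4)
      probs[cbind(seq_len(n), phase_code(lab) + 1L)] <- 0.94
      list(pred = prediction_track(id, 1, probs), truth = truth)
    }
    cases <- list(a = mk("a", 150, 0.95), b = mk("b", 120, 0.9),
                  c = mk("c", 90, 0.85))
  })
  ev <- evaluate_cases(lapply(cases, `[[`, "pred"),
                       lapply(cases, `[[`, "truth"))
  expect_identical(sum(ev$pooled$confusion), 360L)
  expect_identical(nrow(ev$per_case), 3L)
  expect_equal(ev$aggregate$accuracy[["mean"]], mean(ev$per_case$accuracy))
  expect_true(ev$aggregate$accuracy[["lower"]] < ev$aggregate$accuracy[["mean"]])
})
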
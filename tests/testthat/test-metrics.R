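test_that("accuracy, recall, specificity and precision follow their defining ratios", {
  m <- compute_metrics(TP = 9, FN = 1, TN = 8, FP = 2)
  expect_equal(m$ACC, 85)
  expect_equal(m$TPR, 90)
  expect_equal(m$TNR, 80)
  expect_equal(m$PPV, 9 / 11 * 100)
  perfect <- compute_metrics(TP = 10, FN = 0, TN = 10, FP = 0)
  expect_equal(unlist(perfect[, c("ACC", "TPR", "TNR", "PPV")]),
               c(ACC = 100, TPR = 100, TNR = 100, PPV = 100))
})

test_that("precision is flagged undefined when nothing is predicted positive", {
  m <- compute_metrics(TP = 0, FP = 0, TN = 5, FN = 5)
  expect_true(is.na(m$PPV))
  expect_false(m$ppv_defined)
})

test_that("degenerate confusion matrices are rejected", {
  expect_error(compute_metrics(TP = 3, FN = 2, TN = 0, FP = 0),
               "both classes")
  expect_error(compute_metrics(TP = -1, FN = 2, TN = 1, FP = 0),
               "non-negative")
})

test_that("metric identities hold on random confusion matrices against a direct-count oracle", {
  set.seed(17)
  for (i in 1:50) {
    P <- sample(2:80, 1); N <- sample(2:80, 1)
    TP <- sample(0:P, 1); TN <- sample(0:N, 1)
    m <- compute_metrics(TP = TP, FN = P - TP, TN = TN, FP = N - TN)
    # direct-count oracle: simulate labels and predictions and count
    truth <- c(rep("pos", P), rep("neg", N))
    pred <- c(rep("pos", TP), rep("neg", P - TP),
              rep("pos", N - TN), rep("neg", TN))
    expect_equal(m$ACC, mean(truth == pred) * 100)
    expect_equal(m$TPR, mean(pred[truth == "pos"] == "pos") * 100)
    expect_equal(m$TNR, mean(pred[truth == "neg"] == "neg") * 100)
    # ACC identity through the class-weighted rates
    expect_equal(m$ACC, (m$TPR * P + m$TNR * N) / (P + N))
  }
})

test_that("goodness index hits its analytic endpoints and chance value", {
  expect_equal(goodness_index(100, 100), 0)
  expect_equal(goodness_index(0, 0), sqrt(2))
  expect_equal(goodness_index(50, 50), sqrt(0.5), tolerance = 1e-12)
  expect_equal(round(goodness_index(50, 50), 2), 0.71)
  expect_error(goodness_index(120, 50), "\\[0, 100\\]")
})

test_that("goodness index is monotone non-increasing in TPR and TNR", {
  grid <- seq(0, 100, by = 5)
  for (tnr in c(0, 40, 80, 100)) {
    g <- goodness_index(grid, rep(tnr, length(grid)))
    expect_true(all(diff(g) <= 1e-12))
  }
  for (tpr in c(0, 40, 80, 100)) {
    g <- goodness_index(rep(tpr, length(grid)), grid)
    expect_true(all(diff(g) <= 1e-12))
  }
})

test_that("goodness categories split at 0.25 (inclusive) and 0.70 (inclusive)", {
  expect_equal(categorize_goodness(c(0.14, 0.25, 0.26, 0.70, 0.71, 1.0)),
               c("optimum", "optimum", "good", "good", "bad", "bad"))
  expect_error(categorize_goodness(1.5), "sqrt")
})

test_that("gates are evaluated in order and a failed gate blocks the rest", {
  bench <- tibble::tibble(
    experiment = "PDvsHC", positive = "PD",
    spec_id = c("low_acc", "low_tpr", "low_ppv", "passer"),
    # ACC fails / TPR fails / PPV fails / all pass
    TP = c(50, 70, 95, 90), FN = c(50, 30, 5, 10),
    TN = c(50, 95, 70, 85), FP = c(50, 5, 30, 15)
  )
  rep <- selection_report(bench, threshold = 80, auc = FALSE)
  low_acc <- rep[rep$spec_id == "low_acc", ]
  expect_false(low_acc$passed_acc)
  expect_true(is.na(low_acc$passed_recall))
  expect_true(is.na(low_acc$passed_precision))
  expect_equal(low_acc$category, "not_evaluated")
  low_tpr <- rep[rep$spec_id == "low_tpr", ]
  expect_true(low_tpr$passed_acc)
  expect_false(low_tpr$passed_recall)
  expect_true(is.na(low_tpr$passed_precision))
  low_ppv <- rep[rep$spec_id == "low_ppv", ]
  expect_false(low_ppv$passed_precision)
  expect_equal(low_ppv$category, "not_evaluated")
  passer <- rep[rep$spec_id == "passer", ]
  expect_true(all(c(passer$passed_acc, passer$passed_recall,
                    passer$passed_precision)))
  expect_false(is.na(passer$goodness))
  # formatted export renders blocked cells as "/"
  wide <- format_report(rep)
  expect_equal(wide$low_acc[wide$criterion == "TPR"], "/")
  expect_equal(wide$low_ppv[wide$criterion == "G"], "/")
})

test_that("threshold comparison is >= 80 on values rounded to one decimal", {
  # ACC 79.96 rounds to 80.0 and passes; 79.94 rounds to 79.9 and fails
  near <- tibble::tibble(
    experiment = "X", positive = "pos", spec_id = c("just_in", "just_out"),
    TP = c(1999, 1361), FN = c(1, 639), TN = c(1999, 1836), FP = c(1001, 164)
  )
  m1 <- compute_metrics(TP = 1999, FN = 1, TN = 1999, FP = 1001)
  expect_equal(round(m1$ACC, 1), 80.0)  # 79.96
  m2 <- compute_metrics(TP = 1361, FN = 639, TN = 1836, FP = 164)
  expect_equal(round(m2$ACC, 1), 79.9)
  rep <- selection_report(near, auc = FALSE)
  expect_true(rep$passed_acc[rep$spec_id == "just_in"])
  expect_false(rep$passed_acc[rep$spec_id == "just_out"])
})

test_that("any combination categorized optimum or good passed all three 80% gates", {
  feats <- make_blob_features(6, 5, sep = 2, seed = 41)
  bench <- suppressWarnings(run_bench(feats, k = 11, seed = 5))
  rep <- selection_report(bench)
  evaluated <- rep[rep$category %in% c("optimum", "good"), ]
  expect_gt(nrow(evaluated), 0)
  expect_true(all(round(evaluated$ACC, 1) >= 80))
  expect_true(all(round(evaluated$TPR, 1) >= 80))
  expect_true(all(round(evaluated$PPV, 1) >= 80))
})

test_that("best-classifier selection takes the lowest goodness, breaking ties by accuracy", {
  bench <- tibble::tibble(
    experiment = "E1", positive = "pos",
    spec_id = c("g14", "g20"),
    TP = c(99, 95), FN = c(1, 5), TN = c(31, 35), FP = c(5, 1)
  )
  rep <- selection_report(bench, auc = FALSE)
  best <- select_best(rep)
  expect_equal(best$spec_id, rep$spec_id[which.min(rep$goodness)])
  # no passers -> "none"
  none_bench <- tibble::tibble(
    experiment = "E2", positive = "pos", spec_id = "weak",
    TP = 50, FN = 50, TN = 50, FP = 50
  )
  none_rep <- selection_report(none_bench, auc = FALSE)
  expect_equal(select_best(none_rep)$spec_id, "none")
  # single passer selected regardless of its goodness
  single <- tibble::tibble(
    experiment = "E3", positive = "pos", spec_id = "only",
    TP = 90, FN = 10, TN = 80, FP = 20
  )
  expect_equal(select_best(selection_report(single, auc = FALSE))$spec_id,
               "only")
})

test_that("AUC equals brute-force positive-negative pair counting on random instances", {
  set.seed(23)
  for (i in 1:50) {
    n_pos <- sample(3:15, 1); n_neg <- sample(3:15, 1)
    scores <- round(c(rnorm(n_pos, 0.5), rnorm(n_neg)), 1)  # force ties
    labels <- c(rep("pos", n_pos), rep("neg", n_neg))
    # oracle: fraction of (pos, neg) pairs ranked correctly, ties half
    sp <- scores[labels == "pos"]; sn <- scores[labels == "neg"]
    pairs <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(scores, labels, "pos"), mean(pairs),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC and is 1 for perfectly ranked scores", {
  skip_if_not_installed("pROC")
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("p", "p", "n", "n"), "p"),
               1)
  set.seed(29)
  scores <- rnorm(40)
  labels <- sample(c("p", "n"), 40, replace = TRUE, prob = c(0.4, 0.6))
  ours <- roc_auc(scores, labels, "p")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_error(roc_auc(1:3, c("p", "p", "p"), "p"), "both classes")
})

test_that("label-independent scores give chance-level AUC at large n", {
  set.seed(31)
  scores <- rnorm(2000)
  labels <- sample(c("p", "n"), 2000, replace = TRUE)
  expect_equal(roc_auc(scores, labels, "p"), 0.5, tolerance = 0.04)
})

test_that("the reference best-classifier quadruple for PD vs HC is reproduced exactly by an integer confusion matrix", {
  hits <- find_consistent_matrices(acc = 95.6, tpr = 99.0, ppv = 95.2,
                                   g = 0.14, max_total = 200,
                                   tol_pct = 0.05, tol_g = 0.005)
  expect_gt(nrow(hits), 0)
  # one of the matches also reproduces the reported 6 misclassifications
  expect_true(any(hits$FP + hits$FN == 6))
})
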
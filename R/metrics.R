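# Selection metrics: accuracy/recall/precision computed from confusion
# matrices, the ROC-space goodness index with its categories, ordered 80%
# threshold gates, best-classifier selection and AUC.

#' Classification metrics from a confusion matrix
#'
#' Accuracy `ACC = (TP+TN)/(P+N) x 100`, recall `TPR = TP/(TP+FN) x 100`,
#' specificity `TNR = TN/(TN+FP) x 100` and precision
#' `PPV = TP/(TP+FP) x 100`. Precision is undefined (returned as `NA`
#' with `ppv_defined = FALSE`) when no sample was predicted positive.
#'
#' @param cm a one-row confusion matrix tibble (`TP`, `FP`, `TN`, `FN`),
#'   or four counts given separately.
#' @param TP,FP,TN,FN counts (used when `cm` is missing).
#' @return a one-row tibble: `ACC`, `TPR`, `TNR`, `PPV` (percent),
#'   `ppv_defined`.
#' @examples
#' compute_metrics(TP = 9, FN = 1, TN = 8, FP = 2)
#' @export
compute_metrics <- function(cm = NULL, TP = cm$TP, FP = cm$FP, TN = cm$TN,
                            FN = cm$FN) {
  P <- TP + FN
  N <- TN + FP
  if (any(c(TP, FP, TN, FN) < 0)) {
    stop("confusion-matrix counts must be non-negative", call. = FALSE)
  }
  if (P == 0 || N == 0) {
    stop("both classes must be present (P > 0 and N > 0)", call. = FALSE)
  }
  ppv_defined <- (TP + FP) > 0
  tibble::tibble(
    ACC = (TP + TN) / (P + N) * 100,
    TPR = TP / P * 100,
    TNR = TN / N * 100,
    PPV = ifelse(ppv_defined, TP / (TP + FP) * 100, NA_real_),
    ppv_defined = ppv_defined
  )
}

#' ROC-space goodness index
#'
#' Euclidean distance, in the unit ROC square, between the classifier's
#' operating point and the perfect-classifier corner (false positive rate
#' 0, true positive rate 1): `sqrt((1 - TPR/100)^2 + (1 - TNR/100)^2)`.
#' Ranges from 0 (perfect) to sqrt(2) (worst); a chance-level classifier
#' (TPR = TNR = 50%) sits at ~0.707.
#'
#' @param TPR,TNR true positive / true negative rates, percent (0-100).
#' @return numeric goodness index (vectorized).
#' @examples
#' goodness_index(100, 100)  # 0
#' goodness_index(50, 50)    # ~0.707
#' @export
goodness_index <- function(TPR, TNR) {
  if (any(TPR < 0 | TPR > 100 | TNR < 0 | TNR > 100, na.rm = TRUE)) {
    stop("TPR and TNR must be percentages in [0, 100]", call. = FALSE)
  }
  sqrt((1 - TPR / 100)^2 + (1 - TNR / 100)^2)
}

#' Categorize a goodness index
#'
#' `optimum` for G <= 0.25, `good` for 0.25 < G <= 0.70, `bad` for
#' G > 0.70. The chance-level point value G = 0.70 falls inside the
#' `good` interval; callers wanting to flag it can compare against
#' [goodness_index()]`(50, 50)` directly.
#'
#' @param goodness numeric goodness index values in `[0, sqrt(2)]`.
#' @return character vector of categories.
#' @export
categorize_goodness <- function(goodness) {
  if (any(goodness < 0 | goodness > sqrt(2) + 1e-12, na.rm = TRUE)) {
    stop("goodness index must lie in [0, sqrt(2)]", call. = FALSE)
  }
  dplyr::case_when(
    is.na(goodness) ~ NA_character_,
    goodness <= 0.25 ~ "optimum",
    goodness <= 0.70 ~ "good",
    TRUE ~ "bad"
  )
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic normalized by the number
#' of positive-negative pairs, which equals trapezoidal integration of
#' the empirical ROC curve with tied scores handled by averaging.
#'
#' @param scores numeric positive-class scores.
#' @param labels true labels.
#' @param positive label of the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive) {
  is_pos <- labels == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC curve points
#'
#' @inheritParams roc_auc
#' @return a tibble with columns `threshold`, `fpr`, `tpr`, ordered from
#'   the all-negative to the all-positive operating point.
#' @export
roc_points <- function(scores, labels, positive) {
  is_pos <- labels == positive
  ord <- order(scores, decreasing = TRUE)
  thr <- unique(scores[ord])
  pts <- purrr::map_dfr(thr, function(th) {
    pred <- scores >= th
    tibble::tibble(
      threshold = th,
      fpr = sum(pred & !is_pos) / sum(!is_pos),
      tpr = sum(pred & is_pos) / sum(is_pos)
    )
  })
  dplyr::bind_rows(
    tibble::tibble(threshold = Inf, fpr = 0, tpr = 0),
    pts,
    tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1)
  )
}

#' Apply the ordered selection gates and goodness evaluation
#'
#' Implements the selection flow: three threshold gates evaluated in
#' order (accuracy, then recall, then precision, each compared as >=
#' `threshold` on values rounded to one decimal); a failed gate blocks
#' the later ones. Combinations passing all three gates receive a
#' goodness index and category; blocked ones are `not_evaluated`.
#'
#' @param bench a `posture_bench` from [run_bench()] (or any tibble with
#'   `experiment`, `spec_id`, `TP`, `FP`, `TN`, `FN` and optionally a
#'   `scores` list column, used for AUC).
#' @param threshold gate threshold in percent.
#' @param auc compute pooled out-of-fold AUC for gate-passing
#'   combinations (requires the `scores` column).
#' @return a tibble of class `selection_report`: metrics, gate booleans
#'   (`passed_acc`, `passed_recall`, `passed_precision`; `NA` when
#'   blocked by an earlier gate), `goodness`, `category`, `AUC`,
#'   `selected` (best per experiment).
#' @export
selection_report <- function(bench, threshold = 80, auc = TRUE) {
  r1 <- function(x) round(x, 1)
  rows <- purrr::map_dfr(seq_len(nrow(bench)), function(i) {
    b <- bench[i, ]
    m <- compute_metrics(TP = b$TP, FP = b$FP, TN = b$TN, FN = b$FN)
    passed_acc <- r1(m$ACC) >= threshold
    passed_recall <- if (passed_acc) r1(m$TPR) >= threshold else NA
    passed_precision <- if (isTRUE(passed_recall)) {
      !is.na(m$PPV) && r1(m$PPV) >= threshold
    } else NA
    all_gates <- isTRUE(passed_acc) && isTRUE(passed_recall) &&
      isTRUE(passed_precision)
    g <- if (all_gates) goodness_index(m$TPR, m$TNR) else NA_real_
    auc_val <- if (all_gates && auc && "scores" %in% names(b)) {
      sc <- b$scores[[1]]
      roc_auc(sc$score, sc$truth, b$positive)
    } else NA_real_
    dplyr::bind_cols(
      b[, intersect(c("experiment", "positive", "spec_id", "family",
                      "variant", "TP", "FP", "TN", "FN"), names(b))],
      m[, c("ACC", "TPR", "TNR", "PPV")],
      tibble::tibble(
        passed_acc = passed_acc,
        passed_recall = passed_recall,
        passed_precision = passed_precision,
        goodness = g,
        category = ifelse(all_gates, categorize_goodness(g),
                          "not_evaluated"),
        AUC = auc_val
      )
    )
  })
  rows <- dplyr::mutate(tibble::as_tibble(rows), selected = FALSE)
  for (ex in unique(rows$experiment)) {
    best <- select_best_row(rows[rows$experiment == ex, ])
    if (!is.na(best)) {
      rows$selected[rows$experiment == ex][best] <- TRUE
    }
  }
  structure(rows, class = c("selection_report", class(rows)),
            threshold = threshold)
}

# index of the best gate-passing row (lowest goodness, ties by higher
# accuracy then lexicographic spec id), or NA when no row passes
select_best_row <- function(rows) {
  cand <- which(rows$category %in% c("optimum", "good", "bad") &
                  !is.na(rows$goodness))
  if (length(cand) == 0) return(NA_integer_)
  ord <- order(rows$goodness[cand], -rows$ACC[cand], rows$spec_id[cand])
  cand[ord[1]]
}

#' Best classifier per experiment
#'
#' Among gate-passing combinations of each experiment, selects the one
#' with the lowest goodness index (ties broken by higher accuracy, then
#' spec id). Experiments with no gate passer report `"none"`.
#'
#' @param report a `selection_report`.
#' @return a tibble: `experiment`, `spec_id` (or `"none"`), `goodness`,
#'   `ACC`, `category`.
#' @export
select_best <- function(report) {
  purrr::map_dfr(unique(report$experiment), function(ex) {
    rows <- report[report$experiment == ex, ]
    i <- select_best_row(rows)
    if (is.na(i)) {
      tibble::tibble(experiment = ex, spec_id = "none",
                     goodness = NA_real_, ACC = NA_real_,
                     category = NA_character_)
    } else {
      tibble::tibble(experiment = ex, spec_id = rows$spec_id[i],
                     goodness = rows$goodness[i], ACC = rows$ACC[i],
                     category = rows$category[i])
    }
  })
}

#' Export a selection report in the blocked-gate table layout
#'
#' One row per experiment and criterion (ACC, TPR, PPV, G), classifiers
#' as columns; metrics blocked by a failed earlier gate are rendered as
#' `"/"`.
#'
#' @param report a `selection_report`.
#' @return a tibble in wide layout with character cells.
#' @export
format_report <- function(report) {
  fmt <- function(x, digits) {
    ifelse(is.na(x), "/", formatC(round(x, digits), format = "f",
                                  digits = digits))
  }
  long <- purrr::map_dfr(seq_len(nrow(report)), function(i) {
    r <- report[i, ]
    tpr <- if (isTRUE(r$passed_acc)) r$TPR else NA_real_
    ppv <- if (isTRUE(r$passed_recall)) r$PPV else NA_real_
    tibble::tibble(
      experiment = r$experiment, spec_id = r$spec_id,
      criterion = c("ACC", "TPR", "PPV", "G"),
      value = c(fmt(r$ACC, 1), fmt(tpr, 1), fmt(ppv, 1),
                fmt(r$goodness, 2))
    )
  })
  tidyr::pivot_wider(long, names_from = "spec_id", values_from = "value")
}

#' Brute-force search for confusion matrices matching printed metrics
#'
#' Scans all integer confusion matrices with total sample count up to
#' `max_total` for ones whose accuracy, recall, precision and goodness
#' index reproduce a printed quadruple within the given tolerances
#' (defaults: half of one printed decimal for the percentages). Used as a
#' consistency oracle between the metric implementations and externally reported
#' result tables.
#'
#' @param acc,tpr,ppv target percentages.
#' @param g target goodness index.
#' @param max_total maximum `P + N`.
#' @param tol_pct absolute tolerance on the percentages.
#' @param tol_g absolute tolerance on the goodness index.
#' @return a tibble of matching matrices (`TP`, `FP`, `TN`, `FN`, plus
#'   the achieved metrics), possibly empty.
#' @export
find_consistent_matrices <- function(acc, tpr, ppv, g, max_total = 200,
                                     tol_pct = 0.05, tol_g = 0.005) {
  out <- list()
  for (P in 1:(max_total - 1)) {
    # TP values whose recall matches the printed value
    tp <- which(abs((0:P) / P * 100 - tpr) <= tol_pct + 1e-9) - 1L
    if (length(tp) == 0) next
    for (TP in tp) {
      n_max <- max_total - P
      grid <- tidyr::crossing(N = 1:n_max, TN = 0:n_max)
      grid <- grid[grid$TN <= grid$N, ]
      FP <- grid$N - grid$TN
      ACC <- (TP + grid$TN) / (P + grid$N) * 100
      PPV <- ifelse(TP + FP > 0, TP / (TP + FP) * 100, NA)
      TNR <- grid$TN / grid$N * 100
      G <- goodness_index(rep(TP / P * 100, nrow(grid)), TNR)
      ok <- abs(ACC - acc) <= tol_pct + 1e-9 &
        !is.na(PPV) & abs(PPV - ppv) <= tol_pct + 1e-9 &
        abs(G - g) <= tol_g + 1e-9
      if (any(ok)) {
        out[[length(out) + 1]] <- tibble::tibble(
          TP = TP, FP = FP[ok], TN = grid$TN[ok], FN = P - TP,
          ACC = ACC[ok], TPR = TP / P * 100, TNR = TNR[ok],
          PPV = PPV[ok], G = G[ok]
        )
      }
    }
  }
  if (length(out) == 0) {
    tibble::tibble(TP = integer(), FP = integer(), TN = integer(),
                   FN = integer(), ACC = numeric(), TPR = numeric(),
                   TNR = numeric(), PPV = numeric(), G = numeric())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Write / read a selection report
#'
#' @param report a `selection_report`.
#' @param path file path (`.csv` for the formatted table layout, `.json`
#'   for the full report).
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      dplyr::select(tibble::as_tibble(report), -dplyr::any_of("scores")),
      path, auto_unbox = TRUE, digits = NA, na = "null"
    )
  } else {
    readr::write_csv(format_report(report), path)
  }
  invisible(path)
}
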
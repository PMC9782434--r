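# broom-style tidiers and ggplot2 autoplot methods for bench results and
# selection reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a classifier benchmark
#'
#' One row per experiment x classifier combination with the pooled
#' confusion-matrix counts and derived metrics.
#'
#' @param x a `posture_bench` from [run_bench()].
#' @param ... unused.
#' @return a tibble.
#' @method tidy posture_bench
#' @export
tidy.posture_bench <- function(x, ...) {
  x <- tibble::as_tibble(x)
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    b <- x[i, ]
    dplyr::bind_cols(
      b[, c("experiment", "spec_id", "family", "variant",
            "TP", "FP", "TN", "FN", "k_used")],
      compute_metrics(TP = b$TP, FP = b$FP, TN = b$TN,
                      FN = b$FN)[, c("ACC", "TPR", "TNR", "PPV")]
    )
  })
}

#' @rdname tidy.posture_bench
#' @method glance posture_bench
#' @export
glance.posture_bench <- function(x, ...) {
  tibble::tibble(
    n_combinations = nrow(x),
    n_experiments = length(unique(x$experiment)),
    n_classifiers = length(unique(x$spec_id)),
    k = attr(x, "k") %||% NA_integer_,
    seed = attr(x, "seed") %||% NA_integer_
  )
}

#' Tidy a selection report
#'
#' @param x a `selection_report` from [selection_report()].
#' @param ... unused.
#' @return the report as a plain tibble (metrics, gate outcomes,
#'   goodness, category, AUC, selection flag).
#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.selection_report
#' @method glance selection_report
#' @export
glance.selection_report <- function(x, ...) {
  tibble::tibble(
    threshold = attr(x, "threshold") %||% NA_real_,
    n_combinations = nrow(x),
    n_gate_passers = sum(x$category != "not_evaluated"),
    n_optimum = sum(x$category == "optimum"),
    n_good = sum(x$category == "good"),
    n_bad = sum(x$category == "bad")
  )
}

#' @method autoplot selection_report
#' @export
autoplot.selection_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- ifelse(df$category == "not_evaluated", NA, df$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$spec_id,
                                   y = .data$experiment)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$goodness),
                       color = "grey80") +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(is.na(.data$goodness), "/",
                                  sprintf("%.2f", .data$goodness))),
      size = 3
    ) +
    ggplot2::scale_fill_gradient(low = "forestgreen", high = "orangered",
                                 na.value = "grey95",
                                 limits = c(0, sqrt(2))) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "goodness",
      title = "Goodness index of gate-passing classifiers",
      subtitle = "\"/\" = blocked by a failed threshold gate"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' ROC curve plot for selected classifiers
#'
#' @param bench a `posture_bench` with out-of-fold `scores`.
#' @param report optional `selection_report`; when given, only the
#'   selected (best) classifier per experiment is drawn.
#' @return a ggplot object.
#' @export
plot_roc <- function(bench, report = NULL) {
  rows <- seq_len(nrow(bench))
  if (!is.null(report)) {
    sel <- report[report$selected, c("experiment", "spec_id")]
    rows <- which(paste(bench$experiment, bench$spec_id) %in%
                    paste(sel$experiment, sel$spec_id))
  }
  df <- purrr::map_dfr(rows, function(i) {
    b <- bench[i, ]
    sc <- b$scores[[1]]
    pts <- roc_points(sc$score, sc$truth, b$positive)
    auc <- roc_auc(sc$score, sc$truth, b$positive)
    dplyr::mutate(pts, curve = sprintf("%s: %s (AUC %.2f)",
                                       b$experiment, b$spec_id, auc))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   color = .data$curve)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  color = NULL, title = "Pooled out-of-fold ROC curves")
}
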
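# Classifier benchmark: 13 classifier variants (decision trees, k-NN,
# polynomial SVMs, a shallow neural network) x 4 classification
# experiments, cross-validated into pooled confusion matrices.

#' The 13 classifier variants
#'
#' Preset configurations in the style of point-and-click classification
#' apps: three decision trees differing in the maximum number of splits,
#' six k-nearest-neighbour variants differing in neighbourhood size,
#' distance metric and vote weighting, three polynomial-kernel support
#' vector machines, and one shallow neural network (one hidden layer of
#' 10 neurons, 2-unit softmax output).
#'
#' @return a tibble: `spec_id`, `family` (`DT`, `KNN`, `SVM`, `ANN`),
#'   `variant`, and hyperparameter columns (`max_splits`, `k`, `metric`,
#'   `weighting`, `degree`, `hidden`).
#' @export
classifier_specs <- function() {
  tibble::tribble(
    ~spec_id,  ~family, ~variant,   ~max_splits, ~k,  ~metric,      ~weighting,    ~degree, ~hidden,
    "DT_fine",   "DT",  "fine",     100L,        NA,  NA,           NA,            NA,      NA,
    "DT_medium", "DT",  "medium",   20L,         NA,  NA,           NA,            NA,      NA,
    "DT_coarse", "DT",  "coarse",   4L,          NA,  NA,           NA,            NA,      NA,
    "KNN_fine",  "KNN", "fine",     NA,          1L,  "euclidean",  "equal",       NA,      NA,
    "KNN_medium","KNN", "medium",   NA,          10L, "euclidean",  "equal",       NA,      NA,
    "KNN_coarse","KNN", "coarse",   NA,          100L,"euclidean",  "equal",       NA,      NA,
    "KNN_cosine","KNN", "cosine",   NA,          10L, "cosine",     "equal",       NA,      NA,
    "KNN_cubic", "KNN", "cubic",    NA,          10L, "minkowski3", "equal",       NA,      NA,
    "KNN_weighted","KNN","weighted",NA,          10L, "euclidean",  "sq_inverse",  NA,      NA,
    "SVM_linear","SVM", "linear",   NA,          NA,  NA,           NA,            1L,      NA,
    "SVM_quadratic","SVM","quadratic",NA,        NA,  NA,           NA,            2L,      NA,
    "SVM_cubic", "SVM", "cubic",    NA,          NA,  NA,           NA,            3L,      NA,
    "ANN",       "ANN", "shallow",  NA,          NA,  NA,           NA,            NA,      10L
  )
}

#' The four classification experiments
#'
#' Each experiment selects rows of the feature table and defines the
#' positive class: PD vs HC (both medication states of every patient
#' against controls, positive = PD), OFF vs HC (positive = OFF), ON vs HC
#' (positive = ON), OFF vs ON (within patients, positive = ON).
#'
#' @return a tibble: `experiment`, `positive`, `negative`.
#' @export
experiment_defs <- function() {
  tibble::tribble(
    ~experiment, ~positive, ~negative,
    "PDvsHC",    "PD",      "HC",
    "OFFvsHC",   "OFF",     "HC",
    "ONvsHC",    "ON",      "HC",
    "OFFvsON",   "ON",      "OFF"
  )
}

#' Enumerate the full experiment x classifier bench
#'
#' @param experiments tibble from [experiment_defs()] (or a subset).
#' @param specs tibble from [classifier_specs()] (or a subset).
#' @return the cross product in deterministic order (experiments outer,
#'   specs inner), with all columns of both inputs.
#' @examples
#' nrow(enumerate_bench())  # 52
#' @export
enumerate_bench <- function(experiments = experiment_defs(),
                            specs = classifier_specs()) {
  if (nrow(experiments) == 0 || nrow(specs) == 0) {
    out <- dplyr::bind_cols(experiments[0, ], specs[0, ])
    return(out)
  }
  dplyr::bind_cols(
    experiments[rep(seq_len(nrow(experiments)), each = nrow(specs)), ],
    specs[rep(seq_len(nrow(specs)), times = nrow(experiments)), ]
  )
}

# rows and labels of the feature table entering one experiment
experiment_rows <- function(features, experiment) {
  switch(experiment,
    PDvsHC = dplyr::mutate(features, label = .data$group),
    OFFvsHC = dplyr::mutate(
      dplyr::filter(features, .data$state %in% c("OFF", "none")),
      label = ifelse(.data$group == "HC", "HC", "OFF")
    ),
    ONvsHC = dplyr::mutate(
      dplyr::filter(features, .data$state %in% c("ON", "none")),
      label = ifelse(.data$group == "HC", "HC", "ON")
    ),
    OFFvsON = dplyr::mutate(
      dplyr::filter(features, .data$group == "PD"),
      label = .data$state
    ),
    stop("unknown experiment: ", experiment, call. = FALSE)
  )
}

# --- fold construction -------------------------------------------------

# stratified, subject-grouped fold assignment: subjects (not rows) are
# dealt into folds round-robin within each subject-level class so that a
# subject's rows never straddle the train/test boundary
make_folds <- function(subject_ids, labels, k, seed) {
  subjects <- unique(subject_ids)
  subj_label <- labels[match(subjects, subject_ids)]
  k_eff <- min(k, length(subjects))
  if (k_eff < k) {
    warning(sprintf("k reduced from %d to %d (number of subjects)",
                    k, k_eff), call. = FALSE)
  }
  assign <- integer(length(subjects))
  offset <- 0L
  with_seed(seed, {
    for (cl in unique(subj_label)) {
      idx <- sample(which(subj_label == cl))
      assign[idx] <- ((seq_along(idx) - 1L + offset) %% k_eff) + 1L
      offset <- offset + length(idx)
    }
  })
  assign[match(subject_ids, subjects)]
}

# leave-one-subject-out folds
make_loso_folds <- function(subject_ids) {
  match(subject_ids, unique(subject_ids))
}

# z-score standardization fitted on the training rows only
fold_standardize <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(
    train = sweep(sweep(x_train, 2, mu), 2, sdv, `/`),
    test = sweep(sweep(x_test, 2, mu), 2, sdv, `/`),
    mean = mu, sd = sdv
  )
}

# --- classifier backends ----------------------------------------------
# each fit function returns list(labels = predicted class, scores =
# positive-class score) for the test rows

fit_dt <- function(x_train, y_train, x_test, max_splits, positive) {
  df <- data.frame(.y = y_train, x_train, check.names = FALSE)
  tree <- rpart::rpart(
    .y ~ ., data = df, method = "class",
    control = rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0,
                                   xval = 0, maxsurrogate = 0)
  )
  # prune back to at most max_splits splits via the complexity table
  cpt <- tree$cptable
  ok <- cpt[, "nsplit"] <= max_splits
  if (any(ok)) {
    cp_target <- cpt[max(which(ok)), "CP"]
    tree <- rpart::prune(tree, cp = cp_target + 1e-12)
  }
  newdata <- data.frame(x_test, check.names = FALSE)
  prob <- predict(tree, newdata = newdata, type = "prob")
  lab <- colnames(prob)[max.col(prob, ties.method = "first")]
  list(labels = lab, scores = prob[, positive])
}

# distance matrix between test (rows) and train points
knn_distances <- function(x_test, x_train, metric) {
  switch(metric,
    euclidean = {
      cross <- x_test %*% t(x_train)
      d2 <- outer(rowSums(x_test^2), rowSums(x_train^2), `+`) - 2 * cross
      sqrt(pmax(d2, 0))
    },
    minkowski3 = {
      t(apply(x_test, 1, function(v) {
        (colSums(abs(t(x_train) - v)^3))^(1 / 3)
      }))
    },
    cosine = {
      nt <- sqrt(rowSums(x_test^2)); nr <- sqrt(rowSums(x_train^2))
      nt[nt == 0] <- 1; nr[nr == 0] <- 1
      1 - (x_test %*% t(x_train)) / outer(nt, nr)
    },
    stop("unknown metric: ", metric, call. = FALSE)
  )
}

# k-nearest-neighbour prediction with explicit tie-breaking: voting ties
# go to the nearest neighbour's class; equidistant neighbours are taken
# in training-row order. Squared-inverse-distance weighting gives an
# exact-match neighbour (distance 0) full weight.
knn_predict <- function(x_train, y_train, x_test, k, metric, weighting,
                        positive) {
  n_train <- nrow(x_train)
  k_eff <- if (k >= n_train) max(n_train - 1L, 1L) else k
  d <- knn_distances(x_test, x_train, metric)
  labels <- character(nrow(x_test))
  scores <- numeric(nrow(x_test))
  classes <- sort(unique(y_train))
  for (i in seq_len(nrow(x_test))) {
    ord <- order(d[i, ])  # stable: equidistant -> lowest row index
    nb <- ord[seq_len(k_eff)]
    w <- if (weighting == "sq_inverse") {
      di <- d[i, nb]
      if (any(di == 0)) as.numeric(di == 0) else 1 / di^2
    } else rep(1, k_eff)
    votes <- vapply(classes, function(cl) sum(w[y_train[nb] == cl]), 0)
    top <- classes[votes == max(votes)]
    labels[i] <- if (length(top) == 1) top else y_train[nb[1]]
    scores[i] <- votes[match(positive, classes)] / sum(votes)
  }
  list(labels = labels, scores = scores)
}

fit_svm <- function(x_train, y_train, x_test, degree, positive) {
  y <- factor(y_train)
  fit <- e1071::svm(
    x = x_train, y = y, kernel = "polynomial", degree = degree,
    gamma = 1, coef0 = 1, cost = 1, scale = FALSE
  )
  pred <- predict(fit, x_test, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # orient decision values so larger means more positive-class
  pair <- colnames(dv)[1]
  score <- if (startsWith(pair, paste0(positive, "/"))) dv[, 1] else -dv[, 1]
  list(labels = as.character(pred), scores = as.numeric(score))
}

fit_ann <- function(x_train, y_train, x_test, hidden, positive, seed) {
  y_ind <- nnet::class.ind(factor(y_train))
  fit <- with_seed(seed, nnet::nnet(
    x = x_train, y = y_ind, size = hidden, softmax = TRUE,
    decay = 0.01, maxit = 200, MaxNWts = 5000, trace = FALSE
  ))
  prob <- predict(fit, x_test)
  lab <- colnames(y_ind)[max.col(prob, ties.method = "first")]
  list(labels = lab, scores = prob[, positive])
}

# --- cross-validation --------------------------------------------------

#' Cross-validate one classifier on one experiment
#'
#' Runs seeded, stratified, subject-grouped k-fold cross-validation (or
#' leave-one-subject-out for the neural network) and pools the
#' out-of-fold predictions into a single confusion matrix. Features are
#' z-scored using training-fold statistics for the distance- and
#' margin-based families (k-NN, SVM, ANN); trees use the raw features.
#'
#' @param features feature table (`subject_id`, `group`, `state`, feature
#'   columns).
#' @param experiment experiment name (see [experiment_defs()]) or a
#'   one-row experiment definition.
#' @param spec one-row classifier spec from [classifier_specs()], or a
#'   `spec_id` string.
#' @param k number of folds for the k-fold scheme (reduced with a warning
#'   when it exceeds the number of subjects).
#' @param scheme `"kfold"` or `"loso"`; defaults to the family's scheme
#'   (LOSOCV for ANN, k-fold otherwise).
#' @param seed integer seed controlling fold assignment and classifier
#'   initialization.
#' @return a list of class `cv_result`: `experiment`, `spec_id`,
#'   `confusion` (tibble `TP`, `FP`, `TN`, `FN`, `positive`), `scores`
#'   (tibble of pooled out-of-fold positive-class scores with true
#'   labels), `folds` (per-row fold ids), `k_used`.
#' @export
cross_validate <- function(features, experiment, spec, k = 50,
                           scheme = NULL, seed = 0L) {
  if (is.character(spec)) {
    spec <- dplyr::filter(classifier_specs(), .data$spec_id == !!spec)
  }
  if (is.character(experiment)) {
    experiment <- dplyr::filter(experiment_defs(),
                                .data$experiment == !!experiment)
  }
  stopifnot(nrow(spec) == 1, nrow(experiment) == 1)
  exp_name <- experiment$experiment
  positive <- experiment$positive
  data <- experiment_rows(features, exp_name)
  if (length(unique(data$label)) < 2) {
    stop("experiment ", exp_name, " has a single class in the data",
         call. = FALSE)
  }
  if (min(table(data$label)) < 2) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  feat_cols <- feature_columns(features)
  x <- as.matrix(data[, feat_cols])
  y <- data$label
  if (is.null(scheme)) scheme <- if (spec$family == "ANN") "loso" else "kfold"
  folds <- if (scheme == "loso") {
    make_loso_folds(data$subject_id)
  } else {
    make_folds(data$subject_id, y, k, seed)
  }
  standardize <- spec$family %in% c("KNN", "SVM", "ANN")

  pred_lab <- character(nrow(data))
  pred_score <- numeric(nrow(data))
  for (fold in sort(unique(folds))) {
    test_idx <- which(folds == fold)
    train_idx <- which(folds != fold)
    x_tr <- x[train_idx, , drop = FALSE]
    x_te <- x[test_idx, , drop = FALSE]
    if (standardize) {
      z <- fold_standardize(x_tr, x_te)
      x_tr <- z$train; x_te <- z$test
    }
    res <- switch(spec$family,
      DT = fit_dt(x_tr, y[train_idx], x_te, spec$max_splits, positive),
      KNN = knn_predict(x_tr, y[train_idx], x_te, spec$k, spec$metric,
                        spec$weighting, positive),
      SVM = fit_svm(x_tr, y[train_idx], x_te, spec$degree, positive),
      ANN = fit_ann(x_tr, y[train_idx], x_te, spec$hidden, positive,
                    seed = seed + fold)
    )
    pred_lab[test_idx] <- res$labels
    pred_score[test_idx] <- res$scores
  }
  confusion <- confusion_matrix(truth = y, predicted = pred_lab,
                                positive = positive)
  structure(
    list(
      experiment = exp_name,
      spec_id = spec$spec_id,
      confusion = confusion,
      scores = tibble::tibble(subject_id = data$subject_id, truth = y,
                              score = pred_score),
      folds = folds,
      k_used = length(unique(folds))
    ),
    class = "cv_result"
  )
}

#' Confusion matrix from true and predicted labels
#'
#' @param truth,predicted character vectors of class labels.
#' @param positive label of the positive class.
#' @return a one-row tibble: `TP`, `FP`, `TN`, `FN`, `positive`.
#' @export
confusion_matrix <- function(truth, predicted, positive) {
  tibble::tibble(
    TP = sum(truth == positive & predicted == positive),
    FP = sum(truth != positive & predicted == positive),
    TN = sum(truth != positive & predicted != positive),
    FN = sum(truth == positive & predicted != positive),
    positive = positive
  )
}

#' Run the full classifier benchmark
#'
#' Cross-validates every experiment x classifier combination (52 under
#' the defaults) and returns one row per combination with the pooled
#' confusion matrix and out-of-fold scores as list columns.
#'
#' @inheritParams cross_validate
#' @param experiments,specs definitions to cross (defaults: all 4
#'   experiments, all 13 classifier variants).
#' @param progress print one line per combination.
#' @return a tibble of class `posture_bench`: `experiment`, `positive`,
#'   `spec_id`, `family`, `variant`, `k_used`, `TP`, `FP`, `TN`, `FN`,
#'   `scores` (list column).
#' @export
run_bench <- function(features, experiments = experiment_defs(),
                      specs = classifier_specs(), k = 50, seed = 0L,
                      progress = FALSE) {
  combos <- enumerate_bench(experiments, specs)
  rows <- purrr::map(seq_len(nrow(combos)), function(i) {
    cm <- combos[i, ]
    if (progress) {
      message(sprintf("bench %s x %s (%d/%d)", cm$experiment, cm$spec_id,
                      i, nrow(combos)))
    }
    cv <- suppressWarnings(cross_validate(
      features, cm[, c("experiment", "positive", "negative")],
      cm[, setdiff(names(cm), c("experiment", "positive", "negative"))],
      k = k, seed = seed
    ))
    dplyr::bind_cols(
      cm[, c("experiment", "positive", "spec_id", "family", "variant")],
      tibble::tibble(k_used = cv$k_used),
      cv$confusion[, c("TP", "FP", "TN", "FN")],
      tibble::tibble(scores = list(cv$scores))
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("posture_bench", class(out)),
            k = k, seed = seed)
}

#' Write / read benchmark results as JSON
#'
#' Confusion matrices and per-sample out-of-fold scores for every
#' combination, plus the run parameters.
#'
#' @param bench a `posture_bench`.
#' @param path file path.
#' @export
write_bench_json <- function(bench, path) {
  payload <- list(
    k = attr(bench, "k"),
    seed = attr(bench, "seed"),
    results = purrr::map(seq_len(nrow(bench)), function(i) {
      r <- bench[i, ]
      list(
        experiment = r$experiment, positive = r$positive,
        spec_id = r$spec_id, family = r$family, variant = r$variant,
        k_used = r$k_used,
        confusion = as.list(r[, c("TP", "FP", "TN", "FN")]),
        scores = r$scores[[1]]
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bench_json
#' @export
read_bench_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  res <- payload$results
  out <- tibble::tibble(
    experiment = res$experiment, positive = res$positive,
    spec_id = res$spec_id, family = res$family, variant = res$variant,
    k_used = res$k_used,
    TP = res$confusion$TP, FP = res$confusion$FP,
    TN = res$confusion$TN, FN = res$confusion$FN,
    scores = purrr::map(res$scores, tibble::as_tibble)
  )
  structure(out, class = c("posture_bench", class(out)),
            k = payload$k, seed = payload$seed)
}
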
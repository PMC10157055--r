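# Subject-independent evaluation harness: fold planning over subjects,
# temporal-context construction, staging metrics, and the cross-validation
# driver. The no-leakage contract (train and test folds share no subject) is
# asserted inside run_cv before every fold is trained, not just in tests.

#' Plan subject-independent cross-validation folds
#'
#' Subjects are shuffled with the seed and dealt round-robin into k folds, so
#' no epoch of a test subject ever appears in training.
#'
#' @param subject_ids Vector of per-epoch subject identifiers (or just the
#'   unique subjects).
#' @param k Number of folds (2 <= k <= number of distinct subjects).
#' @param seed Integer seed.
#' @return Object of class `fold_plan`: list with `k` and `assignments`
#'   (named integer vector, subject -> fold).
#' @export
make_folds <- function(subject_ids, k, seed = 1) {
  subjects <- unique(subject_ids)
  if (k < 2) stop("k must be at least 2 (k = 1 leaves no training split)")
  if (k > length(subjects)) {
    stop("k = ", k, " exceeds the ", length(subjects), " distinct subjects")
  }
  shuffled <- with_seed(seed, sample(subjects))
  assignments <- stats::setNames(rep(seq_len(k), length.out = length(shuffled)),
                                 shuffled)
  structure(list(k = k, assignments = assignments), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("Subject-independent plan:", length(x$assignments), "subjects in",
      x$k, "folds\n")
  invisible(x)
}

#' Build temporal contexts from a dataset
#'
#' Sliding windows of M consecutive same-subject epochs; the window label is
#' the center epoch's label. Windows never span subjects; at the start and
#' end of a subject's recording the boundary epoch is repeated, so every
#' epoch yields exactly one context.
#'
#' @param dataset A `psg_dataset`.
#' @param M Window length (odd; M = 2c + 1).
#' @return Object of class `epoch_contexts`: `indices` (n x M matrix of epoch
#'   indices), `centers`, `labels` (center labels), `subjects`.
#' @export
build_contexts <- function(dataset, M = 5) {
  if (M %% 2 == 0) stop("M must be odd (M = 2c + 1)")
  ctx <- contexts_from_subjects(dataset$subject_ids, M)
  structure(list(indices = ctx$indices, centers = ctx$centers,
                 labels = dataset$labels[ctx$centers],
                 subjects = dataset$subject_ids[ctx$centers]),
            class = "epoch_contexts")
}

#' Staging metrics from true and predicted labels
#'
#' Accuracy, per-class F1 (harmonic mean of precision and recall), macro F1
#' (unweighted mean over stages present in the data), and the 5x5 confusion
#' matrix (rows = truth). A stage absent from the test data gets `NA` F1 and
#' is excluded from the macro mean (reported via a message).
#'
#' @param truth,pred Stage labels (factors over [stage_levels()] or values
#'   coercible to them).
#' @return Object of class `eval_report`: list with `accuracy`, `macro_f1`,
#'   `per_class_f1`, `confusion`.
#' @export
staging_metrics <- function(truth, pred) {
  truth <- as_stage_factor(truth)
  pred <- as_stage_factor(pred)
  stopifnot(length(truth) == length(pred))
  confusion <- table(truth = truth, pred = pred)
  accuracy <- sum(diag(confusion)) / sum(confusion)
  f1 <- vapply(stage_levels(), function(s) {
    tp <- confusion[s, s]
    support <- sum(confusion[s, ])
    predicted <- sum(confusion[, s])
    if (support == 0) return(NA_real_)
    precision <- if (predicted > 0) tp / predicted else 0
    recall <- tp / support
    if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  }, numeric(1))
  if (anyNA(f1)) {
    message("stage(s) absent from test data, excluded from macro F1: ",
            paste(names(f1)[is.na(f1)], collapse = ", "))
  }
  structure(list(accuracy = accuracy, macro_f1 = mean(f1, na.rm = TRUE),
                 per_class_f1 = f1, confusion = confusion),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Accuracy %.3f | macro F1 %.3f\n", x$accuracy, x$macro_f1))
  cat("Per-class F1:\n")
  print(round(x$per_class_f1, 3))
  cat("Confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Evaluate a fitted model on a test dataset
#'
#' @param object A fitted [stdpgcn()] model.
#' @param data A labeled `psg_dataset`.
#' @return An `eval_report` (see [staging_metrics()]).
#' @export
evaluate <- function(object, data) {
  pred <- predict(object, data)
  staging_metrics(data$labels, pred)
}

#' Subject-independent k-fold cross-validation
#'
#' For each fold: the fold's subjects are held out as the test (and, when
#' adversarial training is on, unlabeled target) domain, the model is trained
#' on the remaining subjects and evaluated on the held-out subjects.
#' Subject-disjointness of the split is asserted before every fold is trained.
#'
#' @param dataset A labeled multi-subject `psg_dataset`.
#' @param config A [stdpgcn_config()].
#' @param k Number of folds.
#' @param seed Integer seed (fold shuffling and per-fold training seeds derive
#'   from it).
#' @return List with `fold_reports` (one `eval_report` per fold), `pooled`
#'   (metrics over the concatenated per-epoch predictions), `plan`.
#' @export
run_cv <- function(dataset, config = stdpgcn_config(), k = 2, seed = 1) {
  plan <- make_folds(dataset$subject_ids, k, seed)
  reports <- vector("list", k)
  all_truth <- all_pred <- factor(character(0), levels = stage_levels())
  for (fold in seq_len(k)) {
    test_subjects <- names(plan$assignments)[plan$assignments == fold]
    test_idx <- which(as.character(dataset$subject_ids) %in% test_subjects)
    train_idx <- setdiff(seq_along(dataset$subject_ids), test_idx)
    if (length(intersect(dataset$subject_ids[train_idx],
                         dataset$subject_ids[test_idx])) > 0) {
      stop("fold ", fold, " is not subject-disjoint")
    }
    train_data <- subset_dataset(dataset, train_idx)
    test_data <- subset_dataset(dataset, test_idx)
    target <- if (config$adversarial) test_data
    fit <- train_fold(train_data, target, config, seed = seed + fold)
    pred <- predict(fit, test_data)
    reports[[fold]] <- staging_metrics(test_data$labels, pred)
    all_truth <- c(all_truth, test_data$labels)
    all_pred <- c(all_pred, pred)
  }
  list(fold_reports = reports,
       pooled = staging_metrics(all_truth, all_pred),
       plan = plan)
}
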
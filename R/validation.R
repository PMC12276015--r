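# Model validation: stratified 70/30 split, thresholded classification
# of posterior probabilities, the eight-metric confusion panel, and ROC
# curves in probability-based and label-based (two-point) form.

#' Stratified train/test split of a cohort
#'
#' Partitions the cohort into disjoint train and test sets. With
#' stratification (the default) each outcome stratum contributes
#' `floor(train_frac * stratum size)` records to the training set and
#' the remainder to the test set, so class balance is stable across
#' seeds. Deterministic given `seed`; the caller's RNG state is
#' untouched.
#'
#' @param cohort A cohort data frame (>= 10 rows).
#' @param train_frac Training fraction in (0, 1); default 0.70.
#' @param seed Integer seed.
#' @param stratify Stratify by the outcome column (default `TRUE`).
#' @param outcome Name of the outcome column; defaults to the last
#'   column.
#' @return List with elements `train` and `test`.
#' @export
split_cohort <- function(cohort, train_frac = 0.7, seed = 1L,
                         stratify = TRUE, outcome = NULL) {
  if (!is.data.frame(cohort) || nrow(cohort) < 10L) {
    abort_haebn("`cohort` must be a data frame with at least 10 rows",
                "argument")
  }
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    abort_haebn("`train_frac` must be in (0, 1)", "argument")
  }
  outcome <- outcome %||% names(cohort)[ncol(cohort)]
  strata <- if (stratify) {
    split(seq_len(nrow(cohort)), cohort[[outcome]], drop = FALSE)
  } else {
    list(all = seq_len(nrow(cohort)))
  }
  if (stratify && any(lengths(strata) == 0L)) {
    abort_haebn(sprintf(
      "outcome stratum '%s' is empty; cannot stratify",
      names(strata)[which(lengths(strata) == 0L)[1]]), "split")
  }
  train_idx <- with_rng_seed(seed, {
    unlist(lapply(strata, function(idx) {
      n_train <- floor(train_frac * length(idx))
      sort(sample(idx, n_train))
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  list(train = cohort[train_idx, , drop = FALSE],
       test = cohort[setdiff(seq_len(nrow(cohort)), train_idx), ,
                     drop = FALSE])
}

#' Threshold a posterior probability into a risk class
#'
#' Predicts `"high"` iff `p >= threshold`. The tie at the threshold
#' goes to `"high"` — conservative toward detecting at-risk patients —
#' and the threshold is configurable.
#'
#' @param p Probabilities in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Character vector of `"high"` / `"low"`.
#' @export
classify <- function(p, threshold = 0.5) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort_haebn("probabilities must lie in [0, 1]", "argument")
  }
  ifelse(p >= threshold, "high", "low")
}

#' Confusion matrix with the high-risk class as positive
#'
#' @param predicted Predicted classes (`"high"`/`"low"`).
#' @param actual Observed classes.
#' @return List with integer cells `TP`, `FP`, `TN`, `FN`, class
#'   `bn_confusion`.
#' @export
confusion_matrix <- function(predicted, actual) {
  predicted <- tolower(as.character(predicted))
  actual <- tolower(as.character(actual))
  if (length(predicted) != length(actual)) {
    abort_haebn("`predicted` and `actual` must have equal length",
                "argument")
  }
  if (!all(c(predicted, actual) %in% c("high", "low"))) {
    abort_haebn("classes must be 'high' or 'low'", "argument")
  }
  structure(list(
    TP = sum(predicted == "high" & actual == "high"),
    FP = sum(predicted == "high" & actual == "low"),
    TN = sum(predicted == "low" & actual == "low"),
    FN = sum(predicted == "low" & actual == "high")
  ), class = "bn_confusion")
}

#' The eight-metric validation panel from a confusion matrix
#'
#' Accuracy, balanced accuracy, sensitivity, specificity, positive and
#' negative predictive value, detection rate (`TP/N`) and detection
#' prevalence (`(TP+FP)/N`), positive class = high mortality risk. By
#' construction the panel satisfies, exactly: balanced accuracy =
#' (sensitivity + specificity)/2; detection rate = PPV x detection
#' prevalence; accuracy = prevalence x sensitivity + (1 - prevalence) x
#' specificity. A metric with a zero denominator is reported as `NA`
#' (undefined), never coerced to 0 or 1.
#'
#' @param cm A `bn_confusion` (or list with `TP`, `FP`, `TN`, `FN`).
#' @return One-row data frame of the eight metrics plus `prevalence`
#'   and `n`.
#' @export
compute_metrics <- function(cm) {
  TP <- cm$TP; FP <- cm$FP; TN <- cm$TN; FN <- cm$FN
  n <- TP + FP + TN + FN
  if (n == 0) abort_haebn("empty confusion matrix", "argument")
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- div(TP, TP + FN)
  spec <- div(TN, TN + FP)
  data.frame(
    accuracy = (TP + TN) / n,
    balanced_accuracy = (sens + spec) / 2,
    sensitivity = sens,
    specificity = spec,
    ppv = div(TP, TP + FP),
    npv = div(TN, TN + FN),
    detection_rate = TP / n,
    detection_prevalence = (TP + FP) / n,
    prevalence = (TP + FN) / n,
    n = n
  )
}

# ROC / AUC -----------------------------------------------------------------

#' ROC curve and AUC for posterior scores
#'
#' `mode = "probability"`: the standard ROC over all score thresholds
#' (tied scores grouped), AUC by the trapezoid rule — equivalently the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, ties counted half. `mode = "label"`: the two-segment ROC
#' through the single (FPR, TPR) operating point of the thresholded
#' classifier, the straight-line curve a purely discrete prediction
#' produces; its AUC equals (sensitivity + specificity) / 2.
#'
#' @param scores Predicted probabilities of the positive (high) class.
#' @param actual Observed classes (`"high"`/`"low"`).
#' @param mode `"probability"` (default) or `"label"`.
#' @param threshold Decision threshold for label mode (default 0.5).
#' @return List with `points` (data frame `fpr`, `tpr`), `auc`, and
#'   `mode`; class `roc_curve`.
#' @export
roc_auc <- function(scores, actual, mode = c("probability", "label"),
                    threshold = 0.5) {
  mode <- match.arg(mode)
  actual <- tolower(as.character(actual))
  y <- actual == "high"
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    abort_haebn("both outcome classes must be present to compute AUC",
                "argument")
  }
  if (mode == "label") {
    pred <- classify(scores, threshold)
    cmx <- confusion_matrix(pred, actual)
    tpr <- cmx$TP / n1
    fpr <- cmx$FP / n0
    points <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
    # two-segment geometry: the area is exactly (sens + spec) / 2,
    # computed with the same arithmetic as the metric panel
    auc <- (cmx$TP / (cmx$TP + cmx$FN) + cmx$TN / (cmx$TN + cmx$FP)) / 2
    return(structure(list(points = points, auc = auc, mode = mode),
                     class = "roc_curve"))
  } else {
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; yy <- y[ord]
    grp_last <- c(s[-1] != s[-length(s)], TRUE)  # last index of tie group
    tp <- cumsum(yy)[grp_last]
    fp <- cumsum(!yy)[grp_last]
    points <- data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  }
  auc <- sum(diff(points$fpr) *
               (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  structure(list(points = points, auc = auc, mode = mode),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC (%s mode): AUC = %.4f over %d points\n", x$mode,
              x$auc, nrow(x$points)))
  invisible(x)
}

#' End-to-end validation of the network on a cohort
#'
#' The full validation stage: stratified train/test split, Bayesian
#' fit on the training partition, posterior scoring of both partitions,
#' thresholded classification, the eight-metric panel, and ROC/AUC in
#' both probability and label modes for train and test. Deterministic
#' given `seed`.
#'
#' @param cohort A cohort data frame.
#' @param dag A `dag_model`.
#' @param alpha Dirichlet concentration for the fit (default 1).
#' @param train_frac Training fraction (default 0.70).
#' @param seed Split seed.
#' @param stratify Stratify the split by outcome (default `TRUE`).
#' @param threshold Classification threshold (default 0.5).
#' @return List of class `bn_validation` with elements `fitted`,
#'   `split` (sizes), and per-partition results `train` / `test`, each
#'   holding `metrics`, `roc_probability`, `roc_label` and `auc`s.
#' @export
validate_pipeline <- function(cohort, dag, alpha = 1, train_frac = 0.7,
                              seed = 1L, stratify = TRUE,
                              threshold = 0.5) {
  cohort <- validate_cohort(cohort, dag)
  out_node <- outcome_node(dag)
  parts <- split_cohort(cohort, train_frac, seed, stratify,
                        outcome = out_node)
  bn <- fit_network(parts$train, dag, alpha = alpha)

  eval_part <- function(df) {
    scores <- predict_outcome_proba(bn, df[predictor_nodes(dag)])
    actual <- tolower(as.character(df[[out_node]]))
    cmx <- confusion_matrix(classify(scores, threshold), actual)
    list(metrics = compute_metrics(cmx),
         confusion = cmx,
         roc_probability = roc_auc(scores, actual, "probability"),
         roc_label = roc_auc(scores, actual, "label", threshold))
  }
  structure(list(
    fitted = bn,
    split = list(train_frac = train_frac, seed = as.integer(seed),
                 stratify = stratify, threshold = threshold,
                 n_train = nrow(parts$train), n_test = nrow(parts$test)),
    train = eval_part(parts$train),
    test = eval_part(parts$test)
  ), class = "bn_validation")
}

#' @export
print.bn_validation <- function(x, ...) {
  cat(sprintf("BN validation: %d train / %d test records\n",
              x$split$n_train, x$split$n_test))
  for (part in c("train", "test")) {
    m <- x[[part]]$metrics
    cat(sprintf(
      " %s: acc %.2f | bal.acc %.2f | sens %.2f | spec %.2f | AUC %.2f (prob) %.2f (label)\n",
      part, m$accuracy, m$balanced_accuracy, m$sensitivity,
      m$specificity, x[[part]]$roc_probability$auc,
      x[[part]]$roc_label$auc))
  }
  invisible(x)
}

#' Validation results as JSON
#'
#' Writes the train/test metric panels and AUCs with fixed key names,
#' plus ROC point CSVs alongside.
#'
#' @param val A `bn_validation`.
#' @param dir Output directory.
#' @return Named vector of files written, invisibly.
#' @export
write_validation <- function(val, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok) abort_haebn(sprintf("cannot create directory '%s'", dir), "io")
  panel <- function(part) {
    m <- as.list(val[[part]]$metrics)
    m$auc_probability <- val[[part]]$roc_probability$auc
    m$auc_label <- val[[part]]$roc_label$auc
    m
  }
  files <- c(json = file.path(dir, "validation.json"))
  writeLines(jsonlite::toJSON(
    list(split = val$split, train = panel("train"), test = panel("test")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"),
    files[["json"]])
  for (part in c("train", "test")) {
    for (mode in c("probability", "label")) {
      f <- file.path(dir, sprintf("roc_%s_%s.csv", part, mode))
      files[[paste(part, mode, sep = "_")]] <- f
      write.csv(val[[part]][[paste0("roc_", mode)]]$points, f,
                row.names = FALSE)
    }
  }
  invisible(files)
}
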
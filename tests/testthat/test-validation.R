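truth <- default_ground_truth()

test_that("stratified split follows floor arithmetic and partitions", {
  dag <- truth$dag
  # construct a cohort with exactly 171 high / 270 low outcomes
  co <- sample_cohort(truth, 2000, seed = 55)
  hi <- which(co$MortalityRisk == "high")[1:171]
  lo <- which(co$MortalityRisk == "low")[1:270]
  co <- co[c(hi, lo), ]
  parts <- split_cohort(co, train_frac = 0.7, seed = 3,
                        outcome = "MortalityRisk")
  expect_identical(nrow(parts$train), 308L)  # floor(0.7*171)+floor(0.7*270)
  expect_identical(nrow(parts$test), 133L)
  expect_identical(sum(parts$train$MortalityRisk == "high"), 119L)

  key <- function(df) sort(do.call(paste, lapply(df, as.character)))
  expect_identical(sort(c(key(parts$train), key(parts$test))), key(co))

  # stratum sizes are seed-invariant; record membership is not
  parts2 <- split_cohort(co, train_frac = 0.7, seed = 99,
                         outcome = "MortalityRisk")
  expect_identical(table(parts2$train$MortalityRisk),
                   table(parts$train$MortalityRisk))
  expect_identical(split_cohort(co, 0.7, seed = 3,
                                outcome = "MortalityRisk"), parts)

  balanced <- data.frame(
    x = letters[1:10],
    MortalityRisk = rep(c("high", "low"), each = 5))
  # plain (unstratified) split halves the cohort exactly
  even <- split_cohort(balanced, 0.5, seed = 1, stratify = FALSE,
                       outcome = "MortalityRisk")
  expect_identical(nrow(even$train), 5L)
  expect_identical(nrow(even$test), 5L)

  onecls <- balanced
  onecls$MortalityRisk <- factor("high", levels = c("high", "low"))
  expect_error(split_cohort(onecls, 0.7, seed = 1,
                            outcome = "MortalityRisk"),
               class = "haebn_split_error")
})

test_that("classification threshold rule: ties predict high", {
  expect_identical(classify(0.5), "high")
  expect_identical(classify(0.49), "low")
  expect_error(classify(1.2), class = "haebn_argument_error")

  set.seed(6)
  scores <- runif(200)
  positives <- vapply(seq(0, 1, by = 0.05), function(t)
    sum(classify(scores, t) == "high"), numeric(1))
  expect_true(all(diff(positives) <= 0))
})

test_that("metric panel matches hand computation and its identities", {
  cm <- list(TP = 53L, FP = 8L, TN = 29L, FN = 10L)
  m <- compute_metrics(cm)
  expect_equal(m$accuracy, 82 / 100)
  expect_equal(m$sensitivity, 53 / 63)
  expect_equal(m$specificity, 29 / 37)
  expect_equal(m$ppv, 53 / 61)
  expect_equal(m$npv, 29 / 39)
  expect_equal(m$detection_rate, 53 / 100)
  expect_equal(m$detection_prevalence, 61 / 100)
  expect_equal(m$balanced_accuracy, (53 / 63 + 29 / 37) / 2)

  # identities hold exactly on random matrices, and agree with caret
  set.seed(10)
  for (rep in 1:20) {
    cells <- as.list(rmultinom(1, 200, runif(4, 0.05, 1))[, 1])
    names(cells) <- c("TP", "FP", "TN", "FN")
    m <- compute_metrics(cells)
    expect_identical(m$balanced_accuracy,
                     (m$sensitivity + m$specificity) / 2)
    expect_equal(m$detection_rate, m$ppv * m$detection_prevalence,
                 tolerance = 1e-12)
    expect_equal(m$accuracy,
                 m$prevalence * m$sensitivity +
                   (1 - m$prevalence) * m$specificity,
                 tolerance = 1e-12)
    ctab <- as.table(matrix(c(cells$TP, cells$FN, cells$FP, cells$TN),
                            nrow = 2,
                            dimnames = list(pred = c("high", "low"),
                                            truth = c("high", "low"))))
    cc <- caret::confusionMatrix(ctab, positive = "high")
    expect_equal(m$accuracy, unname(cc$overall["Accuracy"]))
    expect_equal(m$sensitivity, unname(cc$byClass["Sensitivity"]))
    expect_equal(m$specificity, unname(cc$byClass["Specificity"]))
    expect_equal(m$ppv, unname(cc$byClass["Pos Pred Value"]))
    expect_equal(m$npv, unname(cc$byClass["Neg Pred Value"]))
    expect_equal(m$detection_rate, unname(cc$byClass["Detection Rate"]))
    expect_equal(m$detection_prevalence,
                 unname(cc$byClass["Detection Prevalence"]))
    expect_equal(m$balanced_accuracy,
                 unname(cc$byClass["Balanced Accuracy"]))
  }

  perfect <- compute_metrics(list(TP = 40L, FP = 0L, TN = 60L, FN = 0L))
  expect_true(all(unlist(perfect[1:8]) == 1 |
                    names(unlist(perfect[1:8])) %in%
                    c("detection_rate", "detection_prevalence")))
  expect_equal(perfect$detection_rate, 0.4)

  none_pos <- compute_metrics(list(TP = 0L, FP = 0L, TN = 9L, FN = 1L))
  expect_true(is.na(none_pos$ppv))  # undefined, not coerced to 0
})

test_that("ROC: trapezoid AUC equals Mann-Whitney; label mode is linear", {
  y <- c(rep("high", 5), rep("low", 5))
  expect_equal(roc_auc(c(rep(1, 5), rep(0, 5)), y)$auc, 1)
  expect_equal(roc_auc(c(rep(1, 5), rep(0, 5)), y, "label")$auc, 1)

  set.seed(99)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    labels <- sample(c("high", "low"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("high", "low")
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # force score ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, mw_auc(scores, labels), tolerance = 1e-12)
    # invariant under strictly monotone transforms of the scores
    expect_equal(roc_auc(plogis(5 * scores - 2), labels)$auc, r$auc,
                 tolerance = 1e-12)
    expect_true(all(diff(r$points$fpr) >= 0) &&
                  all(diff(r$points$tpr) >= 0))
  }

  # pROC as an external cross-check on one fixed instance
  set.seed(7)
  labels <- sample(c("high", "low"), 80, replace = TRUE)
  scores <- round(runif(80), 2)
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(
                 response = labels, predictor = scores,
                 levels = c("low", "high"), direction = "<",
                 quiet = TRUE))),
               tolerance = 1e-12)

  # label-mode AUC is exactly (sensitivity + specificity) / 2
  scores <- runif(100)
  labels <- sample(c("high", "low"), 100, replace = TRUE)
  r <- roc_auc(scores, labels, "label")
  cmx <- confusion_matrix(classify(scores), labels)
  m <- compute_metrics(cmx)
  expect_identical(r$auc, (m$sensitivity + m$specificity) / 2)
  expect_identical(nrow(r$points), 3L)

  expect_error(roc_auc(runif(5), rep("high", 5)),
               class = "haebn_argument_error")
})

test_that("pipeline validation tracks the generator's Bayes-optimal AUC", {
  # On a structure whose outcome table is densely observed (outcome
  # parents Age + Severity: 16 rows), n = 5,000 recovers the
  # generator's Bayes-optimal discrimination. The full structure's
  # 4096-row outcome table needs far more data per row; there we
  # assert that the gap to the oracle shrinks with n (see vignette).
  reduced <- parse_model_config(text = jsonlite::toJSON(list(
    nodes = jsonlite::fromJSON(write_model_config(truth$dag),
                               simplifyVector = FALSE)$nodes,
    edges = list(list("Age", "Hypertension"), list("Age", "Autoimmune"),
                 list("Age", "Diabetes"), list("Hypertension", "Severity"),
                 list("Autoimmune", "Severity"), list("Diabetes", "Severity"),
                 list("Age", "MortalityRisk"),
                 list("Severity", "MortalityRisk"))),
    auto_unbox = TRUE))
  rtruth <- default_ground_truth(reduced)
  co <- sample_cohort(rtruth, 5000, seed = 61)
  val <- validate_pipeline(co, reduced, seed = 61)
  expect_identical(val$split$n_train + val$split$n_test, 5000L)

  oracle_auc_for <- function(tr, cohort, dag, split_seed) {
    parts <- split_cohort(cohort, 0.7, seed = split_seed,
                          outcome = "MortalityRisk")
    scores <- predict_outcome_proba(tr, parts$test[predictor_nodes(dag)])
    roc_auc(scores, parts$test$MortalityRisk)$auc
  }
  expect_lt(abs(val$test$roc_probability$auc -
                  oracle_auc_for(rtruth, co, reduced, 61)), 0.03)

  gaps <- vapply(c(5000L, 50000L), function(n) {
    cf <- sample_cohort(truth, n, seed = 61)
    vf <- validate_pipeline(cf, truth$dag, seed = 61)
    oracle_auc_for(truth, cf, truth$dag, 61) -
      vf$test$roc_probability$auc
  }, numeric(1))
  expect_lt(gaps[2], gaps[1])

  # the identities hold on the emitted panels too
  for (part in c("train", "test")) {
    m <- val[[part]]$metrics
    expect_equal(m$balanced_accuracy,
                 (m$sensitivity + m$specificity) / 2)
    expect_identical(val[[part]]$roc_label$auc,
                     (m$sensitivity + m$specificity) / 2)
  }

  files <- write_validation(val, withr::local_tempdir())
  expect_true(all(file.exists(files)))
  payload <- jsonlite::fromJSON(files[["json"]])
  expect_equal(payload$test$accuracy, val$test$metrics$accuracy)
})

test_that("training AUC does not trail test AUC beyond noise", {
  aucs <- sapply(1:20, function(s) {
    co <- sample_cohort(truth, 1500, seed = 700 + s)
    val <- validate_pipeline(co, truth$dag, seed = s)
    c(train = val$train$roc_probability$auc,
      test = val$test$roc_probability$auc)
  })
  expect_true(all(aucs["train", ] >= aucs["test", ] - 0.05))
})
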
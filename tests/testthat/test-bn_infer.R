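truth <- default_ground_truth()

test_that("joint probabilities factorize along the DAG", {
  u <- uniform_bn()
  rec <- lapply(node_names(u$dag), function(v)
    node_categories(u$dag, v)[1])
  names(rec) <- node_names(u$dag)
  expect_equal(joint_probability(u, rec), 1 / 65536)

  bn <- chain3_bn()
  # hand product: P(a1) P(b0|a1) P(high|b0) = 0.7 * 0.4 * 0.2
  expect_equal(joint_probability(bn, c(A = "a1", B = "b0", C = "high")),
               0.7 * 0.4 * 0.2)
  grid <- expand.grid(A = c("a0", "a1"), B = c("b0", "b1"),
                      C = c("low", "high"), stringsAsFactors = FALSE)
  total <- sum(apply(grid, 1, function(r) joint_probability(bn, r)))
  expect_equal(total, 1, tolerance = 1e-9)

  expect_error(joint_probability(bn, c(A = "a1", B = "b0")),
               class = "haebn_argument_error")
})

test_that("soft-evidence semantics: flat is vacuous, degenerate is hard", {
  u <- uniform_bn()
  q <- posterior_by_enumeration(u, "MortalityRisk")
  expect_equal(unname(q$probs), c(0.5, 0.5))

  no_ev <- posterior_by_enumeration(truth, "MortalityRisk")$probs
  flat <- posterior_by_enumeration(
    truth, "MortalityRisk", evidence(Age = rep(1, 4)))$probs
  expect_equal(flat, no_ev, tolerance = 1e-12)

  hard <- posterior_by_enumeration(
    truth, "MortalityRisk", evidence(Hypertension = "yes"))$probs
  degen <- posterior_by_enumeration(
    truth, "MortalityRisk", evidence(Hypertension = c(0, 1)))$probs
  expect_equal(degen, hard, tolerance = 1e-12)

  # same three properties through the elimination engine
  expect_equal(
    posterior_by_elimination(truth, "MortalityRisk",
                             evidence(Age = rep(1, 4)))$probs,
    no_ev, tolerance = 1e-12)
  expect_equal(
    posterior_by_elimination(truth, "MortalityRisk",
                             evidence(Hypertension = c(0, 1)))$probs,
    hard, tolerance = 1e-12)
})

test_that("variable elimination matches enumeration on random models", {
  set.seed(314)
  worst <- 0
  for (rep in 1:60) {
    dag <- random_dag(sample(4:8, 1))
    bn <- random_bn(dag)
    query <- sample(node_names(dag), 1)
    ev <- random_evidence(dag, query)
    a <- posterior_by_enumeration(bn, query, ev)$probs
    b <- posterior_by_elimination(bn, query, ev)$probs
    worst <- max(worst, max(abs(a - b)))
  }
  expect_lt(worst, 1e-9)
})

test_that("full predictor evidence reduces to the Markov blanket", {
  co <- sample_cohort(truth, 30, seed = 21)
  preds <- predictor_nodes(truth$dag)
  p_fast <- predict_outcome_proba(truth, co[preds])
  for (i in c(1L, 7L, 30L)) {
    ev <- do.call(evidence, as.list(sapply(co[i, preds], as.character)))
    expect_equal(p_fast[i],
                 posterior_by_enumeration(truth, "MortalityRisk",
                                          ev)$probs[["high"]],
                 tolerance = 1e-12)
    # with every predictor observed, the outcome posterior is its CPT row
    cfg <- c(list("high"), lapply(dag_parents(truth$dag, "MortalityRisk"),
                                  function(v) as.character(co[i, v])))
    expect_equal(p_fast[i], do.call(`[`, c(list(truth$cpts$MortalityRisk),
                                           cfg)),
                 tolerance = 1e-12)
  }
  expect_error(predict_outcome_proba(truth, co[preds[-1]]),
               class = "haebn_argument_error")
})

test_that("impossible evidence raises a distinct error, not NaN", {
  det <- chain3_bn()
  det$cpts$B[, "a1"] <- c(0, 1)   # B=b0 impossible given A=a1
  det <- discrete_bn(det$dag, det$cpts)
  expect_error(
    posterior_by_enumeration(det, "C", evidence(A = "a1", B = "b0")),
    class = "haebn_impossible_evidence_error")
  expect_error(
    posterior_by_elimination(det, "C", evidence(A = "a1", B = "b0")),
    class = "haebn_impossible_evidence_error")
  expect_error(posterior_by_elimination(det, "C", evidence(C = "low")),
               class = "haebn_argument_error")  # query carries evidence
})

test_that("predictors with no path to the outcome do not move it", {
  dag <- dag_model(
    nodes = list(
      list(name = "Isolated", categories = c("u", "v"),
           role = "predictor"),
      list(name = "Cause", categories = c("no", "yes"),
           role = "predictor"),
      list(name = "MortalityRisk", categories = c("low", "high"),
           role = "outcome")),
    edges = list(c("Cause", "MortalityRisk")))
  set.seed(88)
  bn <- random_bn(dag)
  r1 <- data.frame(Isolated = "u", Cause = "yes")
  r2 <- data.frame(Isolated = "v", Cause = "yes")
  expect_equal(predict_outcome_proba(bn, r1),
               predict_outcome_proba(bn, r2))
})

test_that("risk-increasing findings never lower the high-risk posterior", {
  base <- posterior_by_elimination(truth, "MortalityRisk")$probs[["high"]]
  for (ev in list(evidence(Autoimmune = "yes"),
                  evidence(Hypertension = "yes"),
                  evidence(Severity = "extreme"),
                  evidence(Age = ">=65"))) {
    p <- posterior_by_elimination(truth, "MortalityRisk", ev)$probs[["high"]]
    expect_gte(p, base)
  }
})

test_that("law of total probability ties conditionals to the baseline", {
  bn <- fit_network(sample_cohort(truth, 441, seed = 31), truth$dag)
  base <- posterior_by_elimination(bn, "MortalityRisk")$probs[["high"]]
  marg <- exact_marginals(bn)
  for (node in predictor_nodes(bn$dag)) {
    mix <- sum(vapply(node_categories(bn$dag, node), function(s) {
      ev <- do.call(evidence, setNames(list(s), node))
      marg[[node]][[s]] *
        posterior_by_elimination(bn, "MortalityRisk", ev)$probs[["high"]]
    }, numeric(1)))
    expect_equal(mix, base, tolerance = 1e-9)
  }
})
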
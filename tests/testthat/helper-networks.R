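# Fixtures built in code: small hand networks, random networks and
# independent brute-force oracles.

# Two-node chain with hand-specified CPTs (used for hand tallies).
chain2_dag <- function() {
  dag_model(
    nodes = list(
      list(name = "Exposure", categories = c("no", "yes"),
           role = "predictor"),
      list(name = "MortalityRisk", categories = c("low", "high"),
           role = "outcome")),
    edges = list(c("Exposure", "MortalityRisk")))
}

# Three-node chain A -> B -> C with hand CPTs for joint-probability
# checks. C doubles as the outcome.
chain3_bn <- function() {
  dag <- dag_model(
    nodes = list(
      list(name = "A", categories = c("a0", "a1"), role = "predictor"),
      list(name = "B", categories = c("b0", "b1"), role = "predictor"),
      list(name = "C", categories = c("low", "high"), role = "outcome")),
    edges = list(c("A", "B"), c("B", "C")))
  cpts <- list(
    A = array(c(0.3, 0.7), dim = 2, dimnames = list(A = c("a0", "a1"))),
    B = array(c(0.9, 0.1, 0.4, 0.6), dim = c(2, 2),
              dimnames = list(B = c("b0", "b1"), A = c("a0", "a1"))),
    C = array(c(0.8, 0.2, 0.25, 0.75), dim = c(2, 2),
              dimnames = list(C = c("low", "high"), B = c("b0", "b1"))))
  discrete_bn(dag, cpts)
}

# All-CPTs-uniform network over a schema (prior-only posterior).
uniform_bn <- function(dag = default_model()) {
  empty <- as.data.frame(setNames(
    lapply(node_names(dag), function(v) character(0)), node_names(dag)))
  fit_network(empty, dag, alpha = 1)
}

# Random DAG over n nodes (last node is the binary outcome); edges drawn
# upper-triangular so the graph is acyclic by construction.
random_dag <- function(n_nodes, p_edge = 0.35, max_card = 3) {
  names <- paste0("N", seq_len(n_nodes))
  nodes <- lapply(seq_len(n_nodes), function(i) {
    if (i == n_nodes) {
      list(name = names[i], categories = c("low", "high"),
           role = "outcome")
    } else {
      k <- sample(2:max_card, 1)
      list(name = names[i], categories = paste0("s", seq_len(k)),
           role = "predictor")
    }
  })
  edges <- list()
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (runif(1) < p_edge) edges <- c(edges, list(c(names[i], names[j])))
    }
  }
  dag_model(nodes, edges)
}

# Random CPTs (Dirichlet rows) for a DAG.
random_bn <- function(dag) {
  cpts <- lapply(node_names(dag), function(node) {
    k <- length(node_categories(dag, node))
    parents <- dag_parents(dag, node)
    cards <- vapply(parents, function(p)
      length(node_categories(dag, p)), integer(1))
    ncfg <- prod(c(1L, cards))
    m <- matrix(rgamma(k * ncfg, shape = 1), nrow = k)
    m <- sweep(m, 2, colSums(m), `/`)
    array(m, dim = c(k, cards),
          dimnames = setNames(
            c(list(node_categories(dag, node)),
              lapply(parents, function(p) node_categories(dag, p))),
            c(node, parents)))
  })
  names(cpts) <- node_names(dag)
  discrete_bn(dag, cpts)
}

# Random evidence on a subset of nodes (never the query): mixes hard
# states and soft likelihood vectors.
random_evidence <- function(dag, query, max_nodes = 3) {
  pool <- setdiff(node_names(dag), query)
  picked <- sample(pool, min(length(pool), sample(0:max_nodes, 1)))
  ev <- lapply(picked, function(node) {
    cats <- node_categories(dag, node)
    if (runif(1) < 0.5) {
      sample(cats, 1)
    } else {
      w <- runif(length(cats))
      w[sample(length(w), 1)] <- w[sample(length(w), 1)] + 0.2
      w
    }
  })
  names(ev) <- picked
  do.call(evidence, ev)
}

# Brute-force cycle detection by DFS over every start node: the
# independent oracle for the acyclicity check.
has_cycle_dfs <- function(node_names, edges) {
  adj <- lapply(setNames(node_names, node_names), function(v)
    unlist(lapply(edges, function(e) if (e[1] == v) e[2] else NULL)))
  visit <- function(v, stack) {
    if (v %in% stack) return(TRUE)
    for (w in adj[[v]]) if (visit(w, c(stack, v))) return(TRUE)
    FALSE
  }
  any(vapply(node_names, function(v) visit(v, character(0)), logical(1)))
}

# Deterministic label permutation for null-model checks.
with_seed_shuffle <- function(x, seed) {
  withr::with_seed(seed, sample(x))
}

# Brute-force Mann-Whitney AUC: pairwise comparison of every
# positive/negative score pair, ties counted one half.
mw_auc <- function(scores, actual) {
  y <- tolower(as.character(actual)) == "high"
  s1 <- scores[y]; s0 <- scores[!y]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
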
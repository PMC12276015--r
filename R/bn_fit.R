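# Bayesian parameter estimation: cross-tabulated sufficient statistics
# per node, Dirichlet posterior-mean CPTs, and the fitted-network
# container shared by the generator and the inference engine.

#' Construct a discrete Bayesian network from a DAG and CPTs
#'
#' A `discrete_bn` couples a `dag_model` with one conditional probability
#' table per node. Each CPT is a numeric array whose first dimension is
#' the node itself and whose remaining dimensions are its parents in
#' declaration order; every column (one per parent configuration) must
#' be a probability vector. Both fitted networks and simulation
#' ground-truth networks use this class.
#'
#' @param dag A `dag_model`.
#' @param cpts Named list of CPT arrays, one per node.
#' @param fit Optional list of fit metadata (e.g. `alpha`, `n`).
#' @param provenance Optional free-form provenance list.
#' @return An object of class `discrete_bn`.
#' @export
discrete_bn <- function(dag, cpts, fit = NULL, provenance = NULL) {
  stopifnot(inherits(dag, "dag_model"))
  missing_cpt <- setdiff(node_names(dag), names(cpts))
  if (length(missing_cpt)) {
    abort_haebn(sprintf("missing CPT(s) for node(s): %s",
                        paste(missing_cpt, collapse = ", ")), "schema")
  }
  for (node in node_names(dag)) {
    cpt <- cpts[[node]]
    want_vars <- c(node, dag_parents(dag, node))
    dn <- dimnames(cpt)
    if (!identical(names(dn), want_vars)) {
      abort_haebn(sprintf(
        "CPT for '%s' must have dimensions (%s), got (%s)",
        node, paste(want_vars, collapse = ", "),
        paste(names(dn), collapse = ", ")), "schema")
    }
    for (v in want_vars) {
      if (!identical(dn[[v]], node_categories(dag, v))) {
        abort_haebn(sprintf(
          "CPT for '%s': category labels along '%s' do not match schema",
          node, v), "schema")
      }
    }
    if (any(cpt < 0) || anyNA(cpt)) {
      abort_haebn(sprintf("CPT for '%s' has negative or missing entries",
                          node), "schema")
    }
    sums <- colSums(matrix(cpt, nrow = dim(cpt)[1]))
    if (any(abs(sums - 1) > 1e-9)) {
      abort_haebn(sprintf(
        "CPT for '%s': %d parent configuration(s) do not sum to 1",
        node, sum(abs(sums - 1) > 1e-9)), "schema")
    }
  }
  structure(list(dag = dag, cpts = cpts[node_names(dag)], fit = fit,
                 provenance = provenance),
            class = "discrete_bn")
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat(sprintf("Discrete Bayesian network: %d nodes, %d edges\n",
              length(x$dag$nodes), nrow(x$dag$edges)))
  if (!is.null(x$fit)) {
    cat(sprintf("Fitted from n = %s records (Dirichlet alpha = %s)\n",
                x$fit$n %||% "?", x$fit$alpha %||% "?"))
  }
  invisible(x)
}

#' Cross-tabulate a cohort into per-node count tables
#'
#' For each node, counts of every (node category x parent configuration)
#' cell — the sufficient statistics for CPT estimation. Parent
#' configurations never observed in the cohort appear as zero columns.
#'
#' @param cohort A cohort data frame (see [read_cohort()] /
#'   [sample_cohort()]); validated against `dag`'s schema.
#' @param dag A `dag_model`.
#' @return Named list of count arrays (node dimension first), class
#'   `bn_counts`.
#' @export
count_configurations <- function(cohort, dag) {
  cohort <- validate_cohort(cohort, dag)
  n <- nrow(cohort)
  counts <- lapply(node_names(dag), function(node) {
    vars <- c(node, dag_parents(dag, node))
    cols <- lapply(vars, function(v) {
      factor(as.character(cohort[[v]]), levels = node_categories(dag, v))
    })
    names(cols) <- vars
    tab <- table(cols)
    arr <- array(as.integer(tab), dim = dim(tab), dimnames = dimnames(tab))
    arr
  })
  names(counts) <- node_names(dag)
  structure(counts, class = "bn_counts", n = n)
}

#' Dirichlet posterior-mean CPT from a count table
#'
#' Under a symmetric Dirichlet(alpha, ..., alpha) prior on each parent
#' configuration's probability vector, the posterior mean is
#' `(N_ijk + alpha) / (N_ij + k * alpha)` where `k` is the node's
#' category count. With `alpha = 1` (the default, a uniform prior) an
#' unobserved parent configuration yields the uniform vector `1/k`, and
#' no probability is ever exactly 0 or 1 — the smoothing that keeps
#' sparse strata of a small cohort from producing degenerate tables.
#' `alpha = 0` gives the maximum-likelihood estimate and is only valid
#' when every parent configuration was observed.
#'
#' @param counts A count array for one node (node dimension first), as
#'   produced by [count_configurations()].
#' @param alpha Dirichlet concentration per category (>= 0; default 1).
#' @return A CPT array of the same shape.
#' @export
#' @examples
#' counts <- array(c(3L, 1L), dim = 2L,
#'                 dimnames = list(Outcome = c("low", "high")))
#' posterior_cpt(counts)  # (3+1)/(4+2), (1+1)/(4+2)
posterior_cpt <- function(counts, alpha = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0) {
    abort_haebn("`alpha` must be a single nonnegative number", "argument")
  }
  dm <- dim(counts) %||% length(counts)
  k <- dm[1]
  m <- matrix(as.numeric(counts), nrow = k)
  n_ij <- colSums(m)
  if (alpha == 0 && any(n_ij == 0)) {
    abort_haebn(paste0(
      "alpha = 0 (maximum likelihood) with unobserved parent ",
      "configuration(s); use alpha > 0 for Dirichlet smoothing"),
      "estimation")
  }
  theta <- sweep(m + alpha, 2, n_ij + k * alpha, `/`)
  array(theta, dim = dm, dimnames = dimnames(counts))
}

#' Fit a Bayesian network to a cohort
#'
#' Composes [count_configurations()] and [posterior_cpt()] over every
#' node of the DAG: the Bayesian parameter-estimation stage. The result
#' is deterministic given the cohort, DAG and `alpha`.
#'
#' @inheritParams count_configurations
#' @param alpha Dirichlet concentration per category (default 1).
#' @return A `discrete_bn` with fit metadata (`alpha`, cohort size).
#' @export
#' @examples
#' truth <- default_ground_truth()
#' cohort <- sample_cohort(truth, n = 441, seed = 7)
#' bn <- fit_network(cohort, truth$dag)
#' baseline_risk(bn)
fit_network <- function(cohort, dag, alpha = 1) {
  counts <- count_configurations(cohort, dag)
  cpts <- lapply(counts, posterior_cpt, alpha = alpha)
  discrete_bn(dag, cpts,
              fit = list(alpha = alpha, n = attr(counts, "n"),
                         estimator = "dirichlet_posterior_mean"))
}

# Serialization -------------------------------------------------------------

#' Write a fitted network to JSON
#'
#' Full-precision serialization of the DAG and every CPT; reading the
#' file back reproduces the network exactly (to 17 significant digits).
#'
#' @param bn A `discrete_bn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fitted_bn <- function(bn, path) {
  payload <- list(
    schema = jsonlite::fromJSON(write_model_config(bn$dag),
                                simplifyVector = FALSE),
    cpts = lapply(bn$cpts, function(cpt) {
      list(vars = names(dimnames(cpt)),
           card = unname(vapply(dimnames(cpt), length, integer(1))),
           values = as.numeric(cpt))
    }),
    fit = bn$fit
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE,
                              digits = I(17), null = "null",
                              pretty = TRUE), path)
  invisible(path)
}

#' Read a fitted network from JSON
#'
#' @param path Path written by [write_fitted_bn()].
#' @return A `discrete_bn`.
#' @export
read_fitted_bn <- function(path) {
  if (!file.exists(path)) {
    abort_haebn(sprintf("fitted-network file '%s' not found", path), "io")
  }
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dag <- config_to_dag(payload$schema)
  cpts <- lapply(names(payload$cpts), function(node) {
    entry <- payload$cpts[[node]]
    vars <- unlist(entry$vars)
    card <- unlist(entry$card)
    array(unlist(entry$values), dim = card,
          dimnames = setNames(lapply(vars, function(v)
            node_categories(dag, v)), vars))
  })
  names(cpts) <- names(payload$cpts)
  discrete_bn(dag, cpts, fit = payload$fit)
}
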
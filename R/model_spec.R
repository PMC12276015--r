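# Network schema: nodes with ordered category labels, directed edges,
# and the graph utilities the rest of the pipeline relies on.

#' Construct a validated DAG model
#'
#' A `dag_model` holds the network schema: a list of nodes, each with a
#' name, an ordered set of category labels and a role (`"predictor"` or
#' `"outcome"`), plus a directed edge list. Exactly one node must carry
#' the outcome role and it must be binary with categories `low`/`high`.
#' The edge set must be acyclic, with no self-loops or duplicates.
#'
#' @param nodes List of nodes, each a list with elements `name`,
#'   `categories` (character, length >= 2) and `role`.
#' @param edges Edge list: a list of length-2 character vectors
#'   `c(parent, child)`, or a 2-column character matrix.
#' @return An object of class `dag_model`.
#' @export
#' @examples
#' dag <- dag_model(
#'   nodes = list(
#'     list(name = "Exposure", categories = c("no", "yes"),
#'          role = "predictor"),
#'     list(name = "MortalityRisk", categories = c("low", "high"),
#'          role = "outcome")
#'   ),
#'   edges = list(c("Exposure", "MortalityRisk"))
#' )
#' topological_order(dag)
dag_model <- function(nodes, edges = list()) {
  if (!is.list(nodes) || length(nodes) == 0L) {
    abort_haebn("`nodes` must be a non-empty list of node definitions.",
                "schema")
  }
  nodes <- lapply(nodes, function(nd) {
    if (is.null(nd$name) || !nzchar(nd$name)) {
      abort_haebn("every node needs a non-empty `name`", "schema")
    }
    cats <- trimws(as.character(nd$categories))
    if (length(cats) < 2L) {
      abort_haebn(sprintf("node '%s' needs at least 2 categories", nd$name),
                  "schema")
    }
    if (anyDuplicated(tolower(cats))) {
      abort_haebn(sprintf("node '%s' has duplicate category labels", nd$name),
                  "schema")
    }
    role <- match.arg(nd$role %||% "predictor", c("predictor", "outcome"))
    list(name = as.character(nd$name), categories = cats, role = role)
  })
  names(nodes) <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(names(nodes))) {
    abort_haebn("duplicate node names in schema", "schema")
  }

  out_idx <- which(vapply(nodes, `[[`, character(1), "role") == "outcome")
  if (length(out_idx) != 1L) {
    abort_haebn("exactly one node must have role = 'outcome'", "schema")
  }
  out_cats <- tolower(nodes[[out_idx]]$categories)
  if (length(out_cats) != 2L || !setequal(out_cats, c("low", "high"))) {
    abort_haebn("the outcome node must be binary with categories low/high",
                "schema")
  }

  if (is.matrix(edges)) {
    edges <- lapply(seq_len(nrow(edges)), function(i) edges[i, ])
  }
  emat <- if (length(edges)) {
    do.call(rbind, lapply(edges, function(e) {
      e <- trimws(as.character(e))
      if (length(e) != 2L) {
        abort_haebn("each edge must be a (parent, child) pair", "schema")
      }
      e
    }))
  } else {
    matrix(character(0), ncol = 2)
  }
  colnames(emat) <- c("parent", "child")

  unknown <- setdiff(c(emat), names(nodes))
  if (length(unknown)) {
    abort_haebn(sprintf("edge endpoint(s) not declared as nodes: %s",
                        paste(unknown, collapse = ", ")), "schema")
  }
  if (any(emat[, 1] == emat[, 2])) {
    abort_haebn("self-loop edges are not allowed", "schema")
  }
  if (anyDuplicated(paste(emat[, 1], emat[, 2], sep = "\r"))) {
    abort_haebn("duplicate edges are not allowed", "schema")
  }

  dag <- structure(list(nodes = nodes, edges = emat), class = "dag_model")
  topological_order(dag)  # raises haebn_acyclicity_error on a cycle
  dag
}

#' @export
print.dag_model <- function(x, ...) {
  cat(sprintf("Discrete BN schema: %d nodes, %d edges, outcome = %s\n",
              length(x$nodes), nrow(x$edges), outcome_node(x)))
  cat(sprintf("Joint state space: %s states\n",
              format(joint_state_space_size(x), big.mark = ",")))
  invisible(x)
}

#' Node names of a DAG model
#' @param dag A `dag_model`.
#' @return Character vector in declaration order.
#' @export
node_names <- function(dag) names(dag$nodes)

#' Category labels of a node
#' @param dag A `dag_model`.
#' @param node Node name.
#' @return Character vector of the node's ordered category labels.
#' @export
node_categories <- function(dag, node) {
  if (!node %in% names(dag$nodes)) {
    abort_haebn(sprintf("unknown node '%s'", node), "schema")
  }
  dag$nodes[[node]]$categories
}

#' Parents of a node
#' @param dag A `dag_model`.
#' @param node Node name.
#' @return Character vector of parent names, in declaration order.
#' @export
dag_parents <- function(dag, node) {
  if (!node %in% names(dag$nodes)) {
    abort_haebn(sprintf("unknown node '%s'", node), "schema")
  }
  p <- dag$edges[dag$edges[, "child"] == node, "parent"]
  names(dag$nodes)[names(dag$nodes) %in% p]
}

#' The outcome node of a schema
#' @param dag A `dag_model`.
#' @return Name of the single node with role `"outcome"`.
#' @export
outcome_node <- function(dag) {
  roles <- vapply(dag$nodes, `[[`, character(1), "role")
  names(roles)[roles == "outcome"]
}

#' Predictor nodes of a schema
#' @param dag A `dag_model`.
#' @return Names of all nodes with role `"predictor"`, declaration order.
#' @export
predictor_nodes <- function(dag) {
  setdiff(node_names(dag), outcome_node(dag))
}

#' Size of the joint state space
#'
#' Product of the category counts over all nodes: the number of complete
#' joint configurations the network distributes probability over.
#'
#' @param dag A `dag_model`.
#' @return A number.
#' @export
joint_state_space_size <- function(dag) {
  prod(vapply(dag$nodes, function(nd) length(nd$categories), numeric(1)))
}

#' Topological order of the DAG
#'
#' Kahn's algorithm with declaration-order tie-breaking, so the returned
#' order is deterministic for a given schema. Every parent precedes all
#' of its children; a cycle raises an acyclicity error.
#'
#' @param dag A `dag_model` (or a bare list with `nodes` and `edges`,
#'   used internally during validation).
#' @return Character vector of node names.
#' @export
topological_order <- function(dag) {
  nn <- names(dag$nodes)
  emat <- dag$edges
  indeg <- setNames(integer(length(nn)), nn)
  if (nrow(emat)) {
    tab <- table(emat[, "child"])
    indeg[names(tab)] <- as.integer(tab)
  }
  order <- character(0)
  ready <- nn[indeg == 0L]
  while (length(ready)) {
    v <- ready[[1L]]          # declaration order: `ready` kept sorted below
    ready <- ready[-1L]
    order <- c(order, v)
    if (nrow(emat)) {
      ch <- emat[emat[, "parent"] == v, "child"]
      for (w in ch) {
        indeg[[w]] <- indeg[[w]] - 1L
        if (indeg[[w]] == 0L) {
          ready <- nn[nn %in% c(ready, w)]
        }
      }
    }
  }
  if (length(order) != length(nn)) {
    abort_haebn("the edge set contains a directed cycle", "acyclicity")
  }
  order
}

# Config parsing ------------------------------------------------------------

#' Parse a model configuration (JSON or YAML) into a DAG model
#'
#' The config declares `nodes` (each with `name`, `categories`, `role`)
#' and `edges` (a list of `[parent, child]` pairs). JSON is tried first,
#' then YAML; a path ending in `.yml`/`.yaml` goes straight to the YAML
#' reader.
#'
#' @param path Path to a config file. Exactly one of `path`/`text`.
#' @param text Config given directly as a string.
#' @return A validated `dag_model`.
#' @seealso [default_model()] for the shipped hereditary-angioedema schema.
#' @export
parse_model_config <- function(path = NULL, text = NULL) {
  if (is.null(path) == is.null(text)) {
    abort_haebn("supply exactly one of `path` or `text`", "argument")
  }
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort_haebn(sprintf("model config '%s' not found", path), "io")
    }
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      cfg <- yaml::yaml.load(text)
      return(config_to_dag(cfg))
    }
  }
  cfg <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) {
      tryCatch(yaml::yaml.load(text), error = function(e2) {
        abort_haebn("model config is neither valid JSON nor valid YAML",
                    "format")
      })
    }
  )
  config_to_dag(cfg)
}

config_to_dag <- function(cfg) {
  if (is.null(cfg$nodes)) {
    abort_haebn("model config must declare `nodes`", "format")
  }
  dag_model(nodes = cfg$nodes, edges = cfg$edges %||% list())
}

#' Serialize a DAG model to a JSON model config
#'
#' Writing then re-parsing reproduces an identical `dag_model`.
#'
#' @param dag A `dag_model`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned instead.
#' @return The JSON string, invisibly when written to `path`.
#' @export
write_model_config <- function(dag, path = NULL) {
  cfg <- list(
    nodes = lapply(unname(dag$nodes), function(nd) {
      list(name = nd$name, categories = as.list(nd$categories),
           role = nd$role)
    }),
    edges = lapply(seq_len(nrow(dag$edges)),
                   function(i) as.list(unname(dag$edges[i, ])))
  )
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(as.character(json))
}

#' The default hereditary-angioedema network schema
#'
#' Ten nodes: age group, race, income quartile, primary payer, census
#' region, hypertension, autoimmune disease, diabetes, APR-DRG severity,
#' and the binary mortality-risk outcome. The default edge set routes the
#' demographic nodes directly into mortality risk, age additionally into
#' the three comorbidities, the comorbidities into admission severity,
#' and severity into mortality risk. The shipped JSON config file
#' (`system.file("extdata", "default_model.json", package = "haebn")`) is
#' the single source of truth; pass an alternative config to use a
#' different structure without code changes.
#'
#' @return A `dag_model` with 10 nodes and 12 edges.
#' @export
#' @examples
#' dag <- default_model()
#' joint_state_space_size(dag)  # 65,536 joint states
default_model <- function() {
  parse_model_config(system.file("extdata", "default_model.json",
                                 package = "haebn", mustWork = TRUE))
}

# Label canonicalization ----------------------------------------------------

# Match labels to declared categories case-insensitively after trimming.
# Unknown labels are reported with their positions; never coerced.
canonicalize_categories <- function(values, categories, context = "value") {
  idx <- match(tolower(trimws(values)), tolower(categories))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    abort_haebn(sprintf(
      "unknown %s label(s) %s at position(s) %s (expected one of: %s)",
      context,
      paste(sQuote(unique(values[bad])), collapse = ", "),
      paste(head(bad, 5L), collapse = ", "),
      paste(categories, collapse = ", ")), "format")
  }
  categories[idx]
}
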
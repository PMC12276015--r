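# The conditional-risk query battery: baseline risk, single-factor
# conditioning deltas, multi-factor scenarios, and report output.

high_state <- function(dag) {
  cats <- node_categories(dag, outcome_node(dag))
  cats[match("high", tolower(cats))]
}

#' Baseline mortality risk of a network
#'
#' `P(outcome = high)` with no evidence: the model's marginal posterior
#' estimate, which differs from the raw cohort prevalence whenever the
#' Dirichlet prior carries weight (it pulls sparse CPT rows toward
#' uniform). All conditioning deltas are benchmarked against this value.
#'
#' @param bn A `discrete_bn`.
#' @return `P(outcome = high)` as a probability.
#' @export
baseline_risk <- function(bn) {
  q <- posterior_by_elimination(bn, outcome_node(bn$dag))
  unname(q$probs[high_state(bn$dag)])
}

#' Single-factor conditioning deltas
#'
#' For every (predictor node, state) pair, the probability of the
#' high-risk outcome under hard evidence on that single state, and its
#' signed change from the baseline in percentage points. Rows are
#' sorted by absolute delta, largest first. Within each node the rows
#' satisfy the law of total probability: the state probabilities
#' weighted by the node's marginal recover the baseline exactly.
#'
#' @param bn A `discrete_bn`.
#' @return Data frame with columns `node`, `state`, `p_high`,
#'   `delta_pp`, plus a `baseline` attribute.
#' @export
single_factor_deltas <- function(bn) {
  dag <- bn$dag
  base <- baseline_risk(bn)
  hs <- high_state(dag)
  rows <- do.call(rbind, lapply(predictor_nodes(dag), function(node) {
    do.call(rbind, lapply(node_categories(dag, node), function(state) {
      ev <- do.call(evidence, setNames(list(state), node))
      p <- posterior_by_elimination(bn, outcome_node(dag), ev)$probs[[hs]]
      data.frame(node = node, state = state, p_high = p,
                 delta_pp = 100 * p - 100 * base,
                 stringsAsFactors = FALSE)
    }))
  }))
  rows <- rows[order(-abs(rows$delta_pp)), ]
  rownames(rows) <- NULL
  attr(rows, "baseline") <- base
  rows
}

# Scenario specs ------------------------------------------------------------

#' Default multi-factor risk scenarios
#'
#' The four scenario queries shipped with the package: Black patients in
#' the Midwest; Black patients in the South; Black patients in the
#' Midwest aged 65+; and Hispanic patients covered by Medicare or
#' Medicaid (the payer spread over the two states as an explicit
#' likelihood, since the schema has a single payer node).
#'
#' @return List of scenario specs (`label` + `evidence`).
#' @export
default_scenarios <- function() {
  list(
    list(label = "Black, Midwest",
         evidence = list(Race = "Black", Region = "Midwest")),
    list(label = "Black, South",
         evidence = list(Race = "Black", Region = "South")),
    list(label = "Black, Midwest, age >=65",
         evidence = list(Race = "Black", Region = "Midwest",
                         Age = ">=65")),
    list(label = "Hispanic, Medicare/Medicaid",
         evidence = list(Race = "Hispanic",
                         Payer = c(Medicare = 0.5, Medicaid = 0.5)))
  )
}

#' Read scenario specs from a JSON file
#'
#' Format: a JSON list of objects `{label, evidence}` where each
#' evidence entry maps a node either to a state label or to an object
#' of `state: weight` pairs.
#'
#' @param path JSON file path.
#' @return List of scenario specs.
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) {
    abort_haebn(sprintf("scenario file '%s' not found", path), "io")
  }
  specs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(specs, function(sp) {
    list(label = sp$label %||% "scenario",
         evidence = lapply(sp$evidence, function(e) {
           if (is.list(e)) unlist(e) else e
         }))
  })
}

# Build a bn_evidence from a scenario spec under the requested mode.
# Hard mode keeps state labels as hard findings; soft mode converts a
# state label into a likelihood vector with `strength` on the observed
# state and the remainder spread uniformly. Explicit weight vectors are
# used verbatim in either mode.
scenario_evidence <- function(spec_ev, dag, mode = c("hard", "soft"),
                              strength = 0.9) {
  mode <- match.arg(mode)
  if (strength <= 0 || strength >= 1) {
    abort_haebn("`strength` must be strictly between 0 and 1", "argument")
  }
  ev <- list()
  for (node in names(spec_ev)) {
    if (!node %in% node_names(dag)) {
      abort_haebn(sprintf("scenario names unknown node '%s'", node),
                  "argument")
    }
    x <- spec_ev[[node]]
    cats <- node_categories(dag, node)
    if (is.character(x) && length(x) == 1L) {
      state <- canonicalize_categories(x, cats, context = node)
      if (mode == "hard") {
        ev[[node]] <- state
      } else {
        k <- length(cats)
        w <- setNames(rep((1 - strength) / (k - 1), k), cats)
        w[state] <- strength
        ev[[node]] <- w
      }
    } else if (is.numeric(x)) {
      nm <- canonicalize_categories(names(x), cats, context = node)
      w <- setNames(rep(0, length(cats)), cats)
      w[nm] <- as.numeric(x)
      ev[[node]] <- w
    } else {
      abort_haebn(sprintf(
        "scenario evidence on '%s' must be a state or a weight vector",
        node), "argument")
    }
  }
  do.call(evidence, ev)
}

#' Evaluate multi-factor risk scenarios
#'
#' Runs each scenario's evidence through the inference engine in the
#' requested mode and reports the conditioned probability of the
#' high-risk outcome next to its delta from baseline. In `"soft"` mode,
#' state labels become likelihood vectors with `strength` on the
#' observed state (the observation is treated probabilistically rather
#' than deterministically); explicit weight vectors in a spec are used
#' as given. In `"hard"` mode a weight vector is expanded into one row
#' per positively weighted state.
#'
#' @param bn A `discrete_bn`.
#' @param scenarios List of scenario specs (default:
#'   [default_scenarios()]).
#' @param mode `"soft"` (default) or `"hard"`.
#' @param strength Soft-evidence likelihood on the observed state
#'   (default 0.9).
#' @return Data frame with columns `label`, `mode`, `p_high`,
#'   `delta_pp`, plus a `baseline` attribute.
#' @export
run_scenarios <- function(bn, scenarios = default_scenarios(),
                          mode = c("soft", "hard"), strength = 0.9) {
  mode <- match.arg(mode)
  dag <- bn$dag
  base <- baseline_risk(bn)
  hs <- high_state(dag)

  expand_specs <- function(sp) {
    multi <- names(sp$evidence)[vapply(sp$evidence, is.numeric, logical(1))]
    if (mode == "hard" && length(multi)) {
      # one hard run per positively weighted state of each weight spec
      out <- list()
      for (node in multi) {
        w <- sp$evidence[[node]]
        for (state in names(w)[w > 0]) {
          ev2 <- sp$evidence
          ev2[[node]] <- state
          out <- c(out, expand_specs(list(
            label = sprintf("%s [%s=%s]", sp$label, node, state),
            evidence = ev2)))
        }
        return(out)
      }
    }
    list(sp)
  }

  specs <- do.call(c, lapply(scenarios, expand_specs))
  rows <- do.call(rbind, lapply(specs, function(sp) {
    if (length(sp$evidence) == 0L) {
      abort_haebn(sprintf("scenario '%s' has empty evidence", sp$label),
                  "argument")
    }
    ev <- scenario_evidence(sp$evidence, dag, mode, strength)
    p <- posterior_by_elimination(bn, outcome_node(dag), ev)$probs[[hs]]
    data.frame(label = sp$label, mode = mode, p_high = p,
               delta_pp = 100 * p - 100 * base, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  attr(rows, "baseline") <- base
  rows
}

#' Write the risk-analysis report
#'
#' Emits a machine-readable CSV pair (full precision) and a markdown
#' summary (percentages at one decimal place) covering the baseline,
#' the single-factor delta table and any scenarios.
#'
#' @param deltas Output of [single_factor_deltas()].
#' @param scenarios Output of [run_scenarios()], or `NULL`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(deltas, scenarios = NULL, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok) abort_haebn(sprintf("cannot create directory '%s'", dir), "io")
  base <- attr(deltas, "baseline")
  files <- c(deltas = file.path(dir, "risk_deltas.csv"),
             report = file.path(dir, "risk_report.md"))
  d <- deltas
  d$baseline <- base
  write.csv(format(d, digits = 17, trim = TRUE, scientific = FALSE),
            files[["deltas"]], row.names = FALSE, quote = FALSE)

  lines <- c("# Conditional mortality-risk report", "",
             sprintf("Baseline P(high mortality risk): %.1f%%",
                     100 * base), "",
             "## Single-factor conditioning", "",
             "| Node | State | P(high) | Delta (pp) |",
             "|---|---|---|---|",
             sprintf("| %s | %s | %.1f%% | %+.1f |", deltas$node,
                     deltas$state, 100 * deltas$p_high, deltas$delta_pp))
  if (!is.null(scenarios) && nrow(scenarios)) {
    files[["scenarios"]] <- file.path(dir, "risk_scenarios.csv")
    s <- scenarios
    s$baseline <- base
    write.csv(format(s, digits = 17, trim = TRUE, scientific = FALSE),
              files[["scenarios"]], row.names = FALSE, quote = FALSE)
    lines <- c(lines, "", "## Multi-factor scenarios", "",
               "| Scenario | Mode | P(high) | Delta (pp) |",
               "|---|---|---|---|",
               sprintf("| %s | %s | %.1f%% | %+.1f |", scenarios$label,
                       scenarios$mode, 100 * scenarios$p_high,
                       scenarios$delta_pp))
  }
  writeLines(lines, files[["report"]])
  invisible(files)
}
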
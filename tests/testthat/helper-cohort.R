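# Shared fixtures, built in code. The default cohort (full study conditions,
# seed 1) is expensive enough to compute once and reuse across test files.

.fixtures <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.fixtures$default_run)) {
    .fixtures$default_run <- suppressMessages(run_all(cohort_config(seed = 1L)))
  }
  .fixtures$default_run
}

small_config <- function(seed = 7L, ...) {
  cohort_config(n_sites = 10, seed = seed, ...)
}

# mean fitted aridity slope (per 0.1 AI) across depths for one seeded cohort,
# field moisture only
fitted_gradient_slopes <- function(seed) {
  cfg <- cohort_config(seed = seed, moisture_levels = "field")
  cohort <- generate_cohort(cfg)
  em <- compute_fluxes(cohort$incubation, cfg$protocol)
  part <- partition_all(em, cohort$samples, cfg$end_members)
  q10 <- fit_q10_all(part, cohort$samples, sources = c("SOC", "SIC"))
  g <- aridity_gradient(q10, cohort$sites)
  c(soc = mean(g$slope_per_0p1_ai[g$source == "SOC"]),
    sic = mean(g$slope_per_0p1_ai[g$source == "SIC"]))
}

# brute-force total-effect oracle: enumerate every directed path from each
# predictor to the response and sum the products of edge coefficients
enumerate_total_effects <- function(dag, response) {
  nodes <- unique(c(dag$from, dag$to))
  paths_sum <- function(node) {
    if (node == response) return(1)
    out <- dag[dag$from == node, , drop = FALSE]
    if (nrow(out) == 0) return(0)
    sum(out$coefficient * vapply(out$to, paths_sum, numeric(1)))
  }
  preds <- setdiff(nodes, response)
  setNames(vapply(preds, paths_sum, numeric(1)), preds)
}

# all directed graphs on `n` labelled nodes (edge subsets), keeping the
# acyclic ones; returns list of data.frames(from, to)
all_dags <- function(n) {
  nodes <- paste0("v", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  m <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^m - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1)))
    edges <- pairs[sel, , drop = FALSE]
    if (nrow(edges) == 0) next
    ok <- tryCatch({
      dryq10:::topological_order(unique(c(edges$from, edges$to)), edges)
      TRUE
    }, error = function(e) FALSE)
    if (ok) out[[length(out) + 1]] <- edges
  }
  out
}

# random DAG on n nodes: random topological order, each forward edge kept
# with probability p
random_dag <- function(n, p = 0.5) {
  nodes <- sample(paste0("v", seq_len(n)))
  edges <- expand.grid(i = seq_len(n), j = seq_len(n))
  edges <- edges[edges$i < edges$j, ]
  keep <- runif(nrow(edges)) < p
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0) return(NULL)
  data.frame(from = nodes[edges$i], to = nodes[edges$j],
             stringsAsFactors = FALSE)
}

# path_model stub with a given coefficient edge list, for effect-decomposition
# checks that do not need data
manual_path_model <- function(dag, response) {
  nodes <- unique(c(dag$from, dag$to))
  B <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(dag))) B[dag$from[i], dag$to[i]] <- dag$coefficient[i]
  structure(list(nodes = nodes, dag = dag, B = B, response = response),
            class = "path_model")
}
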
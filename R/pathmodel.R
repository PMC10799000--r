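#' First-principal-component composite scores
#'
#' Standardizes the member variables (mean 0, SD 1) and projects them onto the
#' first eigenvector of their correlation matrix. The eigenvector sign is
#' fixed so the loading of the first listed member is positive, removing the
#' reflection ambiguity.
#'
#' @param data Data frame containing the member columns.
#' @param members Character vector of >= 2 column names.
#' @param name Composite label.
#' @return A list of class `composite`: `name`, `members`, `loadings`
#'   (unit norm), `variance_explained`, and `scores`.
#' @export
composite_scores <- function(data, members, name = "composite") {
  stopifnot(length(members) >= 2)
  missing_cols <- setdiff(members, names(data))
  if (length(missing_cols) > 0) {
    stop("missing composite member columns: ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(data[members])
  keep <- complete.cases(x)
  x <- x[keep, , drop = FALSE]
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("constant column in composite members: ",
         paste(members[sds == 0], collapse = ", "))
  }
  xs <- scale(x)
  eg <- eigen(cor(x), symmetric = TRUE)
  v <- eg$vectors[, 1]
  if (v[1] < 0) v <- -v
  scores <- rep(NA_real_, nrow(data))
  scores[keep] <- as.numeric(xs %*% v)
  structure(list(name = name, members = members,
                 loadings = setNames(v, members),
                 variance_explained = eg$values[1] / length(members),
                 scores = scores),
            class = "composite")
}

# topological order of a DAG given as a data.frame(from, to); errors on cycles
topological_order <- function(nodes, edges) {
  indeg <- setNames(integer(length(nodes)), nodes)
  for (to in edges$to) indeg[to] <- indeg[to] + 1L
  order <- character(0)
  avail <- nodes[indeg == 0]
  edges_left <- edges
  while (length(avail) > 0) {
    nd <- avail[1]
    avail <- avail[-1]
    order <- c(order, nd)
    out <- edges_left$from == nd
    for (to in edges_left$to[out]) {
      indeg[to] <- indeg[to] - 1L
      if (indeg[to] == 0) avail <- c(avail, to)
    }
    edges_left <- edges_left[!out, , drop = FALSE]
  }
  if (length(order) != length(nodes)) stop("DAG contains a cycle")
  order
}

#' Fit a recursive path model
#'
#' Estimates each structural equation of an acyclic path diagram by least
#' squares on standardized variables, which coincides with maximum likelihood
#' for recursive, fully observed systems with uncorrelated errors. Reported
#' coefficients are therefore standardized path coefficients; for a
#' single-predictor equation the coefficient equals the Pearson correlation.
#'
#' @param data Data frame with one column per node (composite scores and the
#'   response); rows with any missing node value are dropped.
#' @param dag Data frame with columns `from`, `to` describing the directed
#'   edges.
#' @param response Name of the response node (defaults to a node with no
#'   outgoing edges).
#' @return A list of class `path_model`: `nodes`, `dag` (with a `coefficient`
#'   column), coefficient matrix `B` (`B[i, j]` = standardized effect of node
#'   i in the equation of node j), `residual_variances`, `exogenous`,
#'   sample correlation matrix `S`, `n`, `response`, and `fit` (see
#'   [fit_statistics()]).
#' @export
fit_path_model <- function(data, dag, response = NULL) {
  stopifnot(all(c("from", "to") %in% names(dag)))
  nodes <- unique(c(dag$from, dag$to))
  missing_cols <- setdiff(nodes, names(data))
  if (length(missing_cols) > 0) {
    stop("missing node columns: ", paste(missing_cols, collapse = ", "))
  }
  order <- topological_order(nodes, dag)
  x <- as.matrix(data[order])
  x <- x[complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  p <- ncol(x)
  n_par <- nrow(dag) + p  # edges + variances (resid or exog)
  if (n <= n_par) stop("n must exceed the number of free parameters")
  xs <- scale(x)
  S <- cor(x)
  endo <- unique(dag$to)
  exo <- setdiff(order, endo)
  B <- matrix(0, p, p, dimnames = list(order, order))
  psi <- setNames(numeric(p), order)
  psi[exo] <- 1  # standardized exogenous variance
  dag$coefficient <- NA_real_
  for (nd in endo) {
    preds <- dag$from[dag$to == nd]
    fit <- lm.fit(xs[, preds, drop = FALSE], xs[, nd])
    cf <- fit$coefficients
    B[preds, nd] <- cf
    dag$coefficient[dag$to == nd] <- cf[dag$from[dag$to == nd]]
    psi[nd] <- sum(fit$residuals^2) / (n - 1)
  }
  if (is.null(response)) {
    sinks <- setdiff(order, dag$from)
    response <- sinks[length(sinks)]
  }
  model <- structure(list(nodes = order, dag = dag, B = B,
                          residual_variances = psi, exogenous = exo,
                          S = S, n = n, response = response, fit = NULL),
                     class = "path_model")
  model$fit <- fit_statistics(model)
  model
}

#' Standardized direct, indirect and total effects
#'
#' Path-tracing over the fitted coefficient matrix: the direct effect of a
#' predictor on the response is its edge coefficient (0 if the edge is
#' absent); the indirect effect is the sum over all other directed paths of
#' the products of coefficients along each path; total = direct + indirect.
#' Computed via powers of the (nilpotent) coefficient matrix, which sums all
#' path products exactly.
#'
#' @param model A fitted [fit_path_model()] object.
#' @param response Response node (defaults to the model's).
#' @return Tibble with `predictor`, `direct`, `indirect`, `total`.
#' @export
effect_decomposition <- function(model, response = model$response) {
  B <- model$B
  p <- nrow(B)
  total <- B
  Bp <- B
  for (i in seq_len(p - 1)) {
    Bp <- Bp %*% B
    total <- total + Bp
  }
  preds <- setdiff(model$nodes, response)
  tibble::tibble(
    predictor = preds,
    direct = unname(B[preds, response]),
    indirect = unname(total[preds, response] - B[preds, response]),
    total = unname(total[preds, response])
  )
}

#' Maximum-likelihood fit statistics of a path model
#'
#' Builds the model-implied covariance of the standardized variables from the
#' fitted coefficients and residual variances (exogenous blocks take their
#' sample values), then evaluates the ML discrepancy
#' `F = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p`, `chi2 = (n - 1) F`,
#' `df = p(p+1)/2 - q` free parameters,
#' `RMSEA = sqrt(max(0, chi2 - df) / (df (n - 1)))` (0 when df = 0), and the
#' standard ML goodness-of-fit index
#' `GFI = 1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]`.
#'
#' @param model A `path_model`.
#' @return A list: `chi2`, `df`, `p_value`, `rmsea`, `gfi`, `F_ml`.
#' @export
fit_statistics <- function(model) {
  S <- model$S
  p <- nrow(S)
  n <- model$n
  implied <- implied_covariance(model)
  si <- solve(implied)
  detS <- det(S)
  if (detS <= 0) stop("sample covariance is singular")
  F_ml <- log(det(implied)) + sum(diag(S %*% si)) - log(detS) - p
  F_ml <- max(F_ml, 0)
  n_exo <- length(model$exogenous)
  q <- nrow(model$dag) +                      # edge coefficients
    (p - n_exo) +                             # residual variances
    n_exo * (n_exo + 1) / 2                   # exogenous (co)variances
  df <- p * (p + 1) / 2 - q
  chi2 <- (n - 1) * F_ml
  rmsea <- if (df > 0) sqrt(max(0, chi2 - df) / (df * (n - 1))) else 0
  m <- si %*% S
  gfi <- 1 - sum(diag((m - diag(p)) %*% (m - diag(p)))) / sum(diag(m %*% m))
  list(chi2 = chi2, df = df,
       p_value = if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_,
       rmsea = rmsea, gfi = gfi, F_ml = F_ml)
}

# Sigma = (I - t(B))^-1 Psi (I - t(B))^-T with exogenous block from S
implied_covariance <- function(model) {
  ord <- model$nodes
  p <- length(ord)
  L <- t(model$B)                      # L[j, i]: effect of i in equation j
  Psi <- diag(model$residual_variances, p)
  dimnames(Psi) <- list(ord, ord)
  exo <- model$exogenous
  if (length(exo) > 1) Psi[exo, exo] <- model$S[exo, exo]
  inv <- solve(diag(p) - L)
  out <- inv %*% Psi %*% t(inv)
  dimnames(out) <- list(ord, ord)
  out
}

#' Default path diagram
#'
#' Climate points at each soil composite (physical, chemical, substrate), and
#' all four composites point at the response. Inter-group arrows among the
#' three soil composites are deliberately omitted; the diagram is an argument
#' so alternative structures can be fitted.
#'
#' @param response Response node name.
#' @return Edge data frame (`from`, `to`).
#' @export
default_dag <- function(response = "q10") {
  tibble::tibble(
    from = c("climate", "climate", "climate",
             "climate", "physical", "chemical", "substrate"),
    to = c("physical", "chemical", "substrate",
           response, response, response, response)
  )
}

#' Default composite membership
#'
#' @return Named list of member-variable vectors for the climate, physical,
#'   chemical and substrate composites.
#' @export
default_composites <- function() {
  list(
    climate = c("mat", "aridity_index"),
    physical = c("oc_pom", "oc_maom", "oc_fe", "oc_ca"),
    chemical = c("ph", "cec", "ca", "mg"),
    substrate = c("soc", "sic", "cai", "d_soc")
  )
}

#' PCA-composite path analysis of a fitted cohort
#'
#' Builds the four group composites from the field-moisture factor table of
#' one depth, fits the path model for the requested Q10 response, and
#' decomposes standardized effects.
#'
#' @param q10 Fit table from [fit_q10_all()].
#' @param samples,sites Generator tables.
#' @param response `"q10_soc"` or `"q10_sic"`.
#' @param depth Depth layer.
#' @param dag Edge data frame over composites and `"q10"`.
#' @param composites Named member list, as [default_composites()].
#' @return A list: `model` (path_model), `effects`, `composites` (fitted
#'   composite objects), `data` (node scores).
#' @export
run_path_analysis <- function(q10, samples, sites,
                              response = c("q10_soc", "q10_sic"),
                              depth = "topsoil",
                              dag = default_dag("q10"),
                              composites = default_composites()) {
  response <- match.arg(response)
  fac <- factor_table(q10, samples, sites, depth)
  fac <- fac[is.finite(fac[[response]]) & is.finite(fac$d_soc), ]
  comps <- lapply(names(composites), function(nm) {
    composite_scores(fac, composites[[nm]], nm)
  })
  names(comps) <- names(composites)
  node_data <- tibble::as_tibble(lapply(comps, function(cp) cp$scores))
  node_data$q10 <- fac[[response]]
  model <- fit_path_model(node_data, dag, response = "q10")
  list(model = model, effects = effect_decomposition(model),
       composites = comps, data = node_data)
}
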
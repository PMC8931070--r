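## Node-level covariates and whole-network topology summary.
##
## Path-based quantities (betweenness, diameters, shortest paths) are
## hop counts on the unweighted directed graph: interpreting kcal
## weights as distances would invert their meaning.  Clustering is the
## unweighted local coefficient on the undirected projection.  Hub
## scores and PageRank do use the calorie weights.

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges,
    vertices = data.frame(name = network$countries$id),
    directed = TRUE)
}

#' Per-country topology covariates
#'
#' Degrees and strengths over positive-weight edges; import
#' concentration C4 (share of the four largest suppliers in total
#' imports; 0 for a country with no imports); unweighted local
#' clustering on the undirected projection (0 for nodes with fewer
#' than two neighbours); raw directed unweighted betweenness; weighted
#' HITS hub score (non-negative, unit 2-norm); weighted PageRank with
#' damping 0.85; and the full ANND/ANNS suite over the direction pairs
#' (in, out, tot) x (in, out, tot).
#'
#' @param network a \code{trade_network}
#' @return data.frame, one row per country in sorted id order
#' @export
node_features <- function(network) {
  stopifnot(inherits(network, "trade_network"))
  W <- weight_matrix(network)
  g <- as_igraph(network)
  gu <- igraph::as_undirected(g, mode = "collapse")

  c4 <- apply(W, 2, function(w) {
    w <- w[w > 0]
    if (length(w) == 0) 0 else sum(sort(w, decreasing = TRUE)[seq_len(min(4, length(w)))]) / sum(w)
  })
  ## pin the RNG so the ARPACK start vector (and hence the last ulp of
  ## the converged eigenvector) is reproducible across sessions
  hub <- with_seed(0L, igraph::hits_scores(g))$hub
  hub <- abs(hub)
  nrm <- sqrt(sum(hub^2))
  if (nrm > 0) hub <- hub / nrm

  out <- data.frame(
    id = network$countries$id,
    in_degree = unname(colSums(W > 0)),
    out_degree = unname(rowSums(W > 0)),
    in_strength = unname(colSums(W)),
    out_strength = unname(rowSums(W)),
    c4 = unname(c4),
    clustering = igraph::transitivity(gu, type = "local",
                                      isolates = "zero"),
    betweenness = unname(igraph::betweenness(g, directed = TRUE,
                                             weights = NA)),
    hub = unname(hub),
    pagerank = unname(igraph::page_rank(g, damping = 0.85)$vector),
    stringsAsFactors = FALSE)
  for (a in c("in", "out", "tot")) for (b in c("in", "out", "tot")) {
    out[[paste("annd", a, b, sep = "_")]] <-
      annd_anns(network, a, b, stat = "degree")$values
    out[[paste("anns", a, b, sep = "_")]] <-
      annd_anns(network, a, b, stat = "strength")$values
  }
  rownames(out) <- NULL
  attr(out, "network_hash") <- network_hash(network)
  out
}

#' Average nearest-neighbour degree/strength and assortativity
#'
#' For each node, the mean degree (ANND) or strength (ANNS) of its
#' alpha-directional neighbourhood, where the neighbour values are taken
#' in the beta direction; plus the Pearson correlation between the
#' node's own alpha-degree (or strength) and its ANND (ANNS), the
#' (dis)assortativity coefficient.  The \code{tot} neighbourhood is the
#' union of in- and out-neighbours; \code{tot} degree and strength are
#' the in/out sums.  Nodes with an empty alpha-neighbourhood get NA and
#' are excluded from the correlation.
#'
#' @param network a \code{trade_network}
#' @param alpha_dir,beta_dir one of "in", "out", "tot"
#' @param stat "degree" (ANND) or "strength" (ANNS)
#' @return list with \code{values} (per node, NA when the neighbourhood
#'   is empty), \code{correlation} (NA when fewer than 3 usable nodes or
#'   zero variance), \code{n_used}, \code{n_excluded}
#' @export
annd_anns <- function(network, alpha_dir = "tot", beta_dir = "tot",
                      stat = c("degree", "strength")) {
  stat <- match.arg(stat)
  stopifnot(alpha_dir %in% c("in", "out", "tot"),
            beta_dir %in% c("in", "out", "tot"))
  W <- weight_matrix(network)
  A <- W > 0
  n <- nrow(W)
  kin <- colSums(A); kout <- rowSums(A)
  sin <- colSums(W); sout <- rowSums(W)
  own_deg <- switch(alpha_dir, "in" = kin, "out" = kout, tot = kin + kout)
  beta_val <- if (stat == "degree")
    switch(beta_dir, "in" = kin, "out" = kout, tot = kin + kout)
  else
    switch(beta_dir, "in" = sin, "out" = sout, tot = sin + sout)

  vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nbrs <- switch(alpha_dir,
                   "in" = which(A[, i]),
                   "out" = which(A[i, ]),
                   tot = which(A[, i] | A[i, ]))
    if (length(nbrs) > 0) vals[i] <- sum(beta_val[nbrs]) / length(nbrs)
  }
  own <- if (stat == "degree") own_deg
  else switch(alpha_dir, "in" = sin, "out" = sout, tot = sin + sout)
  use <- !is.na(vals) & own_deg > 0
  corr <- NA_real_
  if (sum(use) >= 3 && stats::sd(own[use]) > 0 && stats::sd(vals[use]) > 0)
    corr <- stats::cor(own[use], vals[use])
  list(values = vals, correlation = corr,
       n_used = sum(use), n_excluded = sum(!use))
}

#' Whole-network topology summary
#'
#' The standard summary suite for a directed weighted trade network:
#' counts, density, average link weight, reciprocity, strongly/weakly
#' connected components, clustering and transitivity, diameters and
#' average shortest paths (unweighted; the directed diameter is NA when
#' the network is not strongly connected), and the degree-ANND and
#' strength-ANNS assortativity coefficients for the direction pairs
#' tot/tot, in/in, in/out, out/in, out/out.
#'
#' @param network a \code{trade_network}
#' @return an object of class \code{topology_summary} (a named list)
#' @export
topology_summary <- function(network) {
  stopifnot(inherits(network, "trade_network"))
  g <- as_igraph(network)
  gu <- igraph::as_undirected(g, mode = "collapse")
  n <- network$n
  m <- nrow(network$edges)
  scc <- igraph::components(g, mode = "strong")
  wcc <- igraph::components(g, mode = "weak")
  combos <- list(c("tot", "tot"), c("in", "in"), c("in", "out"),
                 c("out", "in"), c("out", "out"))
  deg_as <- vapply(combos, function(cc)
    annd_anns(network, cc[1], cc[2], "degree")$correlation, numeric(1))
  str_as <- vapply(combos, function(cc)
    annd_anns(network, cc[1], cc[2], "strength")$correlation, numeric(1))
  nm <- vapply(combos, function(cc) paste(cc[1], cc[2], sep = "/"),
               character(1))
  names(deg_as) <- nm; names(str_as) <- nm

  out <- list(
    n_nodes = n,
    n_edges = m,
    avg_degree = m / n,
    density = m / (n * (n - 1)),
    avg_link_weight = if (m > 0) mean(network$edges$weight) else 0,
    reciprocity = igraph::reciprocity(g),
    n_scc = scc$no,
    n_wcc = wcc$no,
    largest_scc = if (scc$no > 0) max(scc$csize) else 0L,
    largest_wcc = if (wcc$no > 0) max(wcc$csize) else 0L,
    avg_clustering = mean(igraph::transitivity(gu, type = "local",
                                               isolates = "zero")),
    transitivity = igraph::transitivity(gu, type = "global"),
    directed_diameter = if (scc$no == 1L)
      igraph::diameter(g, directed = TRUE, weights = NA) else NA_real_,
    avg_shortest_path = igraph::mean_distance(g, directed = TRUE,
                                              weights = NA,
                                              unconnected = TRUE),
    undirected_diameter = igraph::diameter(gu, directed = FALSE,
                                           weights = NA,
                                           unconnected = TRUE),
    undirected_avg_shortest_path = igraph::mean_distance(gu,
                                                         directed = FALSE,
                                                         weights = NA,
                                                         unconnected = TRUE),
    degree_annd_assortativity = deg_as,
    strength_anns_assortativity = str_as)
  class(out) <- "topology_summary"
  out
}

#' @export
print.topology_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "N.A." else format(signif(v, 6))
  rows <- c(
    "#Nodes" = x$n_nodes, "#Edges" = x$n_edges,
    "Average degree" = x$avg_degree, "Density" = x$density,
    "Average link weight" = x$avg_link_weight,
    "Reciprocity" = x$reciprocity,
    "#Strongly connected components (SCCs)" = x$n_scc,
    "#Weakly connected components (WCCs)" = x$n_wcc,
    "Size largest SCC" = x$largest_scc,
    "Size largest WCC" = x$largest_wcc,
    "Average (unweighted) clustering coefficient" = x$avg_clustering,
    "Transitivity" = x$transitivity,
    "Directed diameter" = x$directed_diameter,
    "Average shortest path length" = x$avg_shortest_path,
    "Undirected diameter" = x$undirected_diameter,
    "Undirected average shortest path length" =
      x$undirected_avg_shortest_path)
  cat("Network topology summary\n")
  for (i in seq_along(rows))
    cat(sprintf("  %-45s %s\n", names(rows)[i], fmt(rows[i])))
  for (nm in names(x$degree_annd_assortativity))
    cat(sprintf("  %-45s %s\n", paste0("Degree-ANND ", nm, " assortativity"),
                fmt(x$degree_annd_assortativity[nm])))
  for (nm in names(x$strength_anns_assortativity))
    cat(sprintf("  %-45s %s\n", paste0("Strength-ANNS ", nm, " assortativity"),
                fmt(x$strength_anns_assortativity[nm])))
  invisible(x)
}
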
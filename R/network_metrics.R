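as_metric_graph <- function(net) {
  if (inherits(net, "trait_network")) return(net$graph)
  if (inherits(net, "igraph")) return(net)
  abort("expected a trait_network or an igraph object.")
}

#' Edge density of a trait network
#'
#' Realized edges over all possible edges, `m / (n(n-1)/2)`: the proportion
#' of trait-trait relationships identified as significant out of all
#' logically possible connections. High edge density indicates a
#' well-connected trait network.
#'
#' @param net a `trait_network` or undirected igraph object.
#' @return A number in `[0, 1]`.
#' @export
edge_density <- function(net) {
  g <- as_metric_graph(net)
  n <- igraph::vcount(g)
  if (n < 2L) abort("edge density needs at least 2 nodes.")
  igraph::ecount(g) / choose(n, 2)
}

#' Detect modules and compute modularity
#'
#' Partitions the trait values into modules (groups with more internal than
#' external connections) and evaluates Newman-Girvan modularity Q. The
#' default algorithm is deterministic greedy agglomerative modularity
#' maximization (Clauset-Newman-Moore), so repeated runs agree without a
#' seed; Louvain and Leiden are available with an explicit seed. Isolated
#' nodes form singleton modules; an edgeless graph has Q defined as 0.
#'
#' @param net a `trait_network` or undirected igraph object.
#' @param method `"fast_greedy"` (default, deterministic), `"louvain"` or
#'   `"leiden"`.
#' @param seed integer seed, required for the stochastic methods.
#' @return An object of class `trait_modules`: list with `membership`
#'   (named integer vector), `modularity` (Q), `n_modules` and `method`.
#' @export
detect_modules <- function(net, method = c("fast_greedy", "louvain", "leiden"),
                           seed = NULL) {
  g <- as_metric_graph(net)
  method <- match.arg(method)
  n <- igraph::vcount(g)
  if (n == 0L) abort("cannot partition an empty graph.")
  nm <- igraph::V(g)$name %||% as.character(seq_len(n))

  if (igraph::ecount(g) == 0L) {
    membership <- setNames(seq_len(n), nm)
    return(structure(
      list(membership = membership, modularity = 0, n_modules = n, method = method),
      class = "trait_modules"
    ))
  }

  comm <- switch(method,
    fast_greedy = igraph::cluster_fast_greedy(g),
    louvain = {
      if (is.null(seed)) abort("`louvain` is stochastic: supply `seed`.")
      withr::with_seed(seed, igraph::cluster_louvain(g))
    },
    leiden = {
      if (is.null(seed)) abort("`leiden` is stochastic: supply `seed`.")
      withr::with_seed(
        seed,
        igraph::cluster_leiden(g, objective_function = "modularity", n_iterations = 10L)
      )
    }
  )
  membership <- setNames(as.integer(igraph::membership(comm)), nm)
  q <- igraph::modularity(g, membership)
  # Never return a partition worse than the connected-components one (whose
  # Q is always >= 0): greedy agglomeration can cut at a negative-Q stage on
  # structureless graphs such as stars or cliques. Components also keep
  # isolated nodes as singleton modules.
  comp <- setNames(as.integer(igraph::components(g)$membership), nm)
  q_comp <- igraph::modularity(g, comp)
  if (q_comp > q + 1e-12) {
    membership <- comp
    q <- q_comp
  }
  structure(
    list(
      membership = membership, modularity = q,
      n_modules = length(unique(membership)), method = method
    ),
    class = "trait_modules"
  )
}

#' @export
print.trait_modules <- function(x, ...) {
  cat(sprintf(
    "<trait_modules> %d modules, Q = %.4f (%s)\n",
    x$n_modules, x$modularity, x$method
  ))
  invisible(x)
}

#' Freeman degree centralization
#'
#' Network-level summary of how concentrated connectivity is on few trait
#' values: `sum_i (d_max - d_i) / ((n-1)(n-2))`. A star scores 1 (one hub
#' holds every connection), any regular graph (e.g. a cycle) scores 0.
#' Networks relying on one or two hub traits are read as more sensitive to
#' disturbance.
#'
#' @param net a `trait_network` or undirected igraph object.
#' @return A number in `[0, 1]`.
#' @export
degree_centralization <- function(net) {
  g <- as_metric_graph(net)
  n <- igraph::vcount(g)
  if (n < 3L) abort("degree centralization needs at least 3 nodes.")
  d <- igraph::degree(g, loops = FALSE)
  sum(max(d) - d) / ((n - 1) * (n - 2))
}

#' Node degrees, standardized degrees and keystone ranking
#'
#' Degree counts the significant partners of each trait value; standardized
#' degree divides by the maximum possible `n - 1` (used for node sizing in
#' network plots). Trait values are ranked by degree, descending, ties
#' broken lexicographically by node name; high-degree trait values are
#' candidate keystone traits.
#'
#' @param net a `trait_network` or undirected igraph object.
#' @return Tibble with columns `node`, `trait`, `level`, `degree`,
#'   `standardized_degree`, `keystone_rank`, ordered by rank.
#' @export
node_degrees <- function(net) {
  g <- as_metric_graph(net)
  n <- igraph::vcount(g)
  if (n < 1L) abort("no nodes.")
  d <- unname(igraph::degree(g, loops = FALSE))
  nm <- igraph::V(g)$name %||% as.character(seq_len(n))
  info <- if (inherits(net, "trait_network")) net$nodes else NULL
  out <- tibble(
    node = nm,
    trait = if (!is.null(info)) info$trait[match(nm, info$node)] else NA_character_,
    level = if (!is.null(info)) info$level[match(nm, info$node)] else nm,
    degree = as.integer(d),
    standardized_degree = if (n > 1L) d / (n - 1) else rep(0, n)
  )
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  out$keystone_rank <- seq_len(nrow(out))
  out
}

#' Full metric report for a trait network
#'
#' Computes the four resilience-oriented metrics in one pass: edge density,
#' modularity (with the detected module partition), Freeman degree
#' centralization, and node degrees with the keystone ranking. All metrics
#' are computed on the binary thresholded network; edge weights are
#' ignored. Centralization is `NA` for networks with fewer than 3 nodes and
#' edge density `NA` below 2 nodes rather than an error, so ensemble
#' replicates can record undefined values as missing.
#'
#' @param net a `trait_network` or undirected igraph object.
#' @param metrics subset of `c("edge_density", "modularity",
#'   "centralization", "degree")` to compute (dropping `"modularity"` skips
#'   module detection, the only non-trivial cost).
#' @param module_method,seed passed to [detect_modules()].
#' @return An object of class `trait_metrics`: list with `summary` (one-row
#'   tibble: n_nodes, n_edges, edge_density, modularity, n_modules,
#'   centralization), `nodes` (per-node tibble with degree, standardized
#'   degree, keystone rank and module id) and `modules`.
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C, A - C, C - D)
#' m <- network_metrics(as_trait_network(g))
#' glance(m)
#' tidy(m)
#' @export
network_metrics <- function(net,
                            metrics = c("edge_density", "modularity",
                                        "centralization", "degree"),
                            module_method = "fast_greedy", seed = NULL) {
  g <- as_metric_graph(net)
  metrics <- match.arg(metrics, several.ok = TRUE)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)

  dens <- if ("edge_density" %in% metrics && n >= 2L) edge_density(g) else NA_real_
  centr <- if ("centralization" %in% metrics && n >= 3L) degree_centralization(g) else NA_real_
  mods <- NULL
  q <- NA_real_
  n_modules <- NA_integer_
  if ("modularity" %in% metrics && n >= 1L) {
    mods <- detect_modules(g, method = module_method, seed = seed)
    q <- mods$modularity
    n_modules <- mods$n_modules
  }
  nodes <- NULL
  if ("degree" %in% metrics && n >= 1L) {
    nodes <- node_degrees(net)
    if (!is.null(mods)) nodes$module <- unname(mods$membership[nodes$node])
  }

  structure(
    list(
      summary = tibble(
        n_nodes = n, n_edges = m, edge_density = dens,
        modularity = q, n_modules = n_modules, centralization = centr
      ),
      nodes = nodes,
      modules = mods
    ),
    class = "trait_metrics"
  )
}

#' @export
print.trait_metrics <- function(x, ...) {
  cat("<trait_metrics>\n")
  print(x$summary)
  if (!is.null(x$nodes)) {
    cat("top trait values by degree:\n")
    print(head(x$nodes, 5L))
  }
  invisible(x)
}

#' @describeIn network_metrics Per-node metric table.
#' @param x a `trait_metrics` object.
#' @param ... unused.
#' @method tidy trait_metrics
#' @export
tidy.trait_metrics <- function(x, ...) {
  if (is.null(x$nodes)) abort("node metrics were not computed.")
  x$nodes
}

#' @describeIn network_metrics One-row network-level summary.
#' @method glance trait_metrics
#' @export
glance.trait_metrics <- function(x, ...) x$summary
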
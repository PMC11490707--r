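# Small named benchmark graphs (stars, cycles, paths, cliques, two-clique
# bridges) with closed-form edge density and centralization.

two_clique_bridge <- function(k1, k2 = k1) {
  g1 <- igraph::make_full_graph(k1)
  g2 <- igraph::make_full_graph(k2)
  g <- igraph::disjoint_union(g1, g2)
  igraph::add_edges(g, c(1, k1 + 1))
}

fixture_graphs <- function() {
  fixtures <- list()
  for (n in 4:8) {
    fixtures[[paste0("star", n)]] <- list(
      graph = igraph::make_star(n, mode = "undirected"),
      density = (n - 1) / choose(n, 2),
      centralization = 1
    )
  }
  for (n in 3:8) {
    fixtures[[paste0("cycle", n)]] <- list(
      graph = igraph::make_ring(n),
      density = n / choose(n, 2),
      centralization = 0
    )
  }
  for (n in 3:8) {
    fixtures[[paste0("path", n)]] <- list(
      graph = igraph::make_ring(n, circular = FALSE),
      density = (n - 1) / choose(n, 2),
      centralization = 2 / ((n - 1) * (n - 2))
    )
  }
  for (n in 3:8) {
    fixtures[[paste0("clique", n)]] <- list(
      graph = igraph::make_full_graph(n),
      density = 1,
      centralization = 0
    )
  }
  for (k in list(c(3, 3), c(4, 4), c(3, 4))) {
    n <- sum(k)
    fixtures[[paste0("bridge", k[1], k[2])]] <- list(
      graph = two_clique_bridge(k[1], k[2]),
      density = (choose(k[1], 2) + choose(k[2], 2) + 1) / choose(n, 2),
      # the two bridge endpoints have degree k_i, everyone else k_i - 1
      centralization = sum(max(k) - c(k, rep(k[1] - 1, k[1] - 1), rep(k[2] - 1, k[2] - 1))) /
        ((n - 1) * (n - 2))
    )
  }
  for (f in names(fixtures)) {
    g <- fixtures[[f]]$graph
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
    fixtures[[f]]$graph <- g
  }
  fixtures
}

# A small expanded trait table with planted structure, for pipeline tests.
toy_observations <- function(n_obs = 30, seed = 42) {
  sc <- trait_scenario(
    n_species = 40, n_sites = n_obs, traits = c(a = 3, b = 3, c = 4),
    rho_in = 0.9, rho_out = 0
  )
  sim <- generate_modern(sc, seed = seed)
  compute_cwm(sim$community, expand_traits(sim$traits))
}
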
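test_that("er_null_ensemble preserves n and m in every replicate", {
  g <- withr::with_seed(3, igraph::sample_gnm(12, 20))
  ens <- er_null_ensemble(g, B = 50, seed = 7)
  expect_equal(nrow(ens$metrics), 50)
  expect_true(all(ens$metrics$n_nodes == 12))
  expect_true(all(ens$metrics$n_edges == 20))
  # fixed m means every null edge density equals the observed one exactly
  expect_true(all(ens$metrics$edge_density == edge_density(g)))

  # m = 0: every null is the empty graph
  e <- igraph::make_empty_graph(6, directed = FALSE)
  ens0 <- er_null_ensemble(e, B = 10, seed = 1)
  expect_true(all(ens0$metrics$edge_density == 0))
  expect_true(all(ens0$metrics$modularity == 0))
})

test_that("substreams make ensembles extensible without reshuffling", {
  g <- withr::with_seed(3, igraph::sample_gnm(10, 15))
  small <- er_null_ensemble(g, B = 20, seed = 5)
  large <- er_null_ensemble(g, B = 40, seed = 5)
  expect_equal(small$metrics, large$metrics[1:20, ])
  # and full determinism
  expect_equal(er_null_ensemble(g, B = 20, seed = 5), small)
})

test_that("G(n,m) edge frequencies are uniform and match an independent sampler", {
  n <- 8; m <- 10
  g <- withr::with_seed(4, igraph::sample_gnm(n, m))
  B <- 600
  # vertex order is 1..n in both samplers, so adjacency matrices align
  count_edges <- function(graphs) {
    tab <- matrix(0, n, n)
    for (gg in graphs) {
      tab <- tab + as.matrix(igraph::as_adjacency_matrix(gg))
    }
    tab[upper.tri(tab)] / length(graphs)
  }
  pkg_graphs <- withr::with_seed(11, lapply(1:B, function(b) igraph::sample_gnm(n, m)))
  ora_graphs <- withr::with_seed(99, lapply(1:B, function(b) oracle_gnm(n, m)))
  expected <- m / choose(n, 2)
  freq_pkg <- count_edges(pkg_graphs)
  freq_ora <- count_edges(ora_graphs)
  # every admissible edge appears at about rate m / C(n,2) in both samplers
  expect_true(all(abs(freq_pkg - expected) < 0.08))
  expect_true(all(abs(freq_ora - expected) < 0.08))

  # null ensemble means match the independent sampler within Monte-Carlo error
  ens <- er_null_ensemble(g, B = 400, seed = 12,
                          metrics = c("modularity", "centralization"))
  ora <- withr::with_seed(77, {
    t(vapply(1:400, function(b) {
      gg <- oracle_gnm(n, m)
      c(q = detect_modules(gg)$modularity, c = oracle_centralization(gg))
    }, c(q = 0, c = 0)))
  })
  expect_lt(abs(mean(ens$metrics$modularity) - mean(ora[, "q"])), 0.03)
  expect_lt(abs(mean(ens$metrics$centralization) - mean(ora[, "c"])), 0.03)
})

test_that("permutation p-values follow the add-one convention", {
  nulls <- c(1, 2, 3, 4, 5)
  expect_equal(permutation_pvalue(10, nulls, "greater"), 1 / 6)
  expect_equal(permutation_pvalue(-10, nulls, "less"), 1 / 6)
  # observed equal to every null: ties count as extreme
  expect_equal(permutation_pvalue(3, rep(3, 9), "greater"), 1)
  expect_equal(permutation_pvalue(3, rep(3, 9), "less"), 1)
  expect_equal(permutation_pvalue(3, rep(3, 9), "two_sided"), 1)
  # two-sided doubles the smaller tail, capped at 1
  expect_equal(permutation_pvalue(4.5, nulls, "two_sided"), 2 * 2 / 6)
  expect_error(permutation_pvalue(1, numeric()), "empty ensemble")
  # never zero, never above one
  withr::with_seed(6, {
    for (i in 1:20) {
      p <- permutation_pvalue(rnorm(1), rnorm(50), sample(c("greater", "less", "two_sided"), 1))
      expect_gt(p, 0)
      expect_lte(p, 1)
    }
  })
})

test_that("null_test flags structure and degenerate nulls sensibly", {
  # a star is maximally centralized: p_greater = 1/(B+1)
  s <- igraph::make_star(12, mode = "undirected")
  nt <- suppressWarnings(null_test(s, B = 99, seed = 8))
  centr <- nt[nt$metric == "centralization", ]
  expect_equal(centr$p_greater, 1 / 100)
  # edge density is constant across G(n,m) nulls -> p = 1 with a warning
  expect_warning(null_test(s, B = 19, seed = 8, metrics = "edge_density"),
                 "constant")
  nt2 <- suppressWarnings(null_test(s, B = 19, seed = 8, metrics = "edge_density"))
  expect_equal(nt2$p_greater, 1)
  expect_equal(nt2$p_less, 1)
})

test_that("bootstrap_ensemble replays an identity resample to the observed metrics", {
  obs <- toy_observations(n_obs = 20)
  net <- trait_network(obs)
  observed <- glance(network_metrics(net))
  boot <- bootstrap_ensemble(obs, replicate_indices = list(seq_len(nrow(obs))), seed = 1)
  expect_equal(boot$B, 1)
  expect_equal(boot$metrics$edge_density, observed$edge_density)
  expect_equal(boot$metrics$modularity, observed$modularity)
  expect_equal(boot$metrics$centralization, observed$centralization)
})

test_that("bootstrap_ensemble is seeded, extensible, and records degenerate replicates", {
  obs <- toy_observations(n_obs = 15)
  b1 <- bootstrap_ensemble(obs, B = 15, seed = 2)
  b2 <- bootstrap_ensemble(obs, B = 15, seed = 2)
  expect_equal(b1, b2)
  b3 <- bootstrap_ensemble(obs, B = 30, seed = 2)
  expect_equal(b1$metrics, b3$metrics[1:15, ])
  expect_error(bootstrap_ensemble(obs[1:2, ], B = 5, seed = 1), "at least 3")
  expect_true(b1$n_degenerate >= 0)
})

test_that("compare_groups matches exhaustive U and handles degenerate ensembles", {
  make_ens <- function(vals) {
    structure(
      list(
        metrics = tibble::tibble(replicate = seq_along(vals), n_nodes = 5,
                                 n_edges = 4, edge_density = vals),
        B = length(vals), seed = 1, n_obs = 10, n_degenerate = 0,
        config = list(r_star = 0.2, alpha = 0.05, rule = "p_and_r",
                      signed = "abs", within_trait = TRUE, p_adjust = "none",
                      metrics = "edge_density")
      ),
      class = "bootstrap_ensemble"
    )
  }
  # hand-listed 3 vs 3 samples: U by exhaustive pair counting
  a <- make_ens(c(0.9, 0.7, 0.5))
  b <- make_ens(c(0.6, 0.4, 0.2))
  cmp <- compare_groups(a, b)
  expect_equal(cmp$u_stat, oracle_u(c(0.9, 0.7, 0.5), c(0.6, 0.4, 0.2)))
  expect_equal(cmp$median_a, 0.7)
  expect_equal(cmp$iqr_b, stats::IQR(c(0.6, 0.4, 0.2)))

  # identical ensembles: U = B^2/2, p ~ 1, not significant
  vals <- seq(0.1, 0.9, length.out = 10)
  cmp2 <- compare_groups(make_ens(vals), make_ens(vals))
  expect_equal(cmp2$u_stat, 100 / 2)
  expect_gt(cmp2$u_p, 0.9)
  expect_false(cmp2$significant)
  expect_true(cmp2$ci_overlap)

  # complete separation: U = B1*B2, minimal p, significant difference
  cmp3 <- compare_groups(make_ens(vals + 10), make_ens(vals))
  expect_equal(cmp3$u_stat, 100)
  expect_lt(cmp3$u_p, 0.01)
  expect_true(cmp3$significant)
  expect_false(cmp3$ci_overlap)

  # constant in both ensembles: p = 1 with a warning, U = B^2/2
  expect_warning(cmp4 <- compare_groups(make_ens(rep(0.5, 8)), make_ens(rep(0.5, 8))),
                 "constant")
  expect_equal(cmp4$t_p, 1)
  expect_equal(cmp4$u_stat, 64 / 2)

  # mismatched pipeline settings are refused
  b_alt <- make_ens(vals)
  b_alt$config$r_star <- 0.5
  expect_error(compare_groups(make_ens(vals), b_alt), "different pipeline settings")
  expect_error(compare_groups(make_ens(vals), make_ens(vals), metrics = "modularity"),
               "not present")
})
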
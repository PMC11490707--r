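test_that("trait_correlation matches the textbook formula and handles exact cases", {
  x <- c(1, 0, 1, 0, 1)
  y <- c(1, 0, 0, 0, 1)
  m <- cbind(a = x, b = y)
  corr <- trait_correlation(m)
  expect_equal(corr$r["a", "b"], oracle_cor(x, y), tolerance = 1e-12)
  expect_equal(corr$p["a", "b"], oracle_cor_p(oracle_cor(x, y), 5), tolerance = 1e-12)

  # identical nonconstant columns -> r = 1, p = 0
  corr2 <- trait_correlation(cbind(a = x, b = x))
  expect_equal(corr2$r["a", "b"], 1)
  expect_equal(corr2$p["a", "b"], 0)

  # a binary column and its complement (two-level one-hot) -> r = -1
  corr3 <- trait_correlation(cbind(a = x, b = 1 - x))
  expect_equal(corr3$r["a", "b"], -1)

  expect_error(trait_correlation(m[1:2, ]), "at least 3 observations")
  expect_error(trait_correlation(cbind(a = c(1, 1, 1), b = c(2, 2, 2))),
               "all trait-value columns are constant")
})

test_that("trait_correlation equals a brute-force oracle on random matrices", {
  withr::with_seed(11, {
    for (i in 1:10) {
      m <- matrix(rnorm(12 * 6), 12, 6, dimnames = list(NULL, paste0("c", 1:6)))
      corr <- trait_correlation(m)
      for (a in 1:5) {
        for (b in (a + 1):6) {
          r_ref <- oracle_cor(m[, a], m[, b])
          expect_equal(corr$r[a, b], r_ref, tolerance = 1e-12)
          expect_equal(corr$p[a, b], oracle_cor_p(r_ref, 12), tolerance = 1e-12)
        }
      }
      expect_equal(corr$r, t(corr$r))
      expect_equal(unname(diag(corr$r)), rep(1, 6))
    }
  })
})

test_that("constant columns are flagged and excluded from the node set", {
  m <- cbind(a = c(1, 0, 1, 0), b = c(0, 1, 0, 1), c = c(1, 1, 1, 1))
  expect_warning(corr <- trait_correlation(m), "constant.*c")
  expect_true(all(is.na(corr$r[, "c"])))
  adj <- threshold_adjacency(corr)
  expect_warning(net <- build_network(adj, corr), "zero-variance.*c")
  expect_false("c" %in% net$nodes$node)
  expect_true(all(c("a", "b") %in% net$nodes$node))
})

test_that("threshold_adjacency applies the inclusion rules", {
  fake_corr <- function(r_vals, p_vals, labels) {
    k <- length(labels)
    r <- diag(k); p <- matrix(0, k, k)
    dimnames(r) <- dimnames(p) <- list(labels, labels)
    idx <- which(upper.tri(r), arr.ind = TRUE)
    r[idx] <- r_vals; p[idx] <- p_vals
    r[lower.tri(r)] <- t(r)[lower.tri(r)]
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
    structure(
      list(r = r, p = p, n_obs = 50, constant = character(),
           trait_info = tibble::tibble(column = labels, trait = labels, level = labels),
           observation_unit = "site"),
      class = "trait_correlation"
    )
  }

  # pairs (r, p): (0.25, 0.01) passes defaults; (0.15, 0.001) fails r;
  # (0.6, 0.2) fails p
  corr <- fake_corr(c(0.25, 0.15, 0.6), c(0.01, 0.001, 0.2), c("x", "y", "z"))
  a <- threshold_adjacency(corr)
  expect_equal(sum(a) / 2, 1)
  expect_equal(a["x", "y"], 1)

  # all p = 0.5 -> empty adjacency whatever r is
  corr2 <- fake_corr(c(0.9, 0.8, 0.95), c(0.5, 0.5, 0.5), c("x", "y", "z"))
  expect_equal(sum(threshold_adjacency(corr2)), 0)

  # r_star = 0, alpha = 1 -> complete graph on nonconstant columns
  m <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("x", "y", "z")))
  corr3 <- trait_correlation(m)
  expect_equal(sum(threshold_adjacency(corr3, r_star = 0, alpha = 1)) / 2, 3)

  expect_error(threshold_adjacency(corr, r_star = 2), "r_star")
  expect_error(threshold_adjacency(corr, alpha = 0), "alpha")

  # p_only ignores r; r_only ignores p; positive_only drops negative r
  corr4 <- fake_corr(c(-0.5, 0.5, 0.1), c(0.001, 0.001, 0.001), c("x", "y", "z"))
  expect_equal(sum(threshold_adjacency(corr4, rule = "p_only")) / 2, 3)
  expect_equal(sum(threshold_adjacency(corr4, rule = "r_only")) / 2, 2)
  expect_equal(sum(threshold_adjacency(corr4, rule = "p_and_r",
                                       signed = "positive_only")) / 2, 1)
})

test_that("threshold_adjacency is monotone in r_star and alpha", {
  withr::with_seed(5, {
    m <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(NULL, paste0("c", 1:8)))
    corr <- trait_correlation(m)
    prev <- NULL
    for (r_star in c(0, 0.1, 0.3, 0.6, 0.9)) {
      a <- threshold_adjacency(corr, r_star = r_star, alpha = 0.5)
      if (!is.null(prev)) expect_true(all(a <= prev))
      prev <- a
    }
    prev <- NULL
    for (alpha in c(0.5, 0.1, 0.01, 0.001)) {
      a <- threshold_adjacency(corr, r_star = 0, alpha = alpha)
      if (!is.null(prev)) expect_true(all(a <= prev))
      prev <- a
    }
  })
})

test_that("multiple-testing correction and within-trait exclusion are honoured", {
  obs <- toy_observations(n_obs = 25)
  corr <- trait_correlation(obs)
  a_raw <- threshold_adjacency(corr, rule = "p_only")
  a_bh <- threshold_adjacency(corr, rule = "p_only", p_adjust = "BH")
  expect_true(all(a_bh <= a_raw))  # BH can only remove edges

  info <- trait_info(obs)
  a_no_within <- threshold_adjacency(corr, within_trait = FALSE)
  for (tr in unique(info$trait)) {
    cols <- intersect(info$column[info$trait == tr], colnames(a_no_within))
    expect_equal(sum(a_no_within[cols, cols]), 0)
  }
})

test_that("build_network keeps isolated nodes and annotates edges", {
  labels <- paste0("t: v", 1:5)
  r <- diag(5); p <- matrix(0.9, 5, 5); diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(labels, labels)
  corr <- structure(
    list(r = r, p = p, n_obs = 30, constant = character(),
         trait_info = tibble::tibble(column = labels, trait = "t", level = labels),
         observation_unit = "site"),
    class = "trait_correlation"
  )
  empty <- matrix(0, 5, 5, dimnames = list(labels, labels))
  net <- build_network(empty, corr)
  expect_equal(igraph::vcount(net$graph), 5)
  expect_equal(igraph::ecount(net$graph), 0)

  complete <- 1 - diag(5); dimnames(complete) <- list(labels, labels)
  net2 <- build_network(complete, corr)
  expect_equal(igraph::ecount(net2$graph), choose(5, 2))
  expect_named(net2$edges, c("from", "to", "r", "p", "sign"))

  expect_error(build_network(matrix(0, 3, 3), corr), "do not match")
})

test_that("the network is invariant to observation order and the pipeline is consistent", {
  obs <- toy_observations(n_obs = 20)
  net1 <- trait_network(obs)
  net2 <- trait_network(obs[sample(nrow(obs)), ])
  expect_equal(net1$edges, net2$edges)
  expect_equal(glance(network_metrics(net1)), glance(network_metrics(net2)))

  # one-shot pipeline equals staged calls
  corr <- trait_correlation(obs)
  staged <- build_network(threshold_adjacency(corr), corr)
  expect_equal(net1$edges, staged$edges)
})

test_that("permuting a column detaches it from the network at roughly the null rate", {
  obs <- toy_observations(n_obs = 40, seed = 9)
  target <- names(obs)[2]
  hits <- withr::with_seed(21, {
    vapply(1:40, function(i) {
      shuffled <- obs
      shuffled[[target]] <- sample(shuffled[[target]])
      net <- suppressWarnings(trait_network(shuffled, r_star = 0))
      sum(net$edges$from == target | net$edges$to == target)
    }, 0)
  })
  n_other <- ncol(obs) - 2L
  # expected significant partners per shuffle is about alpha * n_other
  expect_lt(mean(hits) / n_other, 0.2)
})

test_that("network export writes GraphML, edge list and node table", {
  net <- trait_network(toy_observations(n_obs = 20))
  dir <- withr::local_tempdir()
  paths <- export_network(net, dir)
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(g), igraph::vcount(net$graph))
  expect_equal(igraph::ecount(g), igraph::ecount(net$graph))
  edges <- readr::read_tsv(paths[["edges"]], show_col_types = FALSE)
  expect_equal(nrow(edges), nrow(net$edges))
  nodes <- readr::read_csv(paths[["nodes"]], show_col_types = FALSE)
  expect_true(all(c("node", "trait", "degree") %in% names(nodes)))
})
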
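#' Pairwise trait-value correlations with significance
#'
#' Product-moment (Pearson) correlation between every pair of trait-value
#' columns across observations (sites for community-weighted means, species
#' in direct mode), with two-sided p-values from the t distribution on
#' n - 2 degrees of freedom. On binary columns this r is exactly the phi
#' coefficient. Constant columns have undefined correlations: their entries
#' are `NA`, they are reported in `$constant`, and a warning is raised.
#'
#' @param observations data frame (first column = observation id) or numeric
#'   matrix; rows = observations, columns = trait values.
#' @return An object of class `trait_correlation`: list with symmetric
#'   matrices `r` and `p`, `n_obs`, `constant` (names of zero-variance
#'   columns) and `trait_info`.
#' @export
trait_correlation <- function(observations) {
  m <- as_observation_matrix(observations)
  n <- nrow(m)
  if (n < 3L) abort(sprintf("need at least 3 observations, got %d.", n))
  if (ncol(m) < 2L) abort("need at least 2 trait-value columns.")
  if (anyNA(m)) abort("observations contain missing values.")

  sds <- apply(m, 2L, sd)
  constant <- colnames(m)[sds == 0]
  if (length(constant) == ncol(m)) abort("all trait-value columns are constant.")
  if (length(constant) > 0L) {
    warn(sprintf(
      "%d constant trait-value column(s) have undefined correlations: %s",
      length(constant), paste(constant, collapse = ", ")
    ))
  }

  r <- suppressWarnings(cor(m))
  # t-test for H0: rho = 0; |r| = 1 gives t = Inf, p = 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(r) <- 1
  diag(p) <- 0
  r[constant, ] <- NA_real_; r[, constant] <- NA_real_
  p[constant, ] <- NA_real_; p[, constant] <- NA_real_

  structure(
    list(
      r = r, p = p, n_obs = n, constant = constant,
      trait_info = resolve_trait_info(observations, colnames(m)),
      observation_unit = attr(observations, "observation_unit", exact = TRUE) %||% "observation"
    ),
    class = "trait_correlation"
  )
}

#' @export
print.trait_correlation <- function(x, ...) {
  cat(sprintf(
    "<trait_correlation> %d trait values, %d observations (%ss)%s\n",
    ncol(x$r), x$n_obs, x$observation_unit,
    if (length(x$constant)) sprintf(", %d constant column(s)", length(x$constant)) else ""
  ))
  invisible(x)
}

#' Threshold a correlation matrix into a binary adjacency matrix
#'
#' An unordered pair of trait values becomes an edge when it passes the
#' inclusion rule. The default (`rule = "p_and_r"`, `signed = "abs"`)
#' requires both `p < alpha` and `|r| >= r_star`; `"p_only"` and `"r_only"`
#' apply a single condition. Under `signed = "positive_only"` negative
#' correlations never form edges (useful when modules should reflect
#' positive co-occurrence only; note the levels of one trait are mutually
#' exclusive and hence negatively correlated). Pairs with undefined
#' correlations (constant columns) never form edges.
#'
#' @param corr a [trait_correlation()].
#' @param r_star correlation magnitude threshold in `[0, 1]`, default 0.2.
#' @param alpha significance level in `(0, 1)`, default 0.05.
#' @param rule edge inclusion rule: `"p_and_r"` (default), `"p_only"`,
#'   `"r_only"`.
#' @param signed `"abs"` (default) or `"positive_only"`.
#' @param within_trait include edges between levels of the same trait
#'   (default `TRUE`); `FALSE` removes them regardless of the rule.
#' @param p_adjust multiple-testing correction applied to the pairwise
#'   p-values before thresholding, any method of [stats::p.adjust()];
#'   default `"none"`.
#' @return Symmetric 0/1 matrix with zero diagonal and a `provenance`
#'   attribute recording every setting.
#' @export
threshold_adjacency <- function(corr, r_star = 0.2, alpha = 0.05,
                                rule = c("p_and_r", "p_only", "r_only"),
                                signed = c("abs", "positive_only"),
                                within_trait = TRUE, p_adjust = "none") {
  stopifnot(inherits(corr, "trait_correlation"))
  rule <- match.arg(rule)
  signed <- match.arg(signed)
  check_scalar_number(r_star, "r_star", 0, 1)
  check_scalar_number(alpha, "alpha", 0, 1)
  if (alpha <= 0) abort("`alpha` must be positive.")

  r <- corr$r
  p <- corr$p
  if (p_adjust != "none") {
    ut <- upper.tri(p)
    p[ut] <- p.adjust(p[ut], method = p_adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  mag <- if (signed == "abs") abs(r) else r
  pass <- switch(rule,
    p_and_r = (p < alpha) & (mag >= r_star),
    p_only = p < alpha,
    r_only = mag >= r_star
  )
  if (signed == "positive_only") pass <- pass & (r > 0)
  pass[is.na(pass)] <- FALSE
  if (!within_trait) {
    tr <- corr$trait_info$trait[match(colnames(r), corr$trait_info$column)]
    same <- outer(tr, tr, "==")
    same[is.na(same)] <- FALSE
    pass[same] <- FALSE
  }
  a <- matrix(0, nrow(r), ncol(r), dimnames = dimnames(r))
  a[pass] <- 1
  diag(a) <- 0
  a[a != t(a)] <- 0  # guard symmetry (NA asymmetries already removed)
  attr(a, "provenance") <- list(
    r_star = r_star, alpha = alpha, rule = rule, signed = signed,
    within_trait = within_trait, p_adjust = p_adjust,
    n_obs = corr$n_obs, constant = corr$constant,
    observation_unit = corr$observation_unit
  )
  a
}

#' Assemble the undirected trait network
#'
#' Builds a simple undirected graph whose nodes are trait values and whose
#' edges are the pairs retained by [threshold_adjacency()]. Edges carry the
#' correlation `r`, the p-value and the sign of the association. Trait
#' values whose column had zero variance (absent from every observation, or
#' universal) are excluded from the node set with a warning — a trait value
#' that no longer occurs cannot take part in the network. Nodes with no
#' significant partner are retained as isolated (degree 0) nodes.
#'
#' @param adjacency symmetric binary matrix with zero diagonal, usually from
#'   [threshold_adjacency()].
#' @param corr the [trait_correlation()] the adjacency was derived from.
#' @return An object of class `trait_network`: list with `graph` (igraph),
#'   `nodes` (tibble: node, trait, level), `edges` (tibble: from, to, r, p,
#'   sign) and `provenance`.
#' @export
build_network <- function(adjacency, corr) {
  stopifnot(inherits(corr, "trait_correlation"))
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    abort("`adjacency` must be a square matrix.")
  }
  if (!identical(dim(adjacency), dim(corr$r)) ||
      !identical(colnames(adjacency), colnames(corr$r))) {
    abort("adjacency and correlation dimensions/labels do not match.")
  }
  if (!all(adjacency %in% c(0, 1))) abort("`adjacency` must be binary.")
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) abort("`adjacency` must be symmetric.")
  if (any(diag(adjacency) != 0)) abort("`adjacency` must have a zero diagonal.")

  drop <- corr$constant
  if (length(drop) > 0L) {
    warn(sprintf(
      "excluding %d zero-variance trait value(s) from the node set: %s",
      length(drop), paste(drop, collapse = ", ")
    ))
  }
  keep <- setdiff(colnames(adjacency), drop)
  a <- adjacency[keep, keep, drop = FALSE]
  info <- resolve_trait_info(corr, keep)

  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected", diag = FALSE)
  igraph::V(g)$trait <- info$trait
  igraph::V(g)$level <- info$level

  el <- igraph::as_edgelist(g)
  if (nrow(el) > 0L) {
    r <- corr$r[cbind(el[, 1L], el[, 2L])]
    p <- corr$p[cbind(el[, 1L], el[, 2L])]
    edges <- tibble(
      from = el[, 1L], to = el[, 2L], r = r, p = p,
      sign = ifelse(r >= 0, "positive", "negative")
    )
  } else {
    edges <- tibble(
      from = character(), to = character(), r = numeric(), p = numeric(),
      sign = character()
    )
  }
  igraph::E(g)$r <- edges$r
  igraph::E(g)$p <- edges$p
  igraph::E(g)$sign <- edges$sign

  prov <- attr(adjacency, "provenance") %||% list()
  prov$n_obs <- prov$n_obs %||% corr$n_obs
  prov$dropped_nodes <- drop

  structure(
    list(
      graph = g,
      nodes = tibble(node = keep, trait = info$trait, level = info$level),
      edges = edges,
      trait_info = info,
      provenance = prov
    ),
    class = "trait_network"
  )
}

#' Build a trait network from observations in one call
#'
#' Convenience pipeline `trait_correlation()` |> `threshold_adjacency()` |>
#' `build_network()`; the unit rerun on every bootstrap replicate.
#'
#' @inheritParams trait_correlation
#' @inheritParams threshold_adjacency
#' @return A `trait_network` (see [build_network()]).
#' @examples
#' tab <- tibble::tibble(
#'   species = paste0("sp", 1:8),
#'   size = rep(c("S", "L"), each = 4),
#'   feeding = rep(c("grazer", "predator"), each = 4)
#' )
#' net <- trait_network(direct_trait_matrix(expand_traits(tab)))
#' net
#' @export
trait_network <- function(observations, r_star = 0.2, alpha = 0.05,
                          rule = c("p_and_r", "p_only", "r_only"),
                          signed = c("abs", "positive_only"),
                          within_trait = TRUE, p_adjust = "none") {
  corr <- trait_correlation(observations)
  a <- threshold_adjacency(corr, r_star = r_star, alpha = alpha, rule = rule,
                           signed = signed, within_trait = within_trait,
                           p_adjust = p_adjust)
  build_network(a, corr)
}

#' Coerce an igraph graph to a trait network
#'
#' Wraps an arbitrary undirected igraph object so the package's metric and
#' null-model functions apply (e.g. to benchmark graphs). Vertex attributes
#' `trait`/`level` are used if present.
#'
#' @param graph an undirected igraph object.
#' @return A `trait_network`.
#' @export
as_trait_network <- function(graph) {
  stopifnot(inherits(graph, "igraph"))
  if (igraph::is_directed(graph)) abort("trait networks are undirected.")
  g <- igraph::simplify(graph)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  }
  nm <- igraph::V(g)$name
  tr <- igraph::V(g)$trait %||% rep(NA_character_, length(nm))
  lv <- igraph::V(g)$level %||% nm
  el <- igraph::as_edgelist(g)
  edges <- tibble(
    from = el[, 1L], to = el[, 2L],
    r = igraph::E(g)$r %||% rep(NA_real_, nrow(el)),
    p = igraph::E(g)$p %||% rep(NA_real_, nrow(el)),
    sign = igraph::E(g)$sign %||% rep(NA_character_, nrow(el))
  )
  structure(
    list(
      graph = g,
      nodes = tibble(node = nm, trait = tr, level = lv),
      edges = edges,
      trait_info = tibble(column = nm, trait = tr, level = lv),
      provenance = list()
    ),
    class = "trait_network"
  )
}

#' @export
print.trait_network <- function(x, ...) {
  n <- igraph::vcount(x$graph)
  m <- igraph::ecount(x$graph)
  cat(sprintf("<trait_network> %d trait values, %d edges", n, m))
  if (n >= 2L) cat(sprintf(" (edge density %.3f)", m / choose(n, 2)))
  cat("\n")
  prov <- x$provenance
  if (length(prov) > 0L && !is.null(prov$rule)) {
    cat(sprintf(
      "  rule: %s (r* = %s, alpha = %s, %s%s), n_obs = %s\n",
      prov$rule, prov$r_star, prov$alpha, prov$signed,
      if (isFALSE(prov$within_trait)) ", within-trait edges excluded" else "",
      prov$n_obs
    ))
  }
  if (length(prov$dropped_nodes %||% character()) > 0L) {
    cat("  dropped zero-variance nodes:", paste(prov$dropped_nodes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn trait_network Edge table of a trait network.
#' @param x a `trait_network`.
#' @param ... unused.
#' @method tidy trait_network
#' @export
tidy.trait_network <- function(x, ...) x$edges

#' @describeIn trait_network One-row metric summary (see [network_metrics()]).
#' @method glance trait_network
#' @export
glance.trait_network <- function(x, ...) glance(network_metrics(x))
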
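# Lean per-replicate metric evaluation (plain named vector, no tibbles):
# ensembles call this thousands of times.
replicate_metrics <- function(g, metrics) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  out <- c(n_nodes = as.numeric(n), n_edges = as.numeric(m))
  if ("edge_density" %in% metrics) {
    out[["edge_density"]] <- if (n >= 2L) m / choose(n, 2) else NA_real_
  }
  if ("centralization" %in% metrics) {
    out[["centralization"]] <- if (n >= 3L) {
      d <- igraph::degree(g, loops = FALSE)
      sum(max(d) - d) / ((n - 1) * (n - 2))
    } else NA_real_
  }
  if ("modularity" %in% metrics) {
    if (n >= 1L && m > 0L) {
      memb <- igraph::membership(igraph::cluster_fast_greedy(g))
      out[["modularity"]] <- igraph::modularity(g, memb)
      out[["n_modules"]] <- length(unique(memb))
    } else {
      out[["modularity"]] <- if (n >= 1L) 0 else NA_real_
      out[["n_modules"]] <- as.numeric(n)
    }
  }
  out
}

#' Erdős–Rényi G(n, m) null ensemble for an observed network
#'
#' Generates `B` uniform random graphs with exactly the observed network's
#' node and edge counts but randomized structure, and computes the network
#' metrics for each replicate. Edge density is preserved by construction
#' (every replicate has the same n and m); modularity and centralization
#' vary and form the null distributions for [permutation_pvalue()] /
#' [null_test()]. Replicate `b` uses its own substream of `seed`, so
#' increasing `B` extends the ensemble without reshuffling earlier
#' replicates.
#'
#' @param net a `trait_network` or undirected igraph object.
#' @param B number of replicates (default 1000).
#' @param seed integer master seed (required).
#' @param metrics which metrics to compute per replicate (see
#'   [network_metrics()]); restricting the set speeds large ensembles up.
#' @return An object of class `null_ensemble`: list with `metrics`
#'   (tibble, one row per replicate), `n_nodes`, `n_edges`, `B`, `seed`.
#' @export
er_null_ensemble <- function(net, B = 1000L, seed,
                             metrics = c("edge_density", "modularity", "centralization")) {
  g <- as_metric_graph(net)
  B <- check_count(B, "B")
  check_scalar_number(seed, "seed")
  metrics <- match.arg(metrics, several.ok = TRUE)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n < 2L) abort("null models need at least 2 nodes.")

  rows <- vector("list", B)
  for (b in seq_len(B)) {
    gb <- withr::with_seed(substream_seed(seed, b), igraph::sample_gnm(n, m))
    rows[[b]] <- replicate_metrics(gb, metrics)
  }
  tab <- as_tibble(do.call(rbind, rows))
  tab <- dplyr::bind_cols(tibble(replicate = seq_len(B)), tab)
  structure(
    list(metrics = tab, n_nodes = n, n_edges = m, B = B, seed = seed),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "<null_ensemble> %d G(%d, %d) replicates (seed %s)\n",
    x$B, x$n_nodes, x$n_edges, format(x$seed)
  ))
  invisible(x)
}

#' @describeIn er_null_ensemble Per-replicate null metric table.
#' @param x a `null_ensemble`.
#' @param ... unused.
#' @method tidy null_ensemble
#' @export
tidy.null_ensemble <- function(x, ...) x$metrics

#' Permutation p-value of an observed metric against an ensemble
#'
#' `p = (k + 1) / (B + 1)` where `k` counts ensemble values at least as
#' extreme as the observed one (ties count as extreme); the add-one
#' convention means the p-value is never exactly 0. `"two_sided"` doubles
#' the smaller tail, capped at 1.
#'
#' @param observed observed metric value.
#' @param null_values numeric vector of ensemble metric values (`NA`s are
#'   dropped with a warning).
#' @param side `"greater"`, `"less"` or `"two_sided"` (default).
#' @return A p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(observed, null_values,
                               side = c("two_sided", "greater", "less")) {
  side <- match.arg(side)
  check_scalar_number(observed, "observed")
  if (anyNA(null_values)) {
    warn(sprintf("%d missing ensemble values dropped.", sum(is.na(null_values))))
    null_values <- null_values[!is.na(null_values)]
  }
  b <- length(null_values)
  if (b == 0L) abort("empty ensemble.")
  p_greater <- (sum(null_values >= observed) + 1) / (b + 1)
  p_less <- (sum(null_values <= observed) + 1) / (b + 1)
  switch(side,
    greater = p_greater,
    less = p_less,
    two_sided = min(1, 2 * min(p_greater, p_less))
  )
}

#' Test observed network metrics against the G(n, m) null
#'
#' Builds an Erdős–Rényi null ensemble matched to the observed network and
#' reports, per metric, the observed value, the null mean and sd, and
#' permutation p-values for each side. A metric whose null distribution is
#' constant (e.g. edge density, fixed by construction) yields p = 1 with a
#' warning rather than `NaN`.
#'
#' @inheritParams er_null_ensemble
#' @param alpha significance level used to flag metrics, default 0.05.
#' @return An object of class `null_test`: tibble with columns `metric`,
#'   `observed`, `null_mean`, `null_sd`, `p_greater`, `p_less`,
#'   `p_two_sided`, `significant`; the ensemble rides along as an
#'   attribute.
#' @export
null_test <- function(net, B = 1000L, seed,
                      metrics = c("edge_density", "modularity", "centralization"),
                      alpha = 0.05) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  check_scalar_number(alpha, "alpha", 0, 1)
  obs <- replicate_metrics(as_metric_graph(net), metrics)
  ens <- er_null_ensemble(net, B = B, seed = seed, metrics = metrics)

  rows <- purrr::map(metrics, function(met) {
    nulls <- ens$metrics[[met]]
    ok <- !is.na(nulls)
    if (!any(ok)) abort(sprintf("metric '%s' undefined in every null replicate.", met))
    nulls <- nulls[ok]
    if (sd(nulls) == 0) {
      warn(sprintf("null distribution of '%s' is constant; permutation test is uninformative.", met))
    }
    tibble(
      metric = met,
      observed = unname(obs[[met]]),
      null_mean = mean(nulls),
      null_sd = sd(nulls),
      p_greater = permutation_pvalue(obs[[met]], nulls, "greater"),
      p_less = permutation_pvalue(obs[[met]], nulls, "less"),
      p_two_sided = permutation_pvalue(obs[[met]], nulls, "two_sided")
    )
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p_two_sided < alpha
  attr(out, "ensemble") <- ens
  attr(out, "alpha") <- alpha
  class(out) <- c("null_test", class(out))
  out
}

#' Bootstrap ensemble of trait networks
#'
#' Resamples observation rows (sites in CWM mode, species in direct mode)
#' with replacement, same size, and reruns the full pipeline — correlation,
#' thresholding, network assembly, metrics — on every replicate. Replicates
#' in which a metric is undefined (e.g. too few non-constant trait values)
#' record `NA` for it rather than being dropped, so `B` is preserved.
#' Constant-column warnings inside replicates are suppressed (resampling
#' routinely empties rare trait values); the number of affected replicates
#' is recorded in the result.
#'
#' @inheritParams trait_network
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer master seed (required); replicate `b` draws from its
#'   own substream, so increasing `B` extends the ensemble.
#' @param metrics metrics recorded per replicate (see [network_metrics()]).
#' @param replicate_indices optional list of row-index vectors overriding
#'   the resampling (for deterministic replay; each must have `nrow`
#'   entries). `B` is then taken from its length.
#' @return An object of class `bootstrap_ensemble`: list with `metrics`
#'   (tibble, one row per replicate), `B`, `seed`, `n_obs`, `config` (the
#'   pipeline settings) and `n_degenerate` (replicates with dropped nodes).
#' @export
bootstrap_ensemble <- function(observations, B = 1000L, seed,
                               metrics = c("edge_density", "modularity", "centralization"),
                               r_star = 0.2, alpha = 0.05,
                               rule = c("p_and_r", "p_only", "r_only"),
                               signed = c("abs", "positive_only"),
                               within_trait = TRUE, p_adjust = "none",
                               replicate_indices = NULL) {
  m <- as_observation_matrix(observations)
  metrics <- match.arg(metrics, several.ok = TRUE)
  rule <- match.arg(rule)
  signed <- match.arg(signed)
  n <- nrow(m)
  if (n < 3L) abort("bootstrap needs at least 3 observation rows.")
  info <- resolve_trait_info(observations, colnames(m))

  if (!is.null(replicate_indices)) {
    stopifnot(is.list(replicate_indices),
              all(vapply(replicate_indices, length, 0L) == n))
    B <- length(replicate_indices)
  } else {
    B <- check_count(B, "B")
    check_scalar_number(seed, "seed")
  }

# Lean pipeline rerun: correlation -> threshold -> metrics straight from the
  # adjacency matrix; the full annotated trait_network object (tibbles, edge
  # attributes) is only needed for end products, not for ensemble metrics.
  one_replicate <- function(idx) {
    mb <- m[idx, , drop = FALSE]
    rownames(mb) <- paste0("r", seq_len(n))
    attr(mb, "trait_info") <- info
    tryCatch(
      {
        corr <- suppressWarnings(trait_correlation(mb))
        a <- threshold_adjacency(corr, r_star = r_star, alpha = alpha,
                                 rule = rule, signed = signed,
                                 within_trait = within_trait, p_adjust = p_adjust)
        keep <- setdiff(colnames(a), corr$constant)
        a <- a[keep, keep, drop = FALSE]
        nn <- length(keep)
        mm <- sum(a) / 2
        out <- c(n_nodes = as.numeric(nn), n_edges = mm)
        if ("edge_density" %in% metrics) {
          out[["edge_density"]] <- if (nn >= 2L) mm / choose(nn, 2) else NA_real_
        }
        if ("centralization" %in% metrics) {
          out[["centralization"]] <- if (nn >= 3L) {
            d <- rowSums(a)
            sum(max(d) - d) / ((nn - 1) * (nn - 2))
          } else NA_real_
        }
        if ("modularity" %in% metrics) {
          g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                                   diag = FALSE)
          mods <- detect_modules(g)
          out[["modularity"]] <- mods$modularity
          out[["n_modules"]] <- as.numeric(mods$n_modules)
        }
        list(metrics = out, degenerate = length(corr$constant) > 0L)
      },
      error = function(e) list(metrics = NULL, degenerate = TRUE)
    )
  }

  template <- replicate_metrics(igraph::make_empty_graph(0, directed = FALSE), metrics)
  rows <- vector("list", B)
  degen <- logical(B)
  for (b in seq_len(B)) {
    idx <- if (!is.null(replicate_indices)) {
      replicate_indices[[b]]
    } else {
      withr::with_seed(substream_seed(seed, b), sample.int(n, n, replace = TRUE))
    }
    res <- one_replicate(idx)
    degen[b] <- res$degenerate
    rows[[b]] <- res$metrics %||% setNames(rep(NA_real_, length(template)), names(template))
  }
  tab <- as_tibble(do.call(rbind, rows))
  tab <- dplyr::bind_cols(tibble(replicate = seq_len(B)), tab)
  structure(
    list(
      metrics = tab, B = B,
      seed = if (is.null(replicate_indices)) seed else NA_real_,
      n_obs = n, n_degenerate = sum(degen),
      config = list(r_star = r_star, alpha = alpha, rule = rule, signed = signed,
                    within_trait = within_trait, p_adjust = p_adjust,
                    metrics = metrics)
    ),
    class = "bootstrap_ensemble"
  )
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_ensemble> %d replicates of %d observations (seed %s)\n",
    x$B, x$n_obs, format(x$seed)
  ))
  if (x$n_degenerate > 0L) {
    cat(sprintf("  %d replicate(s) dropped zero-variance nodes\n", x$n_degenerate))
  }
  invisible(x)
}

#' @describeIn bootstrap_ensemble Per-replicate bootstrap metric table.
#' @param x a `bootstrap_ensemble`.
#' @param ... unused.
#' @method tidy bootstrap_ensemble
#' @export
tidy.bootstrap_ensemble <- function(x, ...) x$metrics

#' Compare a network metric between two bootstrap ensembles
#'
#' For each requested metric, reports the two groups' medians and
#' interquartile ranges, percentile 95% confidence intervals and whether
#' they overlap, the Welch two-sample t-test, and the Mann-Whitney rank-sum
#' U with its two-sided p. The primary significance call is the bootstrap
#' difference interval: the percentile interval of the replicate-wise
#' difference `a - b`; the difference is significant at level
#' `1 - conf` when 0 falls outside it. (The t and U tests treat bootstrap
#' replicates as independent samples and are strongly anti-conservative
#' for group-level inference, while requiring the two group intervals to
#' separate completely is strongly conservative; the difference interval is
#' the calibrated middle ground. All three are reported.) Ensembles whose
#' values are constant yield p = 1 with a warning rather than an error.
#'
#' @param a,b `bootstrap_ensemble` objects built with identical pipeline
#'   settings (checked; comparison is refused otherwise).
#' @param metrics metrics to compare; default: all shared metric columns.
#' @param conf confidence level, default 0.95.
#' @return An object of class `trait_comparison`: tibble with one row per
#'   metric (medians, IQRs, CIs, overlap flag, difference CI, `significant`,
#'   `t_stat`, `t_p`, `u_stat`, `u_p`, `b_a`, `b_b`).
#' @export
compare_groups <- function(a, b, metrics = NULL, conf = 0.95) {
  stopifnot(inherits(a, "bootstrap_ensemble"), inherits(b, "bootstrap_ensemble"))
  check_scalar_number(conf, "conf", 0, 1)
  cfg_a <- a$config[setdiff(names(a$config), "metrics")]
  cfg_b <- b$config[setdiff(names(b$config), "metrics")]
  if (!identical(cfg_a, cfg_b)) {
    abort("the two ensembles were built with different pipeline settings; comparison would be confounded.")
  }
  shared <- intersect(names(a$metrics), names(b$metrics))
  shared <- setdiff(shared, c("replicate", "n_nodes", "n_edges"))
  if (is.null(metrics)) metrics <- shared
  missing <- setdiff(metrics, shared)
  if (length(missing) > 0L) {
    abort(sprintf("metric(s) not present in both ensembles: %s", paste(missing, collapse = ", ")))
  }
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)

  rows <- purrr::map(metrics, function(met) {
    xa <- a$metrics[[met]]
    xb <- b$metrics[[met]]
    n_miss <- sum(is.na(xa)) + sum(is.na(xb))
    if (n_miss > 0L) {
      warn(sprintf("metric '%s': %d replicate value(s) missing and dropped.", met, n_miss))
    }
    va <- xa[!is.na(xa)]
    vb <- xb[!is.na(xb)]
    if (length(va) == 0L || length(vb) == 0L) {
      abort(sprintf("metric '%s' has no defined values in one ensemble.", met))
    }
    ci_a <- quantile(va, probs, names = FALSE)
    ci_b <- quantile(vb, probs, names = FALSE)
    # replicate-wise difference interval (pairing is arbitrary but valid for
    # independent ensembles); recycling-safe via common length
    k <- min(length(va), length(vb))
    dd <- va[seq_len(k)] - vb[seq_len(k)]
    ci_d <- quantile(dd, probs, names = FALSE)
    constant <- sd(va) == 0 && sd(vb) == 0
    if (constant) {
      warn(sprintf("metric '%s' is constant in both ensembles; tests return p = 1.", met))
    }
    tt <- tryCatch(t.test(va, vb), error = function(e) NULL)
    wt <- tryCatch(suppressWarnings(wilcox.test(va, vb, exact = FALSE)),
                   error = function(e) NULL)
    u_stat <- if (!is.null(wt)) unname(wt$statistic) else length(va) * length(vb) / 2
    u_p <- if (!is.null(wt) && is.finite(wt$p.value)) wt$p.value else 1
    tibble(
      metric = met,
      median_a = median(va), iqr_a = stats::IQR(va),
      median_b = median(vb), iqr_b = stats::IQR(vb),
      ci_lo_a = ci_a[1L], ci_hi_a = ci_a[2L],
      ci_lo_b = ci_b[1L], ci_hi_b = ci_b[2L],
      ci_overlap = ci_a[1L] <= ci_b[2L] && ci_b[1L] <= ci_a[2L],
      diff_ci_lo = ci_d[1L], diff_ci_hi = ci_d[2L],
      significant = !(ci_d[1L] <= 0 && 0 <= ci_d[2L]),
      t_stat = if (!is.null(tt)) unname(tt$statistic) else NA_real_,
      t_p = if (!is.null(tt)) tt$p.value else 1,
      u_stat = u_stat, u_p = u_p,
      b_a = length(va), b_b = length(vb)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "conf") <- conf
  class(out) <- c("trait_comparison", class(out))
  out
}

#' @export
print.trait_comparison <- function(x, ...) {
  conf <- attr(x, "conf", exact = TRUE) %||% 0.95
  cat(sprintf("<trait_comparison> %d metric(s), %.0f%% intervals\n", nrow(x), 100 * conf))
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %s: median %.3f (IQR %.3f) vs %.3f (IQR %.3f); diff CI [%.3f, %.3f]%s; U = %s, p = %.3g\n",
      x$metric[i], x$median_a[i], x$iqr_a[i], x$median_b[i], x$iqr_b[i],
      x$diff_ci_lo[i], x$diff_ci_hi[i],
      if (x$significant[i]) " *" else "",
      format(x$u_stat[i]), x$u_p[i]
    ))
  }
  invisible(x)
}
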
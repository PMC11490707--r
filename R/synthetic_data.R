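#' Define a synthetic community scenario
#'
#' Describes a community whose species belong to latent life-history
#' strategy blocks (e.g. an r-selected and a K-selected strategy). Each
#' block has one signature level per trait; a species adopts its own
#' block's signature with probability `rho_in`, a specific other block's
#' signature with probability `rho_out`, and otherwise a uniformly random
#' level. Trait values planted in the same block therefore co-occur across
#' species, which is the association structure trait networks are meant to
#' recover; `rho_in = rho_out` removes all structure (every signature is
#' equally likely, trait draws become independent). Site biomass follows a
#' log-normal model weighted along an environmental gradient so sites at
#' either extreme are dominated by one strategy.
#'
#' Defaults mirror a tropical-to-temperate reef-fish survey: 183 species
#' scored for 5 categorical traits (maximum length, pelagic larval
#' duration, trophic level, water-column position, reproductive mode with
#' 4/4/6/8/5 levels, 27 trait values) at 20 sites along the gradient. For a
#' fossil-assemblage shape use e.g. `trait_scenario(n_species = 115,
#' traits = c(motility = 4, tiering = 5, feeding = 5, body_size = 4))`
#' (18 trait values).
#'
#' @param n_species number of species.
#' @param n_sites number of survey sites along the gradient.
#' @param traits named integer vector of level counts per categorical
#'   trait, or named list of character level-name vectors.
#' @param n_blocks number of latent strategy blocks (default 2).
#' @param rho_in probability of adopting the own block's signature level.
#' @param rho_out probability of adopting each other block's signature;
#'   must satisfy `rho_out <= rho_in` and
#'   `rho_in + (n_blocks - 1) rho_out <= 1`.
#' @param abundance_meanlog,abundance_sdlog log-normal biomass parameters.
#' @param gradient per-site mixing weight in `[0, 1]` (default evenly
#'   spaced over `[0, 1]`).
#' @return An object of class `trait_scenario` (validated list).
#' @export
trait_scenario <- function(n_species = 183L, n_sites = 20L,
                           traits = c(max_length = 4L, pld = 4L, trophic_level = 6L,
                                      water_column = 8L, reproduction = 5L),
                           n_blocks = 2L, rho_in = 0.7, rho_out = 0.05,
                           abundance_meanlog = 0, abundance_sdlog = 1,
                           gradient = NULL) {
  n_species <- check_count(n_species, "n_species")
  n_sites <- check_count(n_sites, "n_sites", lower = 0L)
  n_blocks <- check_count(n_blocks, "n_blocks")
  check_scalar_number(rho_in, "rho_in", 0, 1)
  check_scalar_number(rho_out, "rho_out", 0, 1)
  if (rho_out > rho_in) abort("`rho_out` must not exceed `rho_in`.")
  if (rho_in + (n_blocks - 1) * rho_out > 1 + 1e-12) {
    abort("rho_in + (n_blocks - 1) * rho_out must not exceed 1.")
  }
  check_scalar_number(abundance_sdlog, "abundance_sdlog", 0)

  if (is.null(names(traits)) || anyDuplicated(names(traits))) {
    abort("`traits` must have unique names.")
  }
  levels <- if (is.list(traits)) {
    lapply(traits, as.character)
  } else {
    lapply(traits, function(k) paste0("v", seq_len(max(0L, as.integer(k)))))
  }
  if (any(vapply(levels, length, 0L) < 2L)) abort("every trait needs at least 2 levels.")
  if (any(vapply(levels, length, 0L) < n_blocks)) {
    abort("every trait needs at least `n_blocks` levels so block signatures are distinct.")
  }
  if (is.null(gradient)) {
    gradient <- if (n_sites > 1L) seq(0, 1, length.out = n_sites) else rep(0.5, n_sites)
  }
  if (length(gradient) != n_sites || any(gradient < 0 | gradient > 1)) {
    abort("`gradient` must give one value in [0, 1] per site.")
  }

  structure(
    list(
      n_species = n_species, n_sites = n_sites, levels = levels,
      n_blocks = n_blocks, rho_in = rho_in, rho_out = rho_out,
      abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
      gradient = gradient
    ),
    class = "trait_scenario"
  )
}

#' @export
print.trait_scenario <- function(x, ...) {
  cat(sprintf(
    "<trait_scenario> %d species, %d sites, %d traits (%d trait values), %d blocks (rho_in %.2f, rho_out %.2f)\n",
    x$n_species, x$n_sites, length(x$levels),
    sum(vapply(x$levels, length, 0L)), x$n_blocks, x$rho_in, x$rho_out
  ))
  invisible(x)
}

# Block signatures: block k's signature for each trait is that trait's k-th
# level. Returns tibble(block, trait, level, column).
scenario_signatures <- function(scenario) {
  purrr::imap_dfr(scenario$levels, function(levs, tr) {
    tibble(
      block = seq_len(scenario$n_blocks),
      trait = tr,
      level = levs[seq_len(scenario$n_blocks)],
      column = paste0(tr, ": ", levs[seq_len(scenario$n_blocks)])
    )
  })
}

# Draw the categorical trait table given latent block membership.
draw_trait_table <- function(scenario, blocks) {
  n <- scenario$n_species
  k <- scenario$n_blocks
  out <- tibble(species = sprintf("sp%03d", seq_len(n)))
  for (tr in names(scenario$levels)) {
    levs <- scenario$levels[[tr]]
    sig <- levs[seq_len(k)]
    u <- runif(n)
    lev <- character(n)
    own <- u < scenario$rho_in
    lev[own] <- sig[blocks[own]]
    hi <- scenario$rho_in + (k - 1) * scenario$rho_out
    other <- !own & u < hi
    if (any(other)) {
      # uniformly one of the other blocks' signatures
      pick <- function(b) {
        pool <- sig[-b]
        pool[sample.int(length(pool), 1L)]
      }
      lev[other] <- vapply(blocks[other], pick, "")
    }
    rest <- !own & !other
    lev[rest] <- levs[sample.int(length(levs), sum(rest), replace = TRUE)]
    out[[tr]] <- lev
  }
  out
}

#' Generate a modern (site-structured) synthetic community
#'
#' Draws species traits from the scenario's latent strategy blocks and
#' log-normal site biomasses weighted along the environmental gradient:
#' block k peaks at gradient position `(k - 1)/(n_blocks - 1)`, with a
#' small floor so every species can occur anywhere. The output feeds
#' [expand_traits()] / [compute_cwm()] directly.
#'
#' @param scenario a [trait_scenario()].
#' @param seed integer seed; identical scenario + seed reproduce the output
#'   exactly.
#' @return A list of class `synthetic_modern`: `community` (site x species
#'   biomass tibble), `traits` (species x trait tibble), `blocks` (tibble:
#'   species, block), `signatures` (tibble: block, trait, level, column)
#'   and `scenario`.
#' @export
generate_modern <- function(scenario, seed) {
  stopifnot(inherits(scenario, "trait_scenario"))
  check_scalar_number(seed, "seed")
  if (scenario$n_sites < 1L) abort("modern scenarios need at least 1 site.")
  withr::with_seed(seed, {
    n <- scenario$n_species
    k <- scenario$n_blocks
    blocks <- rep(seq_len(k), length.out = n)
    traits <- draw_trait_table(scenario, blocks)

    centers <- if (k > 1L) (seq_len(k) - 1) / (k - 1) else 0.5
    # triangular block weight along the gradient, floored so no site loses a
    # strategy entirely
    wmat <- vapply(seq_len(scenario$n_sites), function(j) {
      g <- scenario$gradient[j]
      w <- pmax(0.05, 1 - abs(g - centers[blocks]) * max(1L, k - 1L))
      w * rlnorm(n, scenario$abundance_meanlog, scenario$abundance_sdlog)
    }, numeric(n))
    amat <- t(wmat)
    dimnames(amat) <- list(NULL, traits$species)
    community <- dplyr::bind_cols(
      tibble(site = sprintf("site%02d", seq_len(scenario$n_sites))),
      as_tibble(amat)
    )
    structure(
      list(
        community = community, traits = traits,
        blocks = tibble(species = traits$species, block = blocks),
        signatures = scenario_signatures(scenario),
        scenario = scenario
      ),
      class = "synthetic_modern"
    )
  })
}

#' Generate a fossil-style pre/post extinction assemblage
#'
#' Draws species traits from the scenario's strategy blocks (no site
#' structure: species occurrence lists per time bin). The pre-extinction
#' assemblage contains every species; survival into the post-extinction bin
#' is Bernoulli with probability `base_survival` multiplied by the
#' trait-targeted factors in `extinction` (named by trait-value column,
#' e.g. `c("feeding: v2" = 0)` removes every deposit-feeding analogue,
#' driving that node out of the post network).
#'
#' @param scenario a [trait_scenario()] (sites are ignored; a fossil shape
#'   would be e.g. 115 taxa, 4 traits, 18 trait values).
#' @param extinction named numeric vector of survival multipliers in
#'   `[0, 1]` keyed by trait-value column name; unlisted trait values have
#'   factor 1.
#' @param base_survival baseline survival probability applied to every
#'   species, default 0.6.
#' @param seed integer seed.
#' @return A list of class `synthetic_fossil`: `traits` (full trait
#'   table), `trait_values` (its [expand_traits()] expansion), `pre` and
#'   `post` (species identifier vectors), `survival` (per-species
#'   probability), `blocks`, `signatures`, `scenario`.
#' @export
generate_fossil <- function(scenario, extinction = NULL, base_survival = 0.6, seed) {
  stopifnot(inherits(scenario, "trait_scenario"))
  check_scalar_number(base_survival, "base_survival", 0, 1)
  check_scalar_number(seed, "seed")
  if (!is.null(extinction)) {
    if (is.null(names(extinction)) || any(extinction < 0 | extinction > 1)) {
      abort("`extinction` must be a named vector of probabilities in [0, 1].")
    }
  }
  withr::with_seed(seed, {
    n <- scenario$n_species
    blocks <- rep(seq_len(scenario$n_blocks), length.out = n)
    traits <- draw_trait_table(scenario, blocks)
    tvm <- suppressWarnings(expand_traits(traits))
    x <- as.matrix(tvm[, -1L, drop = FALSE])
    rownames(x) <- tvm$species

    survival <- rep(base_survival, n)
    if (!is.null(extinction)) {
      unknown <- setdiff(names(extinction), colnames(x))
      if (length(unknown) > 0L) {
        abort(sprintf("unknown trait value(s) in `extinction`: %s", paste(unknown, collapse = ", ")))
      }
      for (tv in names(extinction)) {
        survival <- survival * ifelse(x[, tv] == 1, extinction[[tv]], 1)
      }
    }
    survived <- rbinom(n, 1L, survival) == 1L
    structure(
      list(
        traits = traits, trait_values = tvm,
        pre = tvm$species, post = tvm$species[survived],
        survival = setNames(survival, tvm$species),
        blocks = tibble(species = tvm$species, block = blocks),
        signatures = scenario_signatures(scenario),
        scenario = scenario
      ),
      class = "synthetic_fossil"
    )
  })
}

#' Observation matrix for one time bin of a fossil assemblage
#'
#' Restricts the expanded trait-value matrix to the species present in the
#' chosen bin and relabels it for direct (species-as-observations)
#' correlation.
#'
#' @param fossil a [generate_fossil()] result.
#' @param bin `"pre"` or `"post"`.
#' @return A tibble ready for [trait_network()].
#' @export
fossil_observations <- function(fossil, bin = c("pre", "post")) {
  stopifnot(inherits(fossil, "synthetic_fossil"))
  bin <- match.arg(bin)
  keep <- fossil$trait_values$species %in% fossil[[bin]]
  out <- fossil$trait_values[keep, , drop = FALSE]
  attr(out, "trait_info") <- trait_info(fossil$trait_values)
  direct_trait_matrix(out)
}
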
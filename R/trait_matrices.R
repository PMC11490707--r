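#' Expand a categorical trait table to a binary trait-value matrix
#'
#' Each categorical trait is one-hot encoded: one binary column per
#' (trait, level) pair, named `"trait: level"`. Within a trait, a species
#' with data carries exactly one level; a species with a missing value for a
#' trait gets zeros across that trait's columns and is flagged with a
#' warning. Ordinal traits (e.g. body-size classes) are treated as unordered
#' levels, so every level becomes its own network node.
#'
#' @param traits data frame; first column = species identifier, remaining
#'   columns = categorical traits (character or factor), `NA` allowed.
#' @return A tibble with the species column followed by one 0/1 column per
#'   trait value, carrying a `trait_info` attribute (see [trait_info()]).
#' @examples
#' tab <- tibble::tibble(
#'   species = c("sp1", "sp2", "sp3"),
#'   size = c("S", "S", "M")
#' )
#' expand_traits(tab)
#' @export
expand_traits <- function(traits) {
  if (!is.data.frame(traits) || nrow(traits) == 0L) {
    abort("`traits` must be a nonempty data frame.")
  }
  if (ncol(traits) < 2L) abort("`traits` needs a species column plus at least one trait.")
  species <- as.character(traits[[1L]])
  if (anyDuplicated(species)) {
    abort(sprintf(
      "duplicate species identifiers in trait table: %s",
      paste(unique(species[duplicated(species)]), collapse = ", ")
    ))
  }
  trait_names <- names(traits)[-1L]

  blocks <- list()
  info <- list()
  for (tr in trait_names) {
    x <- as.character(traits[[tr]])
    levs <- sort(unique(x[!is.na(x)]))
    if (length(levs) == 0L) {
      warn(sprintf("trait '%s' has no observed levels; skipped.", tr))
      next
    }
    if (length(levs) == 1L) {
      warn(sprintf("trait '%s' has a single level ('%s'); its column is constant.", tr, levs))
    }
    n_missing <- sum(is.na(x))
    if (n_missing > 0L) {
      warn(sprintf("trait '%s': %d species with missing data (all-zero rows).", tr, n_missing))
    }
    cols <- vapply(levs, function(l) as.numeric(!is.na(x) & x == l), numeric(length(x)))
    cols <- matrix(cols, nrow = length(x), dimnames = list(NULL, paste0(tr, ": ", levs)))
    blocks[[tr]] <- cols
    info[[tr]] <- tibble(column = colnames(cols), trait = tr, level = levs)
  }
  if (length(blocks) == 0L) abort("no trait has any observed level.")
  m <- do.call(cbind, blocks)
  out <- tibble(species = species)
  out <- dplyr::bind_cols(out, as_tibble(m))
  attr(out, "trait_info") <- dplyr::bind_rows(info)
  attr(out, "observation_unit") <- "species"
  out
}

validate_community <- function(community, mode = c("auto", "abundance", "presence")) {
  mode <- match.arg(mode)
  if (!is.data.frame(community) || ncol(community) < 2L) {
    abort("`community` must be a data frame: first column site id, then one column per species.")
  }
  sites <- as.character(community[[1L]])
  if (anyDuplicated(sites)) {
    abort(sprintf(
      "duplicate site identifiers: %s",
      paste(unique(sites[duplicated(sites)]), collapse = ", ")
    ))
  }
  w <- as.matrix(community[, -1L, drop = FALSE])
  storage.mode(w) <- "double"
  rownames(w) <- sites
  if (anyDuplicated(colnames(w))) {
    abort(sprintf(
      "duplicate species identifiers: %s",
      paste(unique(colnames(w)[duplicated(colnames(w))]), collapse = ", ")
    ))
  }
  if (anyNA(w)) abort("community matrix contains missing values.")
  if (any(w < 0)) {
    bad <- which(w < 0, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "negative abundance at site '%s', species '%s'.",
      rownames(w)[bad[1L]], colnames(w)[bad[2L]]
    ))
  }
  if (mode == "auto") mode <- if (all(w %in% c(0, 1))) "presence" else "abundance"
  if (mode == "presence" && !all(w %in% c(0, 1))) {
    abort("presence mode requires all values in {0, 1}.")
  }
  empty <- rowSums(w) == 0
  if (any(empty)) {
    abort(sprintf(
      "empty site row(s): %s", paste(rownames(w)[empty], collapse = ", ")
    ))
  }
  list(weights = w, mode = mode)
}

#' Community-weighted means of trait values
#'
#' Combines a site-by-species matrix with a binary species-by-trait-value
#' matrix into a site-by-trait-value matrix of community-weighted means:
#' `CWM(s, t) = sum_i w_si x_it / sum_i w_si`, with weights `w` the
#' abundances (or 0/1 presences, giving the proportion of present species
#' carrying the trait value). For each trait the denominator only sums
#' species with data for that trait, so missing trait data does not deflate
#' the CWMs of the trait's levels. Within a fully observed trait the level
#' columns of each site sum to 1.
#'
#' @param community data frame, first column = site id, remaining columns =
#'   species abundances/biomass (nonnegative) or presences (0/1).
#' @param trait_values binary species-by-trait-value tibble from
#'   [expand_traits()].
#' @param mode `"auto"` detects presence data (all values 0/1); or force
#'   `"abundance"` / `"presence"`.
#' @return Tibble: `site` column plus one CWM column per trait value, values
#'   in `[0, 1]`, carrying `trait_info` and an `observation_unit = "site"`
#'   attribute.
#' @export
compute_cwm <- function(community, trait_values, mode = c("auto", "abundance", "presence")) {
  comm <- validate_community(community, mode)
  w <- comm$weights
  info <- trait_info(trait_values)
  if (is.null(info)) abort("`trait_values` must come from expand_traits() (missing trait_info).")
  tv_species <- as.character(trait_values[[1L]])
  x <- as.matrix(trait_values[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- tv_species

  shared <- intersect(colnames(w), tv_species)
  if (length(shared) == 0L) abort("community and trait table share no species.")
  drop_comm <- setdiff(colnames(w), shared)
  drop_tv <- setdiff(tv_species, shared)
  if (length(drop_comm) > 0L) {
    warn(sprintf(
      "%d species in the community have no trait data and were dropped: %s",
      length(drop_comm), paste(head(drop_comm, 5L), collapse = ", ")
    ))
  }
  if (length(drop_tv) > 0L) {
    warn(sprintf("%d species in the trait table are absent from the community.", length(drop_tv)))
  }
  w <- w[, shared, drop = FALSE]
  x <- x[shared, , drop = FALSE]
  empty <- rowSums(w) == 0
  if (any(empty)) {
    abort(sprintf(
      "site(s) with zero total abundance after dropping untraited species: %s",
      paste(rownames(w)[empty], collapse = ", ")
    ))
  }

  cwm <- matrix(NA_real_, nrow(w), ncol(x), dimnames = list(rownames(w), colnames(x)))
  for (tr in unique(info$trait)) {
    cols <- info$column[info$trait == tr]
    has_data <- rowSums(x[, cols, drop = FALSE]) > 0
    denom <- as.numeric(w %*% has_data)
    num <- w %*% x[, cols, drop = FALSE]
    if (any(denom == 0)) {
      warn(sprintf(
        "trait '%s': no species with data at site(s) %s; CWM set to NA.",
        tr, paste(rownames(w)[denom == 0], collapse = ", ")
      ))
      denom[denom == 0] <- NA_real_
    }
    cwm[, cols] <- sweep(num, 1L, denom, "/")
  }
  out <- dplyr::bind_cols(tibble(site = rownames(w)), as_tibble(cwm))
  attr(out, "trait_info") <- info
  attr(out, "observation_unit") <- "site"
  attr(out, "mode") <- comm$mode
  out
}

#' Use the species-by-trait-value matrix directly as observations
#'
#' When no site or transect structure exists (typically fossil occurrence
#' data), the correlation step treats species themselves as the
#' observations. This relabels the binary trait-value matrix accordingly;
#' the values are untouched.
#'
#' @param trait_values tibble from [expand_traits()], optionally restricted
#'   to an assemblage (e.g. the survivors of an extinction interval).
#' @return The same tibble with `observation_unit = "species"`, ready for
#'   [trait_network()].
#' @export
direct_trait_matrix <- function(trait_values) {
  if (!is.data.frame(trait_values) || nrow(trait_values) == 0L) {
    abort("`trait_values` must be a nonempty data frame.")
  }
  if (nrow(trait_values) < 3L) {
    warn("fewer than 3 species: downstream correlation will be undefined.")
  }
  out <- as_tibble(trait_values)
  attr(out, "trait_info") <- trait_info(trait_values) %||%
    infer_trait_info(names(out)[-1L])
  attr(out, "observation_unit") <- "species"
  out
}
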
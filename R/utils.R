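# Internal helpers shared across modules.

# Deterministic per-replicate substream: replicate b of a seeded ensemble gets
# its own seed derived from the master seed, so growing B never reshuffles
# earlier replicates. 48271 is the classic Lehmer multiplier; modulus 2^31 - 1.
substream_seed <- function(seed, b) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + b * 48271) %% 2147483647)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) abort(sprintf("`%s` must be an integer.", name))
  invisible(as.integer(x))
}

# Coerce a data frame whose first column is an observation identifier (or a
# plain numeric matrix) into a numeric matrix with rownames.
as_observation_matrix <- function(observations) {
  if (is.matrix(observations)) {
    storage.mode(observations) <- "double"
    if (is.null(rownames(observations))) {
      rownames(observations) <- paste0("obs", seq_len(nrow(observations)))
    }
    return(observations)
  }
  if (!is.data.frame(observations)) {
    abort("`observations` must be a data frame (id column first) or a numeric matrix.")
  }
  if (ncol(observations) < 2L) {
    abort("`observations` needs an id column plus at least one trait-value column.")
  }
  ids <- as.character(observations[[1L]])
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicate observation identifiers: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  m <- as.matrix(observations[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Trait-value annotation of a matrix-like object
#'
#' Expanded trait matrices, community-weighted mean matrices and trait
#' networks carry a small tibble mapping each trait-value column (network
#' node) to its parent trait and level. `trait_info()` retrieves it.
#'
#' @param x an object produced by [expand_traits()], [compute_cwm()],
#'   [direct_trait_matrix()] or [trait_network()].
#' @return A tibble with columns `column`, `trait`, `level`, or `NULL` when
#'   the object carries no annotation.
#' @export
trait_info <- function(x) {
  info <- attr(x, "trait_info", exact = TRUE)
  if (is.null(info) && is.list(x) && !is.data.frame(x)) info <- x$trait_info
  info
}

# Fall back to parsing "trait: level" column names when no annotation rides
# along (e.g. a CWM table read back from CSV).
infer_trait_info <- function(columns) {
  has_sep <- grepl(": ", columns, fixed = TRUE)
  tibble(
    column = columns,
    trait = ifelse(has_sep, sub(": .*$", "", columns), NA_character_),
    level = ifelse(has_sep, sub("^[^:]*: ", "", columns), columns)
  )
}

resolve_trait_info <- function(x, columns) {
  info <- trait_info(x)
  if (is.null(info)) info <- infer_trait_info(columns)
  info[match(columns, info$column), , drop = FALSE]
}
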
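#' Read a site-by-species matrix from CSV
#'
#' First column = site identifier, remaining columns = species, cells =
#' nonnegative abundance/biomass or 0/1 presence. Duplicate site or species
#' identifiers, negative values and empty site rows are rejected.
#'
#' @param path CSV file (UTF-8).
#' @param mode `"auto"`, `"abundance"` or `"presence"`.
#' @param delim field delimiter, default `","`.
#' @return Tibble, first column `site`.
#' @export
read_site_species <- function(path, mode = c("auto", "abundance", "presence"), delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           comment = "#", progress = FALSE,
                           name_repair = "minimal")
  names(raw)[1L] <- "site"
  validate_community(raw, mode)  # errors with a named diagnostic
  raw
}

#' Read a species-by-trait table from CSV
#'
#' First column = species identifier, remaining columns = categorical
#' traits; empty cells become missing values. Duplicate species identifiers
#' are rejected.
#'
#' @inheritParams read_site_species
#' @return Tibble, first column `species`, trait columns as character.
#' @export
read_trait_table <- function(path, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           comment = "#", progress = FALSE, name_repair = "minimal",
                           col_types = readr::cols(.default = readr::col_character()))
  names(raw)[1L] <- "species"
  sp <- raw$species
  if (anyDuplicated(sp)) {
    abort(sprintf(
      "duplicate species identifiers in trait table: %s",
      paste(unique(sp[duplicated(sp)]), collapse = ", ")
    ))
  }
  raw
}

#' Write a community-weighted mean matrix to CSV
#'
#' Rows are observations (sites, or species in direct mode), columns are
#' trait values named `"trait: level"`; a comment header records the
#' orientation.
#'
#' @param cwm tibble from [compute_cwm()] or [direct_trait_matrix()].
#' @param path output CSV path.
#' @export
write_cwm <- function(cwm, path) {
  unit <- attr(cwm, "observation_unit", exact = TRUE) %||% "site"
  header <- sprintf("# rows: %ss; columns: trait values (trait: level)", unit)
  writeLines(header, path)
  readr::write_csv(cwm, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Export a trait network to standard graph formats
#'
#' Writes GraphML (`<name>.graphml`), a weighted tab-separated edge list
#' (`<name>_edges.tsv`: node_a, node_b, r, p) and a node table CSV
#' (`<name>_nodes.csv`: trait value, parent trait, degree).
#'
#' @param net a [trait_network()].
#' @param dir output directory (created if absent).
#' @param name file stem, default `"trait_network"`.
#' @return Invisibly, the named vector of files written.
#' @export
export_network <- function(net, dir, name = "trait_network") {
  stopifnot(inherits(net, "trait_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    graphml = file.path(dir, paste0(name, ".graphml")),
    edges = file.path(dir, paste0(name, "_edges.tsv")),
    nodes = file.path(dir, paste0(name, "_nodes.csv"))
  )
  igraph::write_graph(net$graph, paths[["graphml"]], format = "graphml")
  readr::write_tsv(net$edges[, c("from", "to", "r", "p")], paths[["edges"]])
  nodes <- net$nodes
  nodes$degree <- igraph::degree(net$graph)[nodes$node]
  readr::write_csv(nodes, paths[["nodes"]])
  invisible(paths)
}
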
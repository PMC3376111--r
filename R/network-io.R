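#' Gene interaction network
#'
#' Builds an undirected, simple (no self-loops, no duplicate edges)
#' [igraph][igraph::graph_from_data_frame] graph over gene symbols with an
#' `edge_type` attribute. Edge types follow the interaction-database
#' convention: `pp` (protein-protein), `pd` (protein-DNA), `pr`
#' (protein-RNA) or `unknown`. Edge type is carried for reporting only;
#' layering and hub scoring ignore it. Directed input is symmetrized.
#'
#' @param edges data.frame (or matrix) with columns `from`, `to` and
#'   optionally `edge_type`.
#' @param nodes optional character vector of node names, to include
#'   isolated nodes beyond those in `edges`.
#' @return an igraph object of class `igraph`, undirected, with vertex
#'   `name` and edge `edge_type` attributes.
#' @export
interaction_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    if (!is.null(nodes)) g <- igraph::add_vertices(g, length(nodes), name = as.character(nodes))
    return(g)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  from <- as.character(edges[[1]]); to <- as.character(edges[[2]])
  if (any(!nzchar(from)) || any(!nzchar(to)))
    stop_config("empty node symbol in edge list")
  et <- if (ncol(edges) >= 3) as.character(edges[[3]]) else rep("unknown", length(from))
  et[!et %in% c("pp", "pd", "pr")] <- "unknown"
  self <- from == to
  loop_nodes <- character()
  if (any(self)) {
    loop_nodes <- unique(from[self])
    warning(sprintf("dropping %d self-loop(s): %s", sum(self),
                    paste(loop_nodes, collapse = ", ")), call. = FALSE)
    from <- from[!self]; to <- to[!self]; et <- et[!self]
  }
  # unordered pair identity: keep first occurrence
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  df <- data.frame(from = from[keep], to = to[keep], edge_type = et[keep],
                   stringsAsFactors = FALSE)
  verts <- unique(c(df$from, df$to, loop_nodes,
                    as.character(nodes %||% character())))
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = verts))
}

#' Read a gene interaction network from SIF or a 3-column edge list
#'
#' SIF lines are `nodeA relation nodeB` (whitespace-separated); TSV edge
#' lists are `geneA<TAB>geneB<TAB>edge_type` with an optional header line
#' `from  to  edge_type`. Unknown relation tokens are accepted and mapped
#' to edge type `unknown`; self-loops are dropped with a warning; reversed
#' duplicates collapse to a single undirected edge.
#'
#' @param path input file.
#' @param format `"auto"` (by extension: `.sif` vs anything else),
#'   `"sif"`, or `"tsv"`.
#' @return an [interaction_network()] igraph object.
#' @export
read_network <- function(path, format = c("auto", "sif", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config("network file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(interaction_network(NULL))
  if (format == "sif") {
    parts <- strsplit(trimws(lines), "[ \t]+")
    # SIF permits isolated nodes as single-token lines
    singles <- vapply(parts, length, 0L) == 1L
    iso <- unlist(parts[singles])
    parts <- parts[!singles]
    bad <- which(vapply(parts, length, 0L) != 3L)
    if (length(bad))
      stop_config("malformed SIF line (need 'node relation node'): line %d", bad[1])
    m <- do.call(rbind, parts)
    edges <- data.frame(from = m[, 1], to = m[, 3], edge_type = m[, 2],
                        stringsAsFactors = FALSE)
    return(interaction_network(edges, nodes = iso))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(parts[[1]][1:2]), c("from", "to"))) parts <- parts[-1]
  n <- vapply(parts, length, 0L)
  if (any(n < 2))
    stop_config("malformed edge-list line %d: need at least two columns", which(n < 2)[1])
  edges <- data.frame(
    from = vapply(parts, `[`, "", 1),
    to = vapply(parts, `[`, "", 2),
    edge_type = vapply(parts, function(p) if (length(p) >= 3) p[3] else "unknown", ""),
    stringsAsFactors = FALSE)
  interaction_network(edges)
}

network_edge_df <- function(g) {
  if (igraph::ecount(g) == 0)
    return(data.frame(from = character(), to = character(),
                      edge_type = character(), stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(g)
  et <- igraph::edge_attr(g, "edge_type") %||% rep("unknown", nrow(el))
  df <- data.frame(from = el[, 1], to = el[, 2], edge_type = et,
                   stringsAsFactors = FALSE)
  for (attr in setdiff(igraph::edge_attr_names(g), "edge_type"))
    df[[attr]] <- igraph::edge_attr(g, attr)
  df
}

#' Write an interaction or layered network to SIF, GraphML or JSON
#'
#' SIF output round-trips through [read_network()] to the identical edge
#' set. GraphML and JSON exports carry node attributes (layer
#' memberships, per-timepoint signed fold changes, DMNC where present on
#' the graph) and the `edge_type` edge attribute; for a
#' [build_layered_network()] result the integrated graph is written with
#' a `layers` attribute listing each node's layer labels.
#'
#' @param network an igraph object or a `LayeredNetwork`.
#' @param path output file.
#' @param format one of `"sif"`, `"graphml"`, `"json"`.
#' @return invisibly, `path`.
#' @export
write_network <- function(network, path, format = c("sif", "graphml", "json")) {
  format <- match.arg(format)
  if (inherits(network, "LayeredNetwork")) {
    g <- network$integrated
  } else {
    g <- network
  }
  stopifnot(inherits(g, "igraph"))
  if (format == "sif") {
    df <- network_edge_df(g)
    lines <- sprintf("%s\t%s\t%s", df$from, df$edge_type, df$to)
    iso <- setdiff(igraph::V(g)$name %||% character(), c(df$from, df$to))
    writeLines(c(lines, iso), path)
  } else if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    nodes <- data.frame(id = igraph::V(g)$name %||% character(),
                        stringsAsFactors = FALSE)
    for (attr in igraph::vertex_attr_names(g)) {
      if (attr != "name") nodes[[attr]] <- igraph::vertex_attr(g, attr)
    }
    obj <- list(nodes = nodes, edges = network_edge_df(g))
    jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
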
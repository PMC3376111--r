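#' Build a layered interaction network by backpropagation in time
#'
#' Starting from the differentially expressed (DE) genes at the final
#' timepoint (layer 1), each earlier layer holds the genes that are DE at
#' that timepoint *and* interact (any network edge) with at least one
#' gene already placed in the layer below. The construction connects the
#' end-stage transcriptional state back to its earliest upstream
#' effectors. A gene may appear in multiple layers; a gene is never its
#' own upstream partner (an edge to a different gene in the next layer
#' is required, which the no-self-loop network invariant guarantees).
#' Empty layers are permitted: once a layer is empty every earlier layer
#' is empty too.
#'
#' @param de_sets named list `timepoint -> character vector` of DE genes
#'   (e.g. `lapply(select_de_genes(det)[[ct]], \(x) x$all)`).
#' @param network an [interaction_network()] igraph object.
#' @param timepoint_order character vector of timepoints, earliest
#'   first; must cover `names(de_sets)`.
#' @param cell_type optional label stored on the result.
#' @return A `LayeredNetwork` list: `layers` (named by timepoint, final
#'   timepoint first), `cross_edges` (data.frame of network edges between
#'   consecutive layers), `integrated` (induced igraph subgraph on the
#'   union of layers, see [build_integrated_network()]), `cell_type`,
#'   `timepoint_order`.
#' @export
build_layered_network <- function(de_sets, network, timepoint_order,
                                  cell_type = NA_character_) {
  stopifnot(inherits(network, "igraph"))
  unknown <- setdiff(names(de_sets), timepoint_order)
  if (length(unknown))
    stop_config("unknown timepoint label(s): %s", paste(unknown, collapse = ", "))
  tps <- rev(timepoint_order)  # final timepoint first
  node_names <- igraph::V(network)$name %||% character()
  layers <- stats::setNames(vector("list", length(tps)), tps)
  layers[[tps[1]]] <- sort(unique(as.character(de_sets[[tps[1]]] %||% character())))
  cross <- list()
  for (k in seq_along(tps)[-1]) {
    below <- layers[[tps[k - 1]]]
    cand <- unique(as.character(de_sets[[tps[k]]] %||% character()))
    if (!length(below) || !length(cand)) {
      layers[[tps[k]]] <- character()
      next
    }
    below_in <- intersect(below, node_names)
    cand_in <- intersect(cand, node_names)
    keep <- character()
    if (length(below_in) && length(cand_in)) {
      nb <- igraph::adjacent_vertices(network, below_in)
      partners <- unique(unlist(lapply(nb, function(v) v$name)))
      keep <- intersect(cand_in, partners)
    }
    layers[[tps[k]]] <- sort(keep)
    if (length(keep)) {
      sub <- igraph::induced_subgraph(network, union(keep, below_in))
      df <- network_edge_df(sub)
      df <- df[(df$from %in% keep & df$to %in% below_in) |
                 (df$to %in% keep & df$from %in% below_in), , drop = FALSE]
      if (nrow(df)) {
        df$from_layer <- ifelse(df$from %in% keep, tps[k], tps[k - 1])
        df$to_layer <- ifelse(df$from_layer == tps[k], tps[k - 1], tps[k])
        cross[[tps[k]]] <- df
      }
    }
  }
  cross_edges <- if (length(cross)) do.call(rbind, cross) else
    data.frame(from = character(), to = character(), edge_type = character(),
               from_layer = character(), to_layer = character(),
               stringsAsFactors = FALSE)
  rownames(cross_edges) <- NULL
  ln <- structure(list(layers = layers, cross_edges = cross_edges,
                       integrated = NULL, cell_type = cell_type,
                       timepoint_order = timepoint_order),
                  class = "LayeredNetwork")
  ln$integrated <- build_integrated_network(ln, network)
  ln
}

#' @export
print.LayeredNetwork <- function(x, ...) {
  cat(sprintf("LayeredNetwork (%s): %d layers\n",
              x$cell_type %||% "?", length(x$layers)))
  for (tp in names(x$layers))
    cat(sprintf("  %-4s : %d genes\n", tp, length(x$layers[[tp]])))
  if (inherits(x$integrated, "igraph"))
    cat(sprintf("  integrated: %d nodes, %d edges\n",
                igraph::vcount(x$integrated), igraph::ecount(x$integrated)))
  invisible(x)
}

#' Integrated subgraph of a layered network
#'
#' The induced subgraph of the interaction network on the union of all
#' layer genes, including intra-layer edges. Genes placed in a layer but
#' absent from the interaction network (possible only for the base
#' layer, which is not connectivity-filtered) are kept as isolated nodes
#' with a warning. Each node carries a `layers` attribute
#' (comma-separated timepoint labels) and a `cross_layer` flag marks
#' edges between consecutive layers.
#'
#' @param layered a `LayeredNetwork` (the `integrated` element may be
#'   unset).
#' @param network the [interaction_network()] the layers were built from.
#' @return an igraph object.
#' @export
build_integrated_network <- function(layered, network) {
  stopifnot(inherits(layered, "LayeredNetwork"), inherits(network, "igraph"))
  all_genes <- unique(unlist(layered$layers))
  node_names <- igraph::V(network)$name %||% character()
  missing <- setdiff(all_genes, node_names)
  if (length(missing))
    warning(sprintf("%d layer gene(s) absent from the interaction network kept as isolated nodes: %s",
                    length(missing), paste(utils::head(missing, 5), collapse = ", ")),
            call. = FALSE)
  g <- igraph::induced_subgraph(network, intersect(all_genes, node_names))
  if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  if (igraph::vcount(g)) {
    memb <- vapply(igraph::V(g)$name, function(nm) {
      paste(names(layered$layers)[vapply(layered$layers, function(l) nm %in% l, TRUE)],
            collapse = ",")
    }, "")
    g <- igraph::set_vertex_attr(g, "layers", value = unname(memb))
  }
  if (igraph::ecount(g)) {
    ce <- layered$cross_edges
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    el <- igraph::as_edgelist(g)
    is_cross <- key(el[, 1], el[, 2]) %in% key(ce$from, ce$to)
    g <- igraph::set_edge_attr(g, "cross_layer", value = is_cross)
  }
  g
}

#' Dominance rule for pathway selection
#'
#' @param coverage_threshold minimum fraction of the integrated
#'   network's genes a pathway must contain to qualify (inclusive);
#'   default 0.10.
#' @param alpha enrichment significance threshold (strict `<`); default
#'   0.01.
#' @param adjust multiple-testing method for the enrichment p-values.
#' @return a `DominanceConfig` list.
#' @export
dominance_config <- function(coverage_threshold = 0.10, alpha = 0.01,
                             adjust = c("BH", "Holm")) {
  adjust <- match.arg(adjust)
  if (coverage_threshold <= 0 || coverage_threshold > 1)
    stop_config("coverage_threshold must lie in (0, 1]")
  structure(list(coverage_threshold = coverage_threshold, alpha = alpha,
                 adjust = adjust),
            class = "DominanceConfig")
}

#' Select dominant pathways of a layered network
#'
#' A pathway is dominant when it covers at least the configured fraction
#' (default 10%) of the integrated network's genes *and* is significantly
#' enriched in those genes relative to the universe (one-sided
#' hypergeometric test, adjusted p below `alpha`). Output is filtered to
#' the dominant sets and sorted by coverage descending.
#'
#' @param layered a [build_layered_network()] result (or any object with
#'   a `layers` list).
#' @param collection a [gene_set_collection()].
#' @param universe character vector of all measured genes.
#' @param config a [dominance_config()].
#' @return data.frame of dominant pathways: `set_name`, `coverage`,
#'   `n_covered`, `n_network`, `p_raw`, `p_adj`; attribute
#'   `"all_pathways"` holds the unfiltered table with a `dominant` flag.
#' @export
select_dominant_pathways <- function(layered, collection, universe,
                                     config = dominance_config()) {
  U <- unique(unlist(layered$layers))
  if (!length(U))
    return(structure(data.frame(set_name = character(), coverage = numeric(),
                                n_covered = integer(), n_network = integer(),
                                p_raw = numeric(), p_adj = numeric(),
                                stringsAsFactors = FALSE),
                     all_pathways = NULL))
  U_u <- intersect(U, universe)
  enr <- enrich_gene_sets(U_u, universe, collection, adjust = config$adjust,
                          alpha = config$alpha)
  cov <- vapply(enr$set_name, function(nm)
    length(intersect(collection$sets[[nm]], U)) / length(U), 0)
  tab <- data.frame(set_name = enr$set_name,
                    coverage = unname(cov),
                    n_covered = vapply(enr$set_name, function(nm)
                      length(intersect(collection$sets[[nm]], U)), 0L),
                    n_network = length(U),
                    p_raw = enr$p_raw, p_adj = enr$p_adj,
                    stringsAsFactors = FALSE)
  tab$dominant <- tab$coverage >= config$coverage_threshold &
    tab$p_adj < config$alpha
  out <- tab[tab$dominant, setdiff(names(tab), "dominant"), drop = FALSE]
  out <- out[order(-out$coverage, out$p_adj, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_pathways") <- tab
  out
}

#' Per-layer gene-set enrichment of a layered network
#'
#' Runs [enrich_gene_sets()] independently on each layer's gene set,
#' resolving the time-specific pathway activity the layered construction
#' exposes. Empty layers yield empty reports, not errors.
#'
#' @inheritParams select_dominant_pathways
#' @param adjust,alpha enrichment parameters (see [enrich_gene_sets()]).
#' @param up,down optional direction annotations passed through.
#' @return named list (by timepoint, final first) of enrichment tables.
#' @export
layerwise_enrichment <- function(layered, collection, universe,
                                 adjust = "BH", alpha = 0.01,
                                 up = NULL, down = NULL) {
  lapply(layered$layers, function(genes) {
    genes <- intersect(genes, universe)
    if (!length(genes)) {
      return(data.frame(set_name = character(), n_universe = integer(),
                        n_query = integer(), n_set = integer(),
                        n_overlap = integer(), ratio = numeric(),
                        p_raw = numeric(), p_adj = numeric(),
                        significant = logical(), frac_up = numeric(),
                        frac_down = numeric(), frac_unmodified = numeric(),
                        stringsAsFactors = FALSE))
    }
    enrich_gene_sets(genes, universe, collection, adjust = adjust,
                     alpha = alpha, up = up, down = down)
  })
}
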
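#' MNC and DMNC score of one gene
#'
#' The maximum neighborhood component (MNC) of a node v is the largest
#' connected component of the subgraph induced by v's open neighborhood
#' (v itself excluded). Its density score is
#' `DMNC = |E(MNC)| / |V(MNC)|^epsilon` with `epsilon = 1.7` by default.
#' High DMNC marks genes whose interaction partners are themselves
#' densely interconnected — "focus hubs" whose removal destabilizes the
#' network. Component ties are broken by node count, then edge count,
#' then the lexicographically smallest member. Isolated nodes and nodes
#' whose neighborhood has no edges score 0.
#'
#' @param network an [interaction_network()] igraph object.
#' @param gene gene symbol; must be a network node.
#' @param epsilon density exponent (default 1.7).
#' @return a one-row data.frame (`HubScore`): `gene`, `degree`,
#'   `mnc_size`, `mnc_edges`, `dmnc`; attribute `"mnc_members"` holds
#'   the MNC node set.
#' @export
mnc_dmnc <- function(network, gene, epsilon = 1.7) {
  stopifnot(inherits(network, "igraph"))
  if (!gene %in% (igraph::V(network)$name %||% character()))
    stop_config("gene '%s' is not a network node", gene)
  nb <- igraph::neighbors(network, gene)$name
  nb <- setdiff(unique(nb), gene)
  deg <- igraph::degree(network, gene)
  if (!length(nb)) {
    out <- data.frame(gene = gene, degree = unname(deg), mnc_size = 0L,
                      mnc_edges = 0L, dmnc = 0, stringsAsFactors = FALSE)
    attr(out, "mnc_members") <- character()
    return(out)
  }
  sub <- igraph::induced_subgraph(network, nb)
  comp <- igraph::components(sub)
  sizes <- comp$csize
  # an edge's endpoints share a component, so edge counts come from a
  # single tabulation of endpoint memberships
  ends <- igraph::as_edgelist(sub, names = FALSE)
  edges_of <- tabulate(comp$membership[ends[, 1]], nbins = comp$no)
  sub_names <- igraph::V(sub)$name
  min_member <- vapply(split(sub_names, comp$membership), min, "")
  ord <- order(-sizes, -edges_of, min_member)
  best <- ord[1]
  size <- sizes[best]; ne <- edges_of[best]
  dmnc <- if (size <= 1) 0 else ne / size^epsilon
  out <- data.frame(gene = gene, degree = unname(deg),
                    mnc_size = as.integer(size), mnc_edges = as.integer(ne),
                    dmnc = dmnc, stringsAsFactors = FALSE)
  attr(out, "mnc_members") <- igraph::V(sub)$name[comp$membership == best]
  out
}

#' Rank all genes of a network by DMNC
#'
#' Scores every node with [mnc_dmnc()] and sorts by `dmnc` descending,
#' ties broken by `mnc_size` descending, then `degree` descending, then
#' gene symbol ascending, yielding unique ranks 1..n. `top_k` beyond the
#' node count is clamped.
#'
#' @param network an [interaction_network()] igraph object (non-empty).
#' @param epsilon density exponent (default 1.7).
#' @param top_k number of top hubs to return (default `Inf` = all).
#' @return data.frame of `HubScore` rows with a `rank` column, sorted by
#'   rank.
#' @export
rank_hubs <- function(network, epsilon = 1.7, top_k = Inf) {
  stopifnot(inherits(network, "igraph"))
  nodes <- igraph::V(network)$name %||% character()
  if (!length(nodes)) stop_config("cannot rank hubs of an empty network")
  rows <- lapply(nodes, function(g) mnc_dmnc(network, g, epsilon = epsilon))
  tab <- do.call(rbind, rows)
  ord <- order(-tab$dmnc, -tab$mnc_size, -tab$degree, tab$gene)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  utils::head(tab, n = min(top_k, nrow(tab)))
}

#' Cross-cell-type signature network of focus hubs
#'
#' Identifies the K most interactive focus hubs common to two cell
#' types' integrated networks. Candidates are the genes present in both
#' networks; each candidate's combined score is the sum of its two
#' per-network DMNC ranks (lower is better), ties broken by summed DMNC
#' descending then symbol. The signature carries each hub's per-network
#' DMNC statistics, per-timepoint signed fold changes from the DE
#' tables, and the induced subgraph over the hubs and their first
#' neighbors within each integrated network.
#'
#' @param ranks_a,ranks_b full [rank_hubs()] tables for the two cell
#'   types (all nodes ranked, not just a top slice).
#' @param network_a,network_b the integrated igraph networks the
#'   rankings were computed on.
#' @param K number of signature hubs (default 10).
#' @param de_tables optional [de_table()] data.frame (both cell types)
#'   used to attach fold-change profiles.
#' @param cell_types labels for the two cell types (for annotation).
#' @return A `SignatureNetwork` list: `hubs` (data.frame with per-network
#'   ranks/DMNC and combined score), `fold_changes` (data.frame gene x
#'   cell_type x timepoint signed fold changes, if `de_tables` given),
#'   `subgraph_a`, `subgraph_b` (hub + first-neighbor induced
#'   subgraphs). Empty candidate set yields zero hubs with a warning.
#' @export
signature_network <- function(ranks_a, ranks_b, network_a, network_b,
                              K = 10, de_tables = NULL,
                              cell_types = c("A", "B")) {
  common <- intersect(ranks_a$gene, ranks_b$gene)
  if (!length(common)) {
    warning("no genes common to both networks; empty signature", call. = FALSE)
    return(structure(list(hubs = data.frame(), fold_changes = NULL,
                          subgraph_a = NULL, subgraph_b = NULL,
                          cell_types = cell_types),
                     class = "SignatureNetwork"))
  }
  ia <- match(common, ranks_a$gene); ib <- match(common, ranks_b$gene)
  hubs <- data.frame(
    gene = common,
    rank_a = ranks_a$rank[ia], rank_b = ranks_b$rank[ib],
    dmnc_a = ranks_a$dmnc[ia], dmnc_b = ranks_b$dmnc[ib],
    combined_rank = ranks_a$rank[ia] + ranks_b$rank[ib],
    combined_dmnc = ranks_a$dmnc[ia] + ranks_b$dmnc[ib],
    stringsAsFactors = FALSE)
  hubs <- hubs[order(hubs$combined_rank, -hubs$combined_dmnc, hubs$gene), ]
  hubs <- utils::head(hubs, n = min(K, nrow(hubs)))
  hubs$signature_rank <- seq_len(nrow(hubs))
  rownames(hubs) <- NULL
  first_neighbors <- function(g, genes) {
    present <- intersect(genes, igraph::V(g)$name %||% character())
    if (!length(present)) return(NULL)
    nb <- unique(c(present, unlist(lapply(
      igraph::adjacent_vertices(g, present), function(v) v$name))))
    igraph::induced_subgraph(g, nb)
  }
  fc <- NULL
  if (!is.null(de_tables)) {
    fc <- de_tables[de_tables$gene %in% hubs$gene,
                    c("gene", "cell_type", "timepoint", "signed_fc", "p_adj"),
                    drop = FALSE]
    rownames(fc) <- NULL
  }
  structure(list(hubs = hubs, fold_changes = fc,
                 subgraph_a = first_neighbors(network_a, hubs$gene),
                 subgraph_b = first_neighbors(network_b, hubs$gene),
                 cell_types = cell_types),
            class = "SignatureNetwork")
}

#' @export
print.SignatureNetwork <- function(x, ...) {
  cat(sprintf("SignatureNetwork: %d hubs common to %s and %s\n",
              nrow(x$hubs), x$cell_types[1], x$cell_types[2]))
  if (nrow(x$hubs)) print(x$hubs[, c("gene", "rank_a", "rank_b",
                                     "combined_rank", "signature_rank")])
  invisible(x)
}
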
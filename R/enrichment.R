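#' Gene-set over-representation analysis
#'
#' One-sided Fisher / hypergeometric test of each gene set against a
#' query gene list. With universe size `N`, set size (within the
#' universe) `K`, query size `n` and overlap `x`, the raw p-value is the
#' upper hypergeometric tail `P(X >= x)`. Sets are first intersected
#' with the universe; sets with empty intersection are skipped with a
#' warning. Rows are sorted by adjusted p, ties broken by the affected
#' ratio (`x / K`) descending.
#'
#' @param query character vector of genes of interest; must be a subset
#'   of `universe`.
#' @param universe character vector: all genes eligible for selection
#'   (the measured genes, not the whole genome).
#' @param collection a [gene_set_collection()].
#' @param adjust multiple-testing method, `"BH"` (pathway-style preset)
#'   or `"Holm"` (GO-style preset).
#' @param alpha significance threshold recorded in the output flag.
#' @param up,down optional character vectors of up-/down-regulated genes
#'   used to annotate each set's directionality (fractions of the set's
#'   universe members that are up, down or unmodified).
#' @return data.frame with one row per tested set: `set_name`,
#'   `n_universe`, `n_query`, `n_set`, `n_overlap`, `ratio`, `p_raw`,
#'   `p_adj`, `significant`, `frac_up`, `frac_down`, `frac_unmodified`.
#' @export
enrich_gene_sets <- function(query, universe, collection,
                             adjust = c("BH", "Holm"), alpha = 0.01,
                             up = NULL, down = NULL) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(collection, "GeneSetCollection"))
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!length(query) || !length(universe))
    stop_config("query and universe must be non-empty")
  extra <- setdiff(query, universe)
  if (length(extra))
    stop_config("query genes outside the universe: %s",
                paste(utils::head(extra, 5), collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- list()
  for (nm in names(collection$sets)) {
    set_u <- intersect(collection$sets[[nm]], universe)
    K <- length(set_u)
    if (K == 0) {
      warning(sprintf("set '%s' has no genes in the universe; skipped", nm),
              call. = FALSE)
      next
    }
    ov <- intersect(set_u, query)
    x <- length(ov)
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    dirn <- directionality_summary(set_u, up = up, down = down)
    rows[[nm]] <- data.frame(
      set_name = nm, n_universe = N, n_query = n, n_set = K, n_overlap = x,
      ratio = x / K, p_raw = p,
      frac_up = dirn["frac_up"], frac_down = dirn["frac_down"],
      frac_unmodified = dirn["frac_unmodified"],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(set_name = character(), n_universe = integer(),
                      n_query = integer(), n_set = integer(),
                      n_overlap = integer(), ratio = numeric(),
                      p_raw = numeric(), p_adj = numeric(),
                      significant = logical(), frac_up = numeric(),
                      frac_down = numeric(), frac_unmodified = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- adjust_pvalues(out$p_raw, adjust)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_adj, -out$ratio, out$set_name), ]
  rownames(out) <- NULL
  out[, c("set_name", "n_universe", "n_query", "n_set", "n_overlap", "ratio",
          "p_raw", "p_adj", "significant", "frac_up", "frac_down",
          "frac_unmodified")]
}

#' Up/down/unmodified fractions of a gene set
#'
#' Fractions are computed over the supplied set members (normally the
#' set already intersected with the analysis universe): a gene counts as
#' up if it appears in `up`, down if in `down`, otherwise unmodified.
#' With no members all fractions are 0 (degenerate-input flag).
#'
#' @param members character vector of set members in the universe.
#' @param up,down character vectors of up-/down-regulated genes (may be
#'   `NULL`, meaning none).
#' @return named numeric vector `frac_up`, `frac_down`,
#'   `frac_unmodified` (summing to 1 when `members` is non-empty).
#' @export
directionality_summary <- function(members, up = NULL, down = NULL) {
  m <- length(members)
  if (m == 0)
    return(c(frac_up = 0, frac_down = 0, frac_unmodified = 0))
  n_up <- sum(members %in% (up %||% character()))
  n_down <- sum(members %in% (down %||% character()))
  c(frac_up = n_up / m, frac_down = n_down / m,
    frac_unmodified = (m - n_up - n_down) / m)
}
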
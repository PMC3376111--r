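# Independent reference implementations used as oracles. These are kept
# deliberately naive (flood fill, explicit sums, hand-rolled step-up /
# step-down) and separate from the package's code paths.

# --- graphs ----------------------------------------------------------------

# symmetric logical adjacency matrix with node names
random_adj <- function(n, p, names = sprintf("N%02d", seq_len(n))) {
  a <- matrix(FALSE, n, n, dimnames = list(names, names))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) a[i, j] <- a[j, i] <- TRUE
  }
  a
}

adj_to_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# brute-force DMNC: enumerate the open neighborhood, find components by
# flood fill, pick by size, then edge count, then smallest member name
oracle_dmnc <- function(adj, v, epsilon = 1.7) {
  nms <- rownames(adj)
  nb <- nms[adj[v, ]]
  nb <- setdiff(nb, v)
  if (!length(nb)) return(list(size = 0L, edges = 0L, dmnc = 0))
  sub <- adj[nb, nb, drop = FALSE]
  unvisited <- nb
  comps <- list()
  while (length(unvisited)) {
    queue <- unvisited[1]; comp <- character()
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      if (x %in% comp) next
      comp <- c(comp, x)
      queue <- c(queue, setdiff(nb[sub[x, ]], comp))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    unvisited <- setdiff(unvisited, comp)
  }
  n_edges <- vapply(comps, function(cc)
    sum(sub[cc, cc, drop = FALSE]) / 2, 0)
  sizes <- vapply(comps, length, 0L)
  mins <- vapply(comps, min, "")
  best <- order(-sizes, -n_edges, mins)[1]
  size <- sizes[best]; ne <- n_edges[best]
  list(size = size, edges = as.integer(ne),
       dmnc = if (size <= 1) 0 else ne / size^epsilon,
       members = comps[[best]])
}

# all labeled graphs on n nodes, as adjacency matrices
all_labeled_graphs <- function(n, names = LETTERS[seq_len(n)]) {
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  lapply(seq_len(2^m) - 1L, function(code) {
    bits <- as.logical(bitwAnd(rep(code, m), 2^(seq_len(m) - 1L)))
    a <- matrix(FALSE, n, n, dimnames = list(names, names))
    for (k in which(bits)) {
      i <- pairs[1, k]; j <- pairs[2, k]
      a[i, j] <- a[j, i] <- TRUE
    }
    a
  })
}

# one representative adjacency matrix per isomorphism class of connected
# graphs on n nodes (canonical-form deduplication via BLISS)
connected_class_representatives <- function(n, names = LETTERS[seq_len(n)]) {
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  seen <- new.env(hash = TRUE)
  reps <- list()
  for (code in seq_len(2^m) - 1L) {
    bits <- bitwAnd(rep(code, m), 2^(seq_len(m) - 1L)) > 0
    if (sum(bits) < n - 1) next
    el <- pairs[, bits, drop = FALSE]
    g <- igraph::make_graph(as.vector(el), n = n, directed = FALSE)
    if (!igraph::is_connected(g)) next
    cp <- igraph::canonical_permutation(g)$labeling
    key <- paste(as.vector(igraph::as_adjacency_matrix(
      igraph::permute(g, cp), sparse = FALSE)), collapse = "")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    a <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
    dimnames(a) <- list(names, names)
    reps[[length(reps) + 1L]] <- a
  }
  reps
}

# --- statistics ------------------------------------------------------------

# explicit hypergeometric upper tail P(X >= x) via binomial coefficients
oracle_hyper_tail <- function(N, K, n, x) {
  js <- max(0, x):min(K, n)
  if (x <= max(0, n - (N - K))) return(1)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# hand step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m); out[o] <- adj
  out
}

# hand step-down Holm
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, (m - seq_len(m) + 1) * ps)
  adj <- cummax(adj)
  out <- numeric(m); out[o] <- adj
  out
}

# sort-based quantile normalization with averaged-rank tie handling
oracle_qn <- function(X) {
  ref <- rowMeans(apply(X, 2, sort))
  out <- apply(X, 2, function(col) {
    r <- rank(col, ties.method = "average")
    vapply(r, function(ri) mean(ref[c(floor(ri), ceiling(ri))]), 0)
  })
  dimnames(out) <- dimnames(X)
  out
}

# exhaustive complete-linkage agglomeration: returns merge heights and
# the partition (canonical string) after each merge
oracle_complete_linkage <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(rownames(d))
  heights <- numeric(); partitions <- character()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in (i + 1):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
    partitions <- c(partitions, paste(sort(vapply(clusters, function(x)
      paste(x, collapse = "+"), "")), collapse = " | "))
  }
  list(heights = heights, partitions = partitions)
}

# adjusted Rand index from the standard pair-counting formula
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# brute-force layered construction by direct set comprehension
oracle_layers <- function(de_sets, adj, timepoint_order) {
  tps <- rev(timepoint_order)
  nms <- rownames(adj)
  layers <- list()
  layers[[tps[1]]] <- sort(unique(de_sets[[tps[1]]]))
  for (k in seq_along(tps)[-1]) {
    below <- layers[[tps[k - 1]]]
    cand <- unique(de_sets[[tps[k]]])
    keep <- character()
    for (g in cand) {
      if (!g %in% nms) next
      partners <- setdiff(intersect(below, nms), g)
      if (length(partners) && any(adj[g, partners])) keep <- c(keep, g)
    }
    layers[[tps[k]]] <- sort(keep)
  }
  layers
}
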
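test_that("DMNC handles degenerate neighborhoods: isolated nodes and stars", {
  g <- interaction_network(data.frame(from = c("h", "h", "h"),
                                      to = c("a", "b", "c")),
                           nodes = "iso")
  iso <- mnc_dmnc(g, "iso")
  expect_equal(iso$mnc_size, 0L)
  expect_equal(iso$dmnc, 0)
  # star center: neighborhood is edgeless, components are singletons
  h <- mnc_dmnc(g, "h")
  expect_equal(h$mnc_size, 1L)
  expect_equal(h$mnc_edges, 0L)
  expect_equal(h$dmnc, 0)
  expect_error(mnc_dmnc(g, "nope"), "nope")
})

test_that("DMNC matches hand-computed values on the path and clique cases", {
  # v adjacent to {a,b,c}; a-b, b-c: MNC is the 3-path with 2 edges
  g <- interaction_network(data.frame(
    from = c("v", "v", "v", "a", "b"), to = c("a", "b", "c", "b", "c")))
  sc <- mnc_dmnc(g, "v")
  expect_equal(sc$mnc_size, 3L)
  expect_equal(sc$mnc_edges, 2L)
  expect_equal(sc$dmnc, 2 / 3^1.7, tolerance = 1e-12)
  expect_setequal(attr(sc, "mnc_members"), c("a", "b", "c"))
  # K4: every node sees a triangle
  k4 <- adj_to_graph(random_adj(4, 1.1, names = c("w", "x", "y", "z")))
  for (v in c("w", "x", "y", "z"))
    expect_equal(mnc_dmnc(k4, v)$dmnc, 3 / 3^1.7, tolerance = 1e-12)
})

test_that("DMNC equals the brute-force flood-fill oracle on labeled graphs", {
  # exhaustive over all labeled 4-node graphs
  for (adj in all_labeled_graphs(4)) {
    g <- adj_to_graph(adj)
    for (v in rownames(adj)) {
      sc <- mnc_dmnc(g, v)
      orc <- oracle_dmnc(adj, v)
      expect_equal(sc$dmnc, orc$dmnc, tolerance = 1e-12)
      expect_equal(sc$mnc_size, orc$size)
    }
  }
  # random graphs up to 30 nodes
  set.seed(90)
  for (i in 1:30) {
    n <- sample(5:30, 1)
    adj <- random_adj(n, runif(1, 0.05, 0.5))
    g <- adj_to_graph(adj)
    for (v in sample(rownames(adj), 3)) {
      expect_equal(mnc_dmnc(g, v)$dmnc, oracle_dmnc(adj, v)$dmnc,
                   tolerance = 1e-12)
    }
  }
})

test_that("DMNC is invariant under node relabeling", {
  set.seed(91)
  adj <- random_adj(12, 0.3)
  g <- adj_to_graph(adj)
  base <- vapply(rownames(adj), function(v) mnc_dmnc(g, v)$dmnc, 0)
  for (i in 1:10) {
    perm <- sample(rownames(adj))
    adj2 <- adj[perm, perm]
    rownames(adj2) <- colnames(adj2) <- sprintf("R%02d", seq_along(perm))
    g2 <- adj_to_graph(adj2)
    for (j in seq_along(perm)) {
      expect_equal(mnc_dmnc(g2, sprintf("R%02d", j))$dmnc,
                   unname(base[perm[j]]), tolerance = 1e-12)
    }
  }
})

test_that("hub ranking uses the documented tie-break cascade", {
  # 4-cycle: all DMNC 0, order purely lexicographic among equal degrees
  cyc <- interaction_network(data.frame(from = c("d", "a", "b", "c"),
                                        to = c("a", "b", "c", "d")))
  r <- rank_hubs(cyc)
  expect_identical(r$gene, c("a", "b", "c", "d"))
  expect_true(all(r$dmnc == 0))
  expect_identical(r$rank, 1:4)
  # top_k beyond the node count returns the full ranking
  expect_equal(nrow(rank_hubs(cyc, top_k = 99)), 4)
  expect_error(rank_hubs(interaction_network(NULL)), "empty")
})

test_that("a planted dense-neighborhood hub ranks first in a sparse background", {
  set.seed(92)
  # sparse ring of 30 nodes + hub with a 6-neighbor clique
  ring <- data.frame(from = sprintf("b%02d", 1:30),
                     to = sprintf("b%02d", c(2:30, 1)))
  clique <- t(combn(c("hub", sprintf("c%d", 1:6)), 2))
  # pendant edges give the hub the degree edge over its clique partners,
  # whose DMNC ties with it by symmetry
  pend <- data.frame(from = "hub", to = c("b01", "b05", "b09"))
  g <- interaction_network(rbind(ring,
                                 data.frame(from = clique[, 1], to = clique[, 2]),
                                 pend))
  r <- rank_hubs(g)
  expect_identical(r$gene[1], "hub")
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  brute <- vapply(igraph::V(g)$name, function(v) oracle_dmnc(adj, v)$dmnc, 0)
  expect_equal(unname(brute["hub"]), max(brute), tolerance = 1e-12)
})

test_that("signature ranking follows the hand rank-sum example", {
  mk <- function(genes, dmnc) {
    g <- interaction_network(data.frame(from = genes,
                                        to = c(genes[-1], genes[1])))
    data.frame(gene = genes, degree = 2, mnc_size = 1, mnc_edges = 0,
               dmnc = dmnc, rank = seq_along(genes), stringsAsFactors = FALSE)
  }
  net <- interaction_network(data.frame(from = c("A", "B"), to = c("B", "C")))
  ra <- mk(c("A", "B", "C"), c(0.9, 0.8, 0.7))
  rb <- mk(c("B", "C", "A"), c(0.9, 0.8, 0.7))
  sig <- signature_network(ra, rb, net, net, K = 2)
  # combined ranks: B = 3, A = 4, C = 5
  expect_identical(sig$hubs$gene, c("B", "A"))
  expect_identical(sig$hubs$combined_rank, c(3L, 4L))
  expect_identical(sig$hubs$signature_rank, 1:2)

  # identical rankings: signature is the shared top K
  sig2 <- signature_network(ra, ra, net, net, K = 2)
  expect_identical(sig2$hubs$gene, c("A", "B"))

  # disjoint node sets: empty signature with a warning
  rc <- mk(c("X", "Y", "Z"), c(0.5, 0.4, 0.3))
  expect_warning(sig3 <- signature_network(ra, rc, net, net, K = 2),
                 "empty signature")
  expect_equal(nrow(sig3$hubs), 0)
})

test_that("signature subgraphs contain the hubs and their first neighbors", {
  # de_fraction large enough that the hub modules can be wired through
  # DE genes (and hence survive into the DE-only integrated networks)
  cfg <- test_sim_config(seed = 77, de_fraction = 0.2)
  out <- generate_expression(cfg)
  gn <- generate_interaction_network(cfg, out$truth)
  det <- de_table(out$em)
  de_sets <- select_de_genes(det)
  lns <- lapply(c(EC = "EC", SMC = "SMC"), function(ct)
    build_layered_network(lapply(de_sets[[ct]], `[[`, "all"), gn$network,
                          out$em$timepoints, cell_type = ct))
  ranks <- lapply(lns, function(ln) rank_hubs(ln$integrated))
  sig <- signature_network(ranks$EC, ranks$SMC, lns$EC$integrated,
                           lns$SMC$integrated, K = 10, de_tables = det,
                           cell_types = c("EC", "SMC"))
  expect_lte(nrow(sig$hubs), 10)
  expect_true(all(sig$hubs$gene %in% igraph::V(lns$EC$integrated)$name))
  expect_true(all(sig$hubs$gene %in% igraph::V(lns$SMC$integrated)$name))
  expect_true(all(sig$hubs$gene %in% igraph::V(sig$subgraph_a)$name))
  expect_true(all(sig$fold_changes$gene %in% sig$hubs$gene))
  # planted hubs appear in the signature
  expect_true(all(gn$truth$hub_genes %in% sig$hubs$gene))
})
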
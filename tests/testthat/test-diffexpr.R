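make_fit <- function(n = 3, seed = 1, ng = 50, delta = 0) {
  set.seed(seed)
  ctrl <- matrix(rnorm(ng * n), ng, n, dimnames = list(sprintf("g%d", 1:ng), NULL))
  graft <- matrix(rnorm(ng * n, mean = delta), ng, n,
                  dimnames = list(sprintf("g%d", 1:ng), NULL))
  fit_timepoint_contrasts(two_group_em(ctrl, graft), "EC", "12H")
}

test_that("two-group contrast matches the hand-computed pooled t", {
  ctrl <- matrix(c(1, 2, 3), 1, dimnames = list("g1", NULL))
  graft <- matrix(c(3, 4, 5), 1, dimnames = list("g1", NULL))
  fit <- fit_timepoint_contrasts(two_group_em(ctrl, graft), "EC", "12H")
  expect_equal(fit$log2fc, 2)
  expect_equal(fit$signed_fc, 4)
  expect_equal(fit$s2, 1)
  expect_equal(fit$df, 4)
  expect_equal(fit$t_ordinary, 2 / sqrt(2 / 3), tolerance = 1e-12)
  # identical groups: null gene
  fit0 <- fit_timepoint_contrasts(two_group_em(ctrl, ctrl), "EC", "12H")
  expect_equal(fit0$log2fc, 0)
  expect_equal(fit0$signed_fc, 1)
  expect_equal(fit0$t_ordinary, 0)
})

test_that("signed fold change follows the negative-reciprocal display convention", {
  expect_equal(signed_fc(2), 4)
  expect_equal(signed_fc(0), 1)
  expect_equal(round(signed_fc(-1.07), 2), -2.10)
  x <- seq(-3, 3, by = 0.25)
  expect_equal(sign(signed_fc(x)), ifelse(x == 0, 1, sign(x)))
  expect_equal(abs(signed_fc(x)), 2^abs(x), tolerance = 1e-12)
})

test_that("contrast errors on missing replication and supports pairing", {
  ctrl <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), NULL))
  graft <- matrix(rnorm(2), 2, 1, dimnames = list(c("g1", "g2"), NULL))
  expect_error(fit_timepoint_contrasts(two_group_em(ctrl, graft), "EC", "12H"),
               ">=2 replicates")
  graft4 <- ctrl + 1
  fitp <- fit_timepoint_contrasts(two_group_em(ctrl, graft4), "EC", "12H",
                                  paired = TRUE)
  # constant within-animal shift: zero paired variance, log2fc preserved
  expect_equal(fitp$log2fc, c(1, 1))
  expect_equal(fitp$s2, c(0, 0))
  expect_equal(fitp$df[1], 3)
})

test_that("moderation limits: d0 = 0 gives the ordinary t, equal variances leave t unchanged", {
  fit <- make_fit(seed = 11, ng = 1000)
  mod0 <- ebayes_moderate(fit, params = list(d0 = 0, s0_sq = 1))
  expect_lt(max(abs(mod0$t_moderated - fit$t_ordinary)), 1e-10)
  expect_equal(mod0$df_total[1], fit$df[1])

  # all genes share the same sample variance: shrinkage is a no-op
  ctrl <- matrix(rep(c(-1, 0, 1), each = 1), 1)[rep(1, 20), ]
  rownames(ctrl) <- sprintf("g%d", 1:20)
  graft <- ctrl + rep(seq(0, 2, length.out = 20), 3)
  dimnames(graft) <- dimnames(ctrl)
  f2 <- fit_timepoint_contrasts(two_group_em(ctrl, graft), "EC", "12H")
  expect_equal(length(unique(round(f2$s2, 12))), 1)
  m2 <- ebayes_moderate(f2)
  expect_equal(m2$t_moderated, f2$t_ordinary, tolerance = 1e-8)
  p <- attr(m2, "ebayes_params")
  expect_identical(p$d0, Inf)
})

test_that("posterior variance is a convex combination of prior and sample variance", {
  fit <- make_fit(seed = 3, ng = 200)
  mod <- ebayes_moderate(fit, params = list(d0 = 4, s0_sq = 0.7))
  lo <- pmin(fit$s2, 0.7); hi <- pmax(fit$s2, 0.7)
  expect_true(all(mod$s2_post >= lo - 1e-12 & mod$s2_post <= hi + 1e-12))
  # two-sided p consistent with the t reference distribution
  expect_equal(mod$p_raw, 2 * pt(-abs(mod$t_moderated), df = mod$df_total),
               tolerance = 1e-12)
})

test_that("prior df recovery: moment matching lands near the simulated d0", {
  ok <- 0
  for (s in 1:20) {
    set.seed(s)
    v <- 4 / rchisq(200, df = 4)          # true variances: d0 = 4, s0 = 1
    s2 <- v * rchisq(200, df = 4) / 4     # observed pooled variances, d_g = 4
    est <- graftnet:::estimate_ebayes_params(s2, 4)
    if (est$d0 >= 2 && est$d0 <= 8) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("BH and Holm match hand oracles on the worked examples and permutations", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.04), "Holm"), c(0.02, 0.04))
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(0.03, "Holm"), 0.03)
  base <- c(0.01, 0.02, 0.03, 0.04)
  perms <- list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3), c(3, 1, 4, 2))
  for (pm in perms) {
    p <- base[pm]
    expect_equal(adjust_pvalues(p, "BH"), oracle_bh(p), tolerance = 1e-12)
    expect_equal(adjust_pvalues(p, "Holm"), oracle_holm(p), tolerance = 1e-12)
  }
  expect_error(adjust_pvalues(c(0.5, 1.2), "BH"), "\\[0, 1\\]")
})

test_that("adjustment equals the oracle on exhaustive short grids and is monotone", {
  grid <- c(0.001, 0.02, 0.2, 1)
  for (len in 1:4) {
    idx <- expand.grid(rep(list(seq_along(grid)), len))
    for (r in seq_len(nrow(idx))) {
      p <- grid[as.integer(idx[r, ])]
      expect_equal(adjust_pvalues(p, "BH"), oracle_bh(p), tolerance = 1e-12)
      expect_equal(adjust_pvalues(p, "Holm"), oracle_holm(p), tolerance = 1e-12)
    }
  }
  # monotone in the order statistics
  for (s in 1:20) {
    p <- with_seed_test(s, runif(15))
    for (m in c("BH", "Holm")) {
      adj <- adjust_pvalues(p, m)
      expect_true(all(diff(adj[order(p)]) >= -1e-12))
      expect_true(all(adj >= p - 1e-12))
    }
  }
})

test_that("DE selection applies inclusive fold-change and adjusted-p boundaries", {
  det <- data.frame(
    gene = c("a", "b", "c", "d"),
    cell_type = "EC", timepoint = "12H",
    signed_fc = c(2.0, 1.9, -3.0, 5.0),
    p_adj = c(0.05, 0.0001, 0.01, 0.2))
  sets <- select_de_genes(det, threshold_config())
  expect_identical(sets$EC$`12H`$up, "a")     # both boundaries inclusive
  expect_identical(sets$EC$`12H`$down, "c")   # sign routes to the down set
  expect_false("b" %in% sets$EC$`12H`$all)    # fold-change fail
  expect_false("d" %in% sets$EC$`12H`$all)    # significance fail
})

test_that("DE table satisfies its internal invariants on simulated data", {
  out <- generate_expression(test_sim_config(seed = 13))
  det <- de_table(out$em)
  expect_equal(sign(det$signed_fc), ifelse(det$log2fc == 0, 1, sign(det$log2fc)))
  expect_equal(abs(det$signed_fc), 2^abs(det$log2fc), tolerance = 1e-12)
  expect_true(all(det$p_adj >= det$p_raw - 1e-15))
  thr <- threshold_config()
  expect_identical(det$is_de,
                   abs(det$signed_fc) >= thr$fc_threshold & det$p_adj <= thr$alpha_de)
  expect_equal(nrow(det), 300 * 2 * 5)
})

test_that("moderated F reduces to the squared moderated t for a single timepoint", {
  set.seed(21)
  ctrl <- matrix(rnorm(150), 50, 3, dimnames = list(sprintf("g%d", 1:50), NULL))
  graft <- matrix(rnorm(150, 0.3), 50, 3, dimnames = list(sprintf("g%d", 1:50), NULL))
  em <- two_group_em(ctrl, graft)
  tc <- timecourse_moderated_F(em, "EC")
  fit <- ebayes_moderate(fit_timepoint_contrasts(em, "EC", "12H"))
  expect_equal(tc$stats$F_moderated, fit$t_moderated^2, tolerance = 1e-10)
  expect_equal(tc$stats$p_raw, fit$p_raw, tolerance = 1e-10)
})

test_that("null genes give F = 0 and are never selected", {
  set.seed(5)
  cfg <- test_sim_config(de_fraction = 0, noise_sd = 0.3)
  out <- generate_expression(cfg)
  em <- out$em
  # force one exactly-null flat gene
  tc <- timecourse_moderated_F(em, "EC")
  flat <- which.min(tc$stats$F_moderated)
  expect_gte(tc$stats$F_moderated[flat], 0)
  em$values[1, ] <- 5
  em$values[2, ] <- rnorm(ncol(em$values))  # keep ensemble variance positive
  # fitFDist warns about the single zero-variance gene and offsets it
  tc2 <- suppressWarnings(timecourse_moderated_F(em, "EC"))
  expect_equal(tc2$stats$F_moderated[1], 0)
  expect_false(tc2$stats$selected[1])
})

test_that("time-course selection recovers a gene active at 3 of 5 timepoints", {
  hits <- 0
  for (s in 1:20) {
    cfg <- sim_config(n_genes = 150, de_fraction = 1 / 150, planted_fc = 4,
                      archetypes = "late_rise", noise_sd = 0.25, seed = 100 + s,
                      set_size_range = c(5, 10))
    out <- generate_expression(cfg)
    # widen activity: late_rise covers 2 of 5; add the middle timepoint
    g <- out$truth$de_genes$gene
    em <- out$em
    act <- em$samples$timepoint == "24H" & em$samples$condition == "graft" &
      em$samples$cell_type == "EC"
    em$values[g, act] <- em$values[g, act] + 2
    tc <- timecourse_moderated_F(em, "EC")
    if (g %in% tc$selected) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("overlap reports exclusive sets and all three candidate ratios", {
  de_sets <- list(
    EC = list(`12H` = list(up = c("A", "B", "C"), down = character(),
                           all = c("A", "B", "C"))),
    SMC = list(`12H` = list(up = c("B", "C", "D"), down = character(),
                            all = c("B", "C", "D"))))
  ov <- overlap_sets(de_sets, "12H")
  expect_setequal(ov$members$up$intersection, c("B", "C"))
  expect_identical(ov$members$up$a_only, "A")
  expect_identical(ov$members$up$b_only, "D")
  s <- ov$summary[ov$summary$category == "up", ]
  expect_equal(s$ratio_union, 0.5)
  expect_equal(s$ratio_a, 2 / 3)
  expect_equal(s$ratio_b, 2 / 3)
  # disjoint and identical boundary cases
  dj <- list(EC = list(t = list(up = "A", down = character(), all = "A")),
             SMC = list(t = list(up = "B", down = character(), all = "B")))
  expect_true(all(overlap_sets(dj, "t")$summary[, c("ratio_union", "ratio_a", "ratio_b")][1, ] == 0))
  id <- list(EC = list(t = list(up = c("A", "B"), down = character(), all = c("A", "B"))),
             SMC = list(t = list(up = c("A", "B"), down = character(), all = c("A", "B"))))
  expect_true(all(overlap_sets(id, "t")$summary[1, c("ratio_union", "ratio_a", "ratio_b")] == 1))
})

test_that("K-means recovers separable archetypes and honours degenerate k", {
  profs <- rbind(matrix(rep(c(2, 0, 0), 10), 10, 3, byrow = TRUE),
                 matrix(rep(c(0, 0, 2), 10), 10, 3, byrow = TRUE))
  rownames(profs) <- sprintf("g%d", 1:20)
  cl <- kmeans_temporal(profs, 2)
  expect_equal(cl$tot_withinss, 0, tolerance = 1e-12)
  expect_length(unique(cl$labels[1:10]), 1)
  expect_length(unique(cl$labels[11:20]), 1)
  expect_false(cl$labels[1] == cl$labels[11])

  cl1 <- kmeans_temporal(profs, 1)
  expect_equal(unname(cl1$centers[1, ]), colMeans(cl1$profiles_z), tolerance = 1e-12)
  expect_error(kmeans_temporal(profs, 21), "exceeds")
  # deterministic under a fixed seed
  expect_identical(kmeans_temporal(profs, 2, seed = 5)$labels,
                   kmeans_temporal(profs, 2, seed = 5)$labels)
})

test_that("K-means recovers planted temporal archetypes by adjusted Rand", {
  ok <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    arch <- list(c(3, 0, 0, 0, 0), c(0, 3, 3, 0, 0), c(0, 0, 0, 3, 3))
    profs <- do.call(rbind, lapply(1:3, function(a)
      matrix(rep(arch[[a]], 20), 20, 5, byrow = TRUE) + rnorm(100, 0, 0.1)))
    rownames(profs) <- sprintf("g%d", 1:60)
    truth_lab <- rep(1:3, each = 20)
    cl <- kmeans_temporal(profs, 3, seed = s)
    if (oracle_ari(truth_lab, cl$labels) >= 0.9) ok <- ok + 1
  }
  expect_gte(ok, 18)
})
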
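# Fixture builders shared across test files. All fixtures are generated
# in code; nothing is read from disk.

# ExpressionMatrix for a single cell type / timepoint two-group design:
# `ctrl` and `graft` are gene x replicate matrices (same rownames).
two_group_em <- function(ctrl, graft, cell_type = "EC", timepoint = "12H") {
  n_c <- ncol(ctrl); n_g <- ncol(graft)
  vals <- cbind(ctrl, graft)
  colnames(vals) <- c(sprintf("C%d", seq_len(n_c)), sprintf("G%d", seq_len(n_g)))
  meta <- data.frame(
    sample = colnames(vals),
    cell_type = cell_type,
    condition = rep(c("control", "graft"), c(n_c, n_g)),
    timepoint = timepoint,
    animal = c(sprintf("A%d", seq_len(n_c)), sprintf("A%d", seq_len(n_g))),
    stringsAsFactors = FALSE)
  expression_matrix(vals, meta, timepoints = timepoint)
}

# arbitrary ExpressionMatrix from a bare matrix; metadata is filled with
# placeholder single-group labels (QC tests only need the values)
bare_em <- function(vals, timepoint = "2H") {
  if (is.null(rownames(vals))) rownames(vals) <- sprintf("g%d", seq_len(nrow(vals)))
  if (is.null(colnames(vals))) colnames(vals) <- sprintf("s%d", seq_len(ncol(vals)))
  meta <- data.frame(sample = colnames(vals), cell_type = "EC",
                     condition = "control", timepoint = timepoint,
                     animal = colnames(vals), stringsAsFactors = FALSE)
  expression_matrix(vals, meta, timepoints = timepoint)
}

# the 3-timepoint hand-traced layered-network toy
toy_layered_fixture <- function() {
  de_sets <- list(`30D` = c("A", "B"), `7D` = c("C", "D", "E"),
                  `24H` = c("F", "G"))
  net <- interaction_network(data.frame(
    from = c("C", "D", "F", "G"),
    to = c("A", "B", "C", "E"),
    edge_type = "pp", stringsAsFactors = FALSE))
  list(de_sets = de_sets, network = net,
       timepoint_order = c("24H", "7D", "30D"))
}

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

# small, fast simulation config for tests
test_sim_config <- function(...) {
  defaults <- list(n_genes = 300, network_n = 150, n_gene_sets = 6,
                   set_size_range = c(10, 30), seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
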
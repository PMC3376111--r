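#' Configuration of the synthetic study generator
#'
#' Describes a two-cell-type, five-timepoint graft-vs-control design
#' with three biological replicates per group — the layout of a
#' paired-vessel injury time course — plus the parameters of the planted
#' signal: which fraction of genes is differentially expressed, at what
#' fold change, along which temporal archetype, with how much log2-scale
#' Gaussian noise; and the parameters of the planted interaction network
#' and gene-set collection.
#'
#' Temporal archetypes (activity masks over the ordered timepoints):
#' `early_spike` (first timepoint only), `mid_peak` (middle timepoints),
#' `late_rise` (last two timepoints), `sustained_down` (all timepoints,
#' down-regulated). Planted genes cycle through the archetypes in order.
#'
#' @param n_genes number of genes (default 1000).
#' @param n_replicates biological replicates (animals) per cell type /
#'   condition / timepoint (default 3).
#' @param timepoints ordered timepoint labels, earliest first.
#' @param cell_types cell-type labels (default EC, SMC).
#' @param de_fraction fraction of genes planted as DE (default 0.05).
#' @param planted_fc linear-scale fold change of planted genes (>= 1,
#'   default 4).
#' @param archetypes archetype names to cycle through.
#' @param noise_sd SD of Gaussian noise on the log2 scale (default 0.25).
#' @param baseline_mean,baseline_sd log2-scale parameters of the
#'   per-gene baseline (linear-scale log-normal), defaults 8 and 2.
#' @param network_n,network_m scale-free generator size and edges per
#'   added node (defaults 400, 2).
#' @param n_planted_hubs number of dense-neighborhood hubs planted in
#'   the network (default 2).
#' @param hub_neighborhood clique size wired around each planted hub
#'   (default 8).
#' @param n_gene_sets,set_size_range gene-set collection parameters
#'   (defaults 12 sets of 15-60 genes).
#' @param seed master RNG seed; every generator output is a pure
#'   function of (config, seed).
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(n_genes = 1000, n_replicates = 3,
                       timepoints = c("2H", "12H", "24H", "7D", "30D"),
                       cell_types = c("EC", "SMC"),
                       de_fraction = 0.05, planted_fc = 4,
                       archetypes = c("early_spike", "mid_peak",
                                      "late_rise", "sustained_down"),
                       noise_sd = 0.25,
                       baseline_mean = 8, baseline_sd = 2,
                       network_n = 400, network_m = 2,
                       n_planted_hubs = 2, hub_neighborhood = 8,
                       n_gene_sets = 12, set_size_range = c(15, 60),
                       seed = 1) {
  if (n_genes < 1 || n_replicates < 1 || network_n < 1 || network_m < 1 ||
      n_gene_sets < 1)
    stop_config("all counts must be positive")
  if (de_fraction < 0 || de_fraction > 1)
    stop_config("de_fraction must lie in [0, 1]")
  if (planted_fc < 1) stop_config("planted_fc must be >= 1")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (anyDuplicated(timepoints))
    stop_config("timepoints must be strictly ordered (distinct labels)")
  known <- c("early_spike", "mid_peak", "late_rise", "sustained_down", "null")
  bad <- setdiff(archetypes, known)
  if (length(bad)) stop_config("unknown archetypes: %s", paste(bad, collapse = ", "))
  if (length(set_size_range) != 2 || set_size_range[1] > set_size_range[2])
    stop_config("set_size_range must be c(min, max)")
  if (set_size_range[2] > n_genes)
    stop_config("set_size_range exceeds n_genes")
  structure(list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    timepoints = timepoints, cell_types = cell_types,
    de_fraction = de_fraction, planted_fc = planted_fc,
    archetypes = archetypes, noise_sd = noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    network_n = as.integer(network_n), network_m = as.integer(network_m),
    n_planted_hubs = as.integer(n_planted_hubs),
    hub_neighborhood = as.integer(hub_neighborhood),
    n_gene_sets = as.integer(n_gene_sets),
    set_size_range = as.integer(set_size_range),
    seed = as.integer(seed)
  ), class = "SimulationConfig")
}

# Activity mask (logical over the ordered timepoints) and direction of
# one archetype.
archetype_profile <- function(archetype, timepoints) {
  T <- length(timepoints)
  idx <- switch(archetype,
    early_spike = 1L,
    mid_peak = if (T <= 2) T else
      intersect(c(floor((T + 2) / 2) - 1L, floor((T + 2) / 2)), 2:(T - 1)),
    late_rise = unique(pmax(1L, c(T - 1L, T))),
    sustained_down = seq_len(T),
    null = integer()
  )
  mask <- rep(FALSE, T)
  mask[idx] <- TRUE
  list(mask = mask, direction = if (archetype == "sustained_down") -1 else 1)
}

#' Generate a synthetic expression cohort with planted truth
#'
#' Simulates log2 expression for every (cell type, condition, timepoint,
#' replicate) sample. Each gene has a log-normal baseline (normal on the
#' log2 scale); control samples are noisy draws around it; graft samples
#' of planted genes are shifted by `direction * log2(planted_fc)` at the
#' timepoints where the gene's archetype is active. Down-regulation is
#' planted as a negative signed fold change: graft mean = control mean /
#' fc. The same genes are planted in both cell types. Control and graft
#' replicates at a timepoint share an animal id (paired design), though
#' the default analysis treats the groups as unpaired.
#'
#' @param config a [sim_config()].
#' @return list with `em` (an [expression_matrix()]) and `truth` (a
#'   `PlantedTruth` list: `genes`, `de_genes` data.frame with archetype /
#'   direction / fc, `signed_fc` long data.frame of planted signed fold
#'   changes per (gene, cell_type, timepoint), later augmented by the
#'   network and gene-set generators).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(derive_seed(config$seed, 1L), {
    ng <- config$n_genes
    genes <- sprintf("GENE%04d", seq_len(ng))
    baseline <- stats::rnorm(ng, config$baseline_mean, config$baseline_sd)
    n_de <- round(config$de_fraction * ng)
    arch_pool <- setdiff(config$archetypes, "null")
    de_idx <- if (n_de > 0) sort(sample.int(ng, n_de)) else integer()
    arch <- if (n_de > 0) rep(arch_pool, length.out = n_de) else character()
    tps <- config$timepoints
    profs <- lapply(arch, archetype_profile, timepoints = tps)
    activity <- do.call(rbind, c(lapply(profs, function(p) p$mask),
                                 list(matrix(logical(), 0, length(tps)))))
    direction <- vapply(profs, function(p) p$direction, 0)

    meta <- expand.grid(replicate = seq_len(config$n_replicates),
                        condition = c("control", "graft"),
                        timepoint = tps, cell_type = config$cell_types,
                        stringsAsFactors = FALSE)
    meta$sample <- sprintf("%s_%s_%s_R%d", meta$cell_type, meta$condition,
                           meta$timepoint, meta$replicate)
    meta$animal <- sprintf("%s_%s_A%d", meta$cell_type, meta$timepoint,
                           meta$replicate)
    meta <- meta[, c("sample", "cell_type", "condition", "timepoint", "animal")]

    shift <- matrix(0, ng, nrow(meta))
    if (n_de > 0) {
      lfc <- log2(config$planted_fc)
      for (j in which(meta$condition == "graft")) {
        tp_i <- match(meta$timepoint[j], tps)
        act <- activity[, tp_i]
        shift[de_idx[act], j] <- direction[act] * lfc
      }
    }
    noise <- matrix(stats::rnorm(ng * nrow(meta), 0, config$noise_sd),
                    ng, nrow(meta))
    vals <- baseline + shift + noise
    dimnames(vals) <- list(genes, meta$sample)
    em <- expression_matrix(vals, meta, timepoints = tps)

    sf <- config$planted_fc
    long <- list()
    if (n_de > 0) {
      for (ct in config$cell_types) {
        for (t_i in seq_along(tps)) {
          act <- which(activity[, t_i])
          if (length(act))
            long[[paste(ct, t_i)]] <- data.frame(
              gene = genes[de_idx[act]], cell_type = ct, timepoint = tps[t_i],
              signed_fc = ifelse(direction[act] > 0, sf, -sf),
              stringsAsFactors = FALSE)
        }
      }
    }
    signed_fc_df <- if (length(long)) do.call(rbind, long) else
      data.frame(gene = character(), cell_type = character(),
                 timepoint = character(), signed_fc = numeric(),
                 stringsAsFactors = FALSE)
    rownames(signed_fc_df) <- NULL
    truth <- structure(list(
      genes = genes,
      de_genes = data.frame(gene = genes[de_idx], archetype = arch,
                            direction = direction,
                            fc = rep(config$planted_fc, length(de_idx)),
                            stringsAsFactors = FALSE),
      activity = activity,
      signed_fc = signed_fc_df,
      hub_genes = character(),
      dominant_sets = character()
    ), class = "PlantedTruth")
    list(em = em, truth = truth)
  })
}

#' Scale-free edge list by preferential attachment
#'
#' Starts from `m` edgeless seed nodes; every further node attaches `m`
#' distinct edges to existing nodes sampled with probability
#' proportional to degree + 1. The result therefore has exactly
#' `(n - m) * m` edges.
#'
#' @param n number of nodes; `n >= m + 1`.
#' @param m edges added per node.
#' @return 2-column integer matrix of edges (node indices).
#' @export
sample_preferential_attachment <- function(n, m) {
  if (n < m + 1) stop_config("need n >= m + 1 (got n=%d, m=%d)", n, m)
  deg <- numeric(n)
  from <- integer((n - m) * m); to <- integer((n - m) * m)
  e <- 0L
  for (i in (m + 1L):n) {
    prev <- seq_len(i - 1L)
    targets <- sample(prev, size = min(m, length(prev)), replace = FALSE,
                      prob = deg[prev] + 1)
    for (t in targets) {
      e <- e + 1L
      from[e] <- i; to[e] <- t
      deg[i] <- deg[i] + 1; deg[t] <- deg[t] + 1
    }
  }
  cbind(from[seq_len(e)], to[seq_len(e)])
}

#' Generate a synthetic interaction network with planted hubs
#'
#' Produces a scale-free background graph over a subset of the cohort's
#' gene symbols (all planted DE genes are always included as nodes),
#' then (i) wires each planted hub into a clique with
#' `hub_neighborhood` other nodes so its maximum neighborhood component
#' is dense, giving it a DMNC far above the background, and a few extra
#' pendant edges so it out-ranks its own clique partners on the degree
#' tie-break; and (ii) guarantees the temporal chain: every planted DE
#' gene active at timepoint k has at least one edge to a *different*
#' planted DE gene active at timepoint k+1, so backpropagation layers
#' are non-degenerate. Hubs are drawn from the sustained (all-timepoint)
#' planted genes so they are present in every layer of both cell types.
#'
#' @param config a [sim_config()].
#' @param truth the `PlantedTruth` from [generate_expression()].
#' @return list with `network` (an [interaction_network()] igraph) and
#'   `truth` (updated with `hub_genes` and `network_nodes`).
#' @export
generate_interaction_network <- function(config, truth) {
  stopifnot(inherits(config, "SimulationConfig"), inherits(truth, "PlantedTruth"))
  if (config$network_n < config$network_m + 1)
    stop_config("network_n must be >= network_m + 1")
  if (config$n_planted_hubs > config$network_n)
    stop_config("n_planted_hubs exceeds network_n")
  with_seed(derive_seed(config$seed, 2L), {
    de_genes <- truth$de_genes$gene
    if (config$network_n < length(de_genes))
      stop_config("network_n (%d) must cover the %d planted DE genes",
                  config$network_n, length(de_genes))
    filler <- setdiff(truth$genes, de_genes)
    nodes <- c(de_genes,
               filler[seq_len(min(length(filler),
                                  config$network_n - length(de_genes)))])
    nodes <- sample(nodes)  # decouple attachment order from DE status
    n <- length(nodes)

    el <- sample_preferential_attachment(n, config$network_m)
    from <- nodes[el[, 1]]; to <- nodes[el[, 2]]
    ekey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    keys <- ekey(from, to)
    add_edge <- function(a, b) {
      k <- ekey(a, b)
      if (!(k %in% keys)) {
        from <<- c(from, a); to <<- c(to, b); keys <<- c(keys, k)
      }
    }

    sustained <- truth$de_genes$gene[truth$de_genes$archetype == "sustained_down"]
    hub_pool <- if (length(sustained) >= config$n_planted_hubs) sustained else de_genes
    if (length(hub_pool) < config$n_planted_hubs)
      hub_pool <- nodes
    hubs <- sample(hub_pool, config$n_planted_hubs)
    # clique members are drawn from the planted DE genes so the dense
    # neighborhood survives restriction to the DE-only integrated network
    need <- config$n_planted_hubs * (config$hub_neighborhood + 3L)
    clique_pool <- setdiff(if (length(de_genes) > need) de_genes else nodes, hubs)
    cliques <- list(); pendants <- list()
    for (h in hubs) {
      nbrs <- sample(clique_pool, min(config$hub_neighborhood, length(clique_pool)))
      clique_pool <- setdiff(clique_pool, nbrs)  # cliques do not share members
      cliques[[h]] <- nbrs
      pend <- sample(clique_pool, min(3, length(clique_pool)))
      clique_pool <- setdiff(clique_pool, pend)
      pendants[[h]] <- pend
    }
    # hub modules are wired exclusively by construction: incidental
    # background edges into a module would attach loose ninth nodes to the
    # neighborhood and dilute its density (|E|/|V|^eps falls as |V| grows)
    protected <- unique(c(hubs, unlist(cliques), unlist(pendants)))
    keep <- !(from %in% protected | to %in% protected)
    from <- from[keep]; to <- to[keep]; keys <- keys[keep]
    for (h in hubs) {
      members <- c(h, cliques[[h]])
      for (i in seq_along(members)[-length(members)])
        for (j in (i + 1):length(members))
          add_edge(members[i], members[j])
      # pendant edges: hub wins the degree tie-break over its clique mates
      for (p in pendants[[h]]) add_edge(h, p)
    }

    tps <- config$timepoints
    if (nrow(truth$de_genes) && length(tps) > 1) {
      act_by_tp <- lapply(seq_along(tps), function(t_i)
        truth$de_genes$gene[truth$activity[, t_i]])
      for (t_i in seq_len(length(tps) - 1L)) {
        nxt <- act_by_tp[[t_i + 1L]]
        for (g in act_by_tp[[t_i]]) {
          partners <- setdiff(nxt, g)
          if (!length(partners)) next
          if (any(ekey(g, partners) %in% keys)) next
          # prefer partners outside the hub modules so the planted dense
          # neighborhoods keep their exact clique structure
          free <- setdiff(partners, protected)
          add_edge(g, sample(if (length(free)) free else partners, 1))
        }
      }
    }

    edge_type <- sample(c("pp", "pd", "pr"), length(from), replace = TRUE,
                        prob = c(0.7, 0.2, 0.1))
    net <- interaction_network(
      data.frame(from = from, to = to, edge_type = edge_type,
                 stringsAsFactors = FALSE),
      nodes = nodes)
    truth$hub_genes <- sort(hubs)
    truth$network_nodes <- sort(nodes)
    list(network = net, truth = truth)
  })
}

#' Generate a synthetic gene-set collection with a planted dominant set
#'
#' Builds a GMT-style collection containing (i) one "dominant" set
#' engineered to cover 15% of the genes expected in the backpropagation
#' network (the planted DE genes), comfortably above the 10% dominance
#' threshold, padded with random background genes; and (ii) decoy sets
#' drawn uniformly from the gene universe, which at the default design
#' cover only a few percent of the network by chance.
#'
#' @param config a [sim_config()].
#' @param truth the `PlantedTruth` from the paired generators.
#' @return list with `collection` (a [gene_set_collection()]) and
#'   `truth` (updated with `dominant_sets`).
#' @export
generate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "SimulationConfig"), inherits(truth, "PlantedTruth"))
  with_seed(derive_seed(config$seed, 3L), {
    universe <- truth$genes
    U <- truth$de_genes$gene  # expected backprop-network gene set
    sets <- list(); desc <- character()
    n_cov <- max(1L, ceiling(0.15 * length(U)))
    size_d <- max(config$set_size_range[1],
                  min(config$set_size_range[2], 2 * n_cov))
    # at least half the set comes from the network genes so the set is
    # both covering and hypergeometrically enriched at any cohort scale
    n_core <- min(length(U), max(n_cov, ceiling(size_d / 2)))
    core <- if (length(U)) sample(U, n_core) else character()
    pad <- sample(setdiff(universe, core), max(0, size_d - length(core)))
    sets[["PWY_PLANTED_DOMINANT"]] <- c(core, pad)
    desc["PWY_PLANTED_DOMINANT"] <- "synthetic dominant pathway (planted)"
    for (i in seq_len(config$n_gene_sets - 1L)) {
      nm <- sprintf("PWY_DECOY_%02d", i)
      sz <- sample(seq(config$set_size_range[1], config$set_size_range[2]), 1)
      sets[[nm]] <- sample(universe, sz)
      desc[nm] <- "synthetic decoy pathway (uniform draw)"
    }
    truth$dominant_sets <- "PWY_PLANTED_DOMINANT"
    list(collection = gene_set_collection(sets, desc), truth = truth)
  })
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Runs the three generators and writes: `expression.tsv`,
#' `samples.tsv`, `network.sif`, `gene_sets.gmt`, `truth.json` and
#' `config.yaml` under `outdir`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory `em`, `truth`,
#'   `network`, `collection` and the file `paths`.
#' @export
simulate_bundle <- function(config, outdir) {
  stopifnot(inherits(config, "SimulationConfig"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ge <- generate_expression(config)
  gn <- generate_interaction_network(config, ge$truth)
  gs <- generate_gene_sets(config, gn$truth)
  truth <- gs$truth
  paths <- list(
    expression = file.path(outdir, "expression.tsv"),
    metadata = file.path(outdir, "samples.tsv"),
    network = file.path(outdir, "network.sif"),
    gene_sets = file.path(outdir, "gene_sets.gmt"),
    truth = file.path(outdir, "truth.json"),
    config = file.path(outdir, "config.yaml"))
  write_expression(ge$em, paths$expression, paths$metadata)
  write_network(gn$network, paths$network, format = "sif")
  write_gmt(gs$collection, paths$gene_sets)
  jsonlite::write_json(list(
    de_genes = truth$de_genes,
    signed_fc = truth$signed_fc,
    hub_genes = truth$hub_genes,
    dominant_sets = truth$dominant_sets,
    network_nodes = truth$network_nodes
  ), paths$truth, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  cfg <- unclass(config)
  yaml::write_yaml(cfg, paths$config)
  invisible(list(em = ge$em, truth = truth, network = gn$network,
                 collection = gs$collection, paths = paths))
}
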
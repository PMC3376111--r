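#' Run the full analysis pipeline on expression, network and gene sets
#'
#' Executes, in order: quantile normalization (optional), sample QC (PCA
#' and correlation-based hierarchical clustering), per-timepoint
#' moderated differential expression, cross-cell-type overlap, moderated-F
#' time-course selection, K-means temporal clustering, per-timepoint
#' gene-set enrichment, backpropagation layered-network construction
#' with dominant-pathway selection and per-layer enrichment, DMNC hub
#' ranking per cell type, and cross-cell-type signature-network
#' extraction. All result tables, network exports and a run manifest
#' (configuration echo, seed, package version, per-file MD5 checksums)
#' are written under `outdir`. With identical inputs, configuration and
#' seed the result files are byte-identical.
#'
#' @param expression,metadata,network,gene_sets input file paths
#'   (expression TSV, sample-metadata TSV, SIF / edge-list network, GMT).
#' @param outdir output directory, created if needed.
#' @param thresholds a [threshold_config()].
#' @param dominance a [dominance_config()].
#' @param kmeans_k named integer vector: clusters per cell type (cell
#'   types without an entry default to 8).
#' @param epsilon DMNC density exponent (default 1.7).
#' @param top_k signature size (default 10).
#' @param seed master seed; stage-specific substreams are derived from
#'   it so stages do not perturb each other's draws.
#' @param normalize quantile-normalize before analysis (default TRUE).
#' @param timepoints optional ordered timepoint labels (default: order
#'   of first appearance in the metadata).
#' @return invisibly, a list with every stage's in-memory result
#'   (`em`, `pca`, `hclust`, `de`, `de_sets`, `overlaps`, `timecourse`,
#'   `clusters`, `enrichment`, `layered`, `dominant`, `layer_enrichment`,
#'   `hubs`, `signature`, `manifest`).
#' @export
run_pipeline <- function(expression, metadata, network, gene_sets, outdir,
                         thresholds = threshold_config(),
                         dominance = dominance_config(),
                         kmeans_k = c(EC = 8, SMC = 10),
                         epsilon = 1.7, top_k = 10, seed = 1,
                         normalize = TRUE, timepoints = NULL) {
  inputs <- c(expression = expression, metadata = metadata,
              network = network, gene_sets = gene_sets)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop_config("missing input file(s): %s", paste(missing, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message(sprintf(...))
  wtab <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    name
  }
  files <- character()

  em <- read_expression(expression, metadata, timepoints = timepoints)
  net <- read_network(network)
  collection <- read_gmt(gene_sets)
  if (normalize) {
    log_msg("quantile-normalizing %d genes x %d samples", nrow(em$values), ncol(em$values))
    em <- quantile_normalize(em)
  }
  universe <- rownames(em$values)
  cts <- unique(em$samples$cell_type)

  # --- QC ---
  pca <- pca_samples(em, n_components = min(5, ncol(em$values) - 1))
  files <- c(files, wtab(data.frame(sample = rownames(pca$scores),
                                    pca$scores, check.names = FALSE),
                         "pca_coordinates.tsv"))
  files <- c(files, wtab(data.frame(component = seq_along(pca$var_explained),
                                    var_explained = pca$var_explained),
                         "pca_variance.tsv"))
  hc <- hcluster_samples(em)
  jsonlite::write_json(list(labels = hc$labels, merge = hc$merge,
                            height = hc$height, order = hc$order),
                       file.path(outdir, "dendrogram.json"),
                       auto_unbox = FALSE, digits = NA)
  files <- c(files, "dendrogram.json")

  # --- differential expression ---
  log_msg("applying DE thresholds |FC| >= %g, %s p <= %g",
          thresholds$fc_threshold, thresholds$adjust_method, thresholds$alpha_de)
  det <- de_table(em, thresholds = thresholds)
  files <- c(files, wtab(det, "de_table.tsv"))
  de_sets <- select_de_genes(det, thresholds)
  counts <- do.call(rbind, lapply(names(de_sets), function(ct)
    do.call(rbind, lapply(names(de_sets[[ct]]), function(tp)
      data.frame(cell_type = ct, timepoint = tp,
                 n_up = length(de_sets[[ct]][[tp]]$up),
                 n_down = length(de_sets[[ct]][[tp]]$down),
                 n_de = length(de_sets[[ct]][[tp]]$all),
                 stringsAsFactors = FALSE)))))
  files <- c(files, wtab(counts, "de_counts.tsv"))
  overlaps <- NULL
  if (length(cts) >= 2) {
    ov_rows <- lapply(em$timepoints, function(tp) {
      ov <- overlap_sets(de_sets, tp, cell_types = cts[1:2])
      cbind(timepoint = tp, ov$summary)
    })
    overlaps <- do.call(rbind, ov_rows)
    files <- c(files, wtab(overlaps, "overlap.tsv"))
  }

  # --- time course + clustering ---
  log_msg("time-course selection at raw p < %g", thresholds$alpha_timecourse)
  timecourse <- list(); clusters <- list()
  for (ct in cts) {
    tc <- timecourse_moderated_F(em, ct, thresholds = thresholds)
    timecourse[[ct]] <- tc
    files <- c(files, wtab(tc$stats, sprintf("timecourse_%s.tsv", ct)))
    de_any <- unique(unlist(lapply(de_sets[[ct]], function(x) x$all)))
    cluster_genes <- intersect(tc$selected, de_any)
    if (length(cluster_genes) >= 2) {
      k <- unname(if (ct %in% names(kmeans_k)) kmeans_k[[ct]] else 8)
      k <- min(k, length(cluster_genes))
      cl <- kmeans_temporal(tc$profiles[cluster_genes, , drop = FALSE], k,
                            seed = derive_seed(seed, 40L + match(ct, cts)))
      clusters[[ct]] <- cl
      files <- c(files, wtab(data.frame(gene = names(cl$labels),
                                        cluster = unname(cl$labels)),
                             sprintf("clusters_%s.tsv", ct)))
    } else {
      log_msg("cell type %s: %d genes pass both selections; clustering skipped",
              ct, length(cluster_genes))
    }
  }

  # --- per-timepoint enrichment ---
  enrichment <- list()
  for (ct in cts) {
    for (tp in em$timepoints) {
      s <- de_sets[[ct]][[tp]]
      if (is.null(s) || !length(s$all)) next
      enr <- enrich_gene_sets(s$all, universe, collection,
                              adjust = "BH", alpha = 0.01,
                              up = s$up, down = s$down)
      enrichment[[paste(ct, tp, sep = "_")]] <- enr
      files <- c(files, wtab(enr, sprintf("enrichment_%s_%s.tsv", ct, tp)))
    }
  }

  # --- backpropagation network ---
  layered <- list(); dominant <- list(); layer_enr <- list(); hubs <- list()
  for (ct in cts) {
    sets_ct <- lapply(de_sets[[ct]], function(x) x$all)
    ln <- build_layered_network(sets_ct, net, em$timepoints, cell_type = ct)
    layered[[ct]] <- ln
    write_network(ln, file.path(outdir, sprintf("backprop_%s.graphml", ct)),
                  format = "graphml")
    write_network(ln, file.path(outdir, sprintf("backprop_%s.json", ct)),
                  format = "json")
    files <- c(files, sprintf("backprop_%s.graphml", ct),
               sprintf("backprop_%s.json", ct))
    dom <- select_dominant_pathways(ln, collection, universe, dominance)
    dominant[[ct]] <- dom
    files <- c(files, wtab(dom, sprintf("dominant_pathways_%s.tsv", ct)))
    le <- layerwise_enrichment(ln, collection, universe)
    layer_enr[[ct]] <- le
    le_tab <- do.call(rbind, lapply(names(le), function(tp)
      if (nrow(le[[tp]])) cbind(layer = tp, le[[tp]]) else NULL))
    if (!is.null(le_tab))
      files <- c(files, wtab(le_tab, sprintf("layer_enrichment_%s.tsv", ct)))
    if (igraph::vcount(ln$integrated) > 0) {
      hubs[[ct]] <- rank_hubs(ln$integrated, epsilon = epsilon)
      files <- c(files, wtab(hubs[[ct]], sprintf("hubs_%s.tsv", ct)))
    } else {
      log_msg("cell type %s: integrated network empty; hub ranking skipped", ct)
    }
  }

  # --- signature network ---
  signature <- NULL
  if (length(cts) >= 2 && !is.null(hubs[[cts[1]]]) && !is.null(hubs[[cts[2]]])) {
    signature <- signature_network(
      hubs[[cts[1]]], hubs[[cts[2]]],
      layered[[cts[1]]]$integrated, layered[[cts[2]]]$integrated,
      K = top_k, de_tables = det, cell_types = cts[1:2])
    if (nrow(signature$hubs)) {
      files <- c(files, wtab(signature$hubs, "signature_hubs.tsv"))
      if (!is.null(signature$fold_changes))
        files <- c(files, wtab(signature$fold_changes, "signature_fold_changes.tsv"))
      if (!is.null(signature$subgraph_a)) {
        write_network(signature$subgraph_a,
                      file.path(outdir, sprintf("signature_%s.graphml", cts[1])),
                      format = "graphml")
        files <- c(files, sprintf("signature_%s.graphml", cts[1]))
      }
      if (!is.null(signature$subgraph_b)) {
        write_network(signature$subgraph_b,
                      file.path(outdir, sprintf("signature_%s.graphml", cts[2])),
                      format = "graphml")
        files <- c(files, sprintf("signature_%s.graphml", cts[2]))
      }
    }
  }

  # --- manifest ---
  files <- unique(files)
  sums <- tools::md5sum(file.path(outdir, files))
  names(sums) <- files
  manifest <- list(
    package = "graftnet",
    version = as.character(utils::packageVersion("graftnet")),
    seed = seed,
    inputs = as.list(inputs),
    thresholds = unclass(thresholds),
    dominance = unclass(dominance),
    kmeans_k = as.list(kmeans_k),
    epsilon = epsilon, top_k = top_k, normalize = normalize,
    timecourse_method = "moderated_F_timecourse",
    checksums = as.list(sums))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(em = em, network = net, collection = collection,
                 pca = pca, hclust = hc, de = det, de_sets = de_sets,
                 overlaps = overlaps, timecourse = timecourse,
                 clusters = clusters, enrichment = enrichment,
                 layered = layered, dominant = dominant,
                 layer_enrichment = layer_enr, hubs = hubs,
                 signature = signature, manifest = manifest))
}
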
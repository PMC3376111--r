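#' Analysis thresholds for differential expression
#'
#' @param fc_threshold linear-scale absolute fold-change cutoff (>= 1);
#'   default 2, i.e. a doubling or halving.
#' @param alpha_de adjusted-p cutoff for per-timepoint DE calls
#'   (inclusive, `p_adj <= alpha_de`); default 0.05.
#' @param alpha_timecourse raw-p cutoff for the time-course moderated-F
#'   selection (strict, `p < alpha_timecourse`); default 0.01.
#' @param adjust_method multiple-testing correction for per-timepoint DE,
#'   `"BH"` (Benjamini-Hochberg, default) or `"Holm"`.
#' @return a `ThresholdConfig` list.
#' @export
threshold_config <- function(fc_threshold = 2, alpha_de = 0.05,
                             alpha_timecourse = 0.01,
                             adjust_method = c("BH", "Holm")) {
  adjust_method <- match.arg(adjust_method)
  if (fc_threshold < 1) stop_config("fc_threshold must be >= 1")
  if (alpha_de <= 0 || alpha_de >= 1 || alpha_timecourse <= 0 || alpha_timecourse >= 1)
    stop_config("alpha thresholds must lie in (0, 1)")
  structure(list(fc_threshold = fc_threshold, alpha_de = alpha_de,
                 alpha_timecourse = alpha_timecourse,
                 adjust_method = adjust_method),
            class = "ThresholdConfig")
}

#' Per-gene two-group contrast at one timepoint
#'
#' For one cell type and timepoint, computes per-gene graft-vs-control
#' group means on the log2 scale, the log2 fold change (graft minus
#' control), its signed linear-scale counterpart, the pooled two-sample
#' variance with `n_control + n_graft - 2` degrees of freedom, and the
#' ordinary two-sample t statistic. Genes with zero pooled variance get
#' an infinite (or zero, if the means agree) t; shrinkage downstream
#' makes them finite.
#'
#' @param em an [expression_matrix()] of log2 values.
#' @param cell_type,timepoint labels selecting the sample group.
#' @param paired if `TRUE`, compute the contrast on within-animal
#'   graft-minus-control differences (one-sample model, `n - 1` df).
#'   Default `FALSE`: unpaired two-group model.
#' @return data.frame with one row per gene: `gene`, `mean_control`,
#'   `mean_graft`, `log2fc`, `signed_fc`, `s2` (pooled variance), `df`,
#'   `se_scale` (the sqrt(1/n1 + 1/n2) factor), `t_ordinary`.
#' @export
fit_timepoint_contrasts <- function(em, cell_type, timepoint, paired = FALSE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  sel <- em$samples$cell_type == cell_type & em$samples$timepoint == timepoint
  if (!any(sel))
    stop_config("no samples for cell type '%s' at timepoint '%s'", cell_type, timepoint)
  meta <- em$samples[sel, , drop = FALSE]
  vals <- em$values[, sel, drop = FALSE]
  ctrl <- vals[, meta$condition == "control", drop = FALSE]
  graf <- vals[, meta$condition == "graft", drop = FALSE]
  n_c <- ncol(ctrl); n_g <- ncol(graf)
  if (n_c < 2 || n_g < 2)
    stop_config("need >=2 replicates per condition (%s/%s has %d control, %d graft)",
                cell_type, timepoint, n_c, n_g)
  mean_c <- rowMeans(ctrl); mean_g <- rowMeans(graf)
  log2fc <- mean_g - mean_c
  if (paired) {
    an_c <- meta$animal[meta$condition == "control"]
    an_g <- meta$animal[meta$condition == "graft"]
    if (n_c != n_g || !setequal(an_c, an_g))
      stop_config("paired analysis requires matched animals in both conditions")
    diffs <- graf[, match(an_c, an_g), drop = FALSE] - ctrl
    s2 <- apply(diffs, 1, stats::var)
    df <- n_c - 1
    se_scale <- sqrt(1 / n_c)
  } else {
    ss_c <- rowSums((ctrl - mean_c)^2)
    ss_g <- rowSums((graf - mean_g)^2)
    df <- n_c + n_g - 2
    s2 <- (ss_c + ss_g) / df
    se_scale <- sqrt(1 / n_c + 1 / n_g)
  }
  se <- sqrt(s2) * se_scale
  t_ord <- ifelse(se > 0, log2fc / se, ifelse(log2fc == 0, 0, sign(log2fc) * Inf))
  data.frame(gene = rownames(vals), mean_control = mean_c, mean_graft = mean_g,
             log2fc = log2fc, signed_fc = signed_fc(log2fc),
             s2 = s2, df = rep(df, nrow(vals)), se_scale = se_scale,
             t_ordinary = t_ord, n_control = n_c, n_graft = n_g,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Moment-matching estimate of the scaled inverse-chi-square prior on gene
# variances. Degenerate ensembles (all variances identical) return an
# infinite prior df with the common value as the prior variance.
estimate_ebayes_params <- function(s2, df) {
  if (length(s2) < 10)
    stop_config("empirical-Bayes estimation needs >=10 genes")
  if (max(s2) - min(s2) < .Machine$double.eps * max(1, max(s2)))
    return(list(d0 = Inf, s0_sq = s2[1]))
  fit <- limma::fitFDist(s2, df1 = df)
  list(d0 = fit$df2, s0_sq = fit$scale)
}

#' Empirical-Bayes moderation of per-gene t statistics
#'
#' Shrinks per-gene sample variances toward a common prior:
#' `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)`, a convex combination of
#' the prior variance `s0_sq` (weight: prior df `d0`) and the gene's own
#' variance. The moderated t is the mean difference over the posterior
#' standard error, with `d0 + df` total degrees of freedom. With
#' `params = "estimate"` the prior `(d0, s0_sq)` is fitted by moment
#' matching the log sample variances against a scaled F distribution.
#' `d0 = 0` reproduces the ordinary t; `d0 = Inf` uses the common prior
#' variance for every gene.
#'
#' @param fit output of [fit_timepoint_contrasts()].
#' @param params `"estimate"` or a list with elements `d0` and `s0_sq`.
#' @return `fit` with added columns `s2_post`, `t_moderated`, `df_total`,
#'   `p_raw` (two-sided), and an `ebayes_params` attribute.
#' @export
ebayes_moderate <- function(fit, params = "estimate") {
  if (identical(params, "estimate")) {
    params <- estimate_ebayes_params(fit$s2, fit$df)
  }
  d0 <- params$d0; s0 <- params$s0_sq
  if (is.null(d0) || is.null(s0) || d0 < 0 || s0 < 0)
    stop_config("ebayes params need d0 >= 0 and s0_sq >= 0")
  s2_post <- if (is.infinite(d0)) rep(s0, nrow(fit)) else
    (d0 * s0 + fit$df * fit$s2) / (d0 + fit$df)
  se <- sqrt(s2_post) * fit$se_scale
  t_mod <- ifelse(se > 0, fit$log2fc / se,
                  ifelse(fit$log2fc == 0, 0, sign(fit$log2fc) * Inf))
  df_total <- d0 + fit$df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- fit
  out$s2_post <- s2_post
  out$t_moderated <- t_mod
  out$df_total <- df_total
  out$p_raw <- p
  attr(out, "ebayes_params") <- list(d0 = d0, s0_sq = s0)
  out
}

#' Multiple-testing adjustment (Benjamini-Hochberg or Holm)
#'
#' Thin wrapper over [stats::p.adjust()] exposing the two corrections
#' used in this pipeline: BH step-up control of the false discovery rate
#' and Holm step-down control of the family-wise error rate.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param method `"BH"` or `"Holm"`.
#' @return adjusted p-values in the original order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "Holm")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_config("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "BH") "BH" else "holm")
}

#' Per-timepoint moderated differential expression table
#'
#' Runs [fit_timepoint_contrasts()] + [ebayes_moderate()] for every
#' requested cell type and timepoint, adjusts p-values within each
#' contrast, and flags genes as differentially expressed when both the
#' fold-change rule (`|signed_fc| >= fc_threshold`) and the significance
#' rule (`p_adj <= alpha_de`) hold, both boundaries inclusive.
#'
#' @param em an [expression_matrix()].
#' @param cell_types cell types to analyze (default: all present).
#' @param thresholds a [threshold_config()].
#' @param paired passed to [fit_timepoint_contrasts()].
#' @return A `DETable` data.frame: per (gene, cell_type, timepoint) row
#'   with means, `log2fc`, `signed_fc`, `t_moderated`, `p_raw`, `p_adj`,
#'   `is_de`.
#' @export
de_table <- function(em, cell_types = NULL, thresholds = threshold_config(),
                     paired = FALSE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  cell_types <- cell_types %||% unique(em$samples$cell_type)
  rows <- list()
  for (ct in cell_types) {
    tps <- intersect(em$timepoints,
                     em$samples$timepoint[em$samples$cell_type == ct])
    for (tp in tps) {
      fit <- ebayes_moderate(
        fit_timepoint_contrasts(em, ct, tp, paired = paired))
      fit$p_adj <- adjust_pvalues(fit$p_raw, thresholds$adjust_method)
      fit$cell_type <- ct
      fit$timepoint <- tp
      fit$is_de <- abs(fit$signed_fc) >= thresholds$fc_threshold &
        fit$p_adj <= thresholds$alpha_de
      rows[[paste(ct, tp)]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cols <- c("gene", "cell_type", "timepoint", "mean_control", "mean_graft",
            "log2fc", "signed_fc", "t_moderated", "p_raw", "p_adj", "is_de")
  out <- out[, c(cols, setdiff(names(out), cols))]
  class(out) <- c("DETable", class(out))
  out
}

#' Split a DE table into per-timepoint up/down gene sets
#'
#' @param det a [de_table()] result (the `is_de` flag is recomputed from
#'   `thresholds`, so the same table can be re-thresholded).
#' @param thresholds a [threshold_config()].
#' @return nested list: `sets[[cell_type]][[timepoint]]` is a list with
#'   `up`, `down` and `all` character vectors of gene symbols.
#' @export
select_de_genes <- function(det, thresholds = threshold_config()) {
  stopifnot(is.data.frame(det))
  sel <- abs(det$signed_fc) >= thresholds$fc_threshold &
    det$p_adj <= thresholds$alpha_de
  out <- list()
  for (ct in unique(det$cell_type)) {
    out[[ct]] <- list()
    for (tp in unique(det$timepoint[det$cell_type == ct])) {
      idx <- sel & det$cell_type == ct & det$timepoint == tp
      up <- det$gene[idx & det$signed_fc > 0]
      down <- det$gene[idx & det$signed_fc < 0]
      out[[ct]][[tp]] <- list(up = up, down = down, all = c(up, down))
    }
  }
  out
}

#' Time-course gene selection with a moderated F statistic
#'
#' Selects genes whose temporal graft-vs-control profile departs from
#' zero anywhere along the time course. Per-gene variances are pooled
#' across the J per-timepoint contrasts (total df = sum of per-timepoint
#' df), shrunk by empirical Bayes, and each timepoint's moderated t is
#' combined into `F = mean(t^2)` referred to an F(J, d0 + df_pooled)
#' distribution. Selection uses the raw p-value at `alpha_timecourse`
#' (strict `<`). With a single timepoint this reduces exactly to the
#' two-sided moderated t test.
#'
#' @param em an [expression_matrix()].
#' @param cell_type the cell type to analyze.
#' @param thresholds a [threshold_config()].
#' @param paired passed to [fit_timepoint_contrasts()].
#' @return list with `stats` (data.frame: `gene`, `F_moderated`,
#'   `p_raw`, `selected`), `profiles` (gene x timepoint matrix of log2
#'   fold changes), `params` (fitted prior) and `selected` (character
#'   vector of selected genes).
#' @export
timecourse_moderated_F <- function(em, cell_type,
                                   thresholds = threshold_config(),
                                   paired = FALSE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  tps <- intersect(em$timepoints,
                   em$samples$timepoint[em$samples$cell_type == cell_type])
  if (!length(tps)) stop_config("no samples for cell type '%s'", cell_type)
  fits <- lapply(tps, function(tp)
    fit_timepoint_contrasts(em, cell_type, tp, paired = paired))
  J <- length(fits)
  genes <- fits[[1]]$gene
  dfs <- vapply(fits, function(f) f$df[1], 0)
  s2m <- vapply(fits, function(f) f$s2, numeric(length(genes)))
  if (!is.matrix(s2m)) s2m <- matrix(s2m, nrow = length(genes))
  df_pool <- sum(dfs)
  s2_pool <- as.vector(s2m %*% dfs) / df_pool
  params <- estimate_ebayes_params(s2_pool, df_pool)
  d0 <- params$d0
  s2_post <- if (is.infinite(d0)) rep(params$s0_sq, length(genes)) else
    (d0 * params$s0_sq + df_pool * s2_pool) / (d0 + df_pool)
  t2 <- matrix(0, length(genes), J)
  for (j in seq_len(J)) {
    se <- sqrt(s2_post) * fits[[j]]$se_scale
    tj <- ifelse(se > 0, fits[[j]]$log2fc / se,
                 ifelse(fits[[j]]$log2fc == 0, 0, Inf))
    t2[, j] <- tj^2
  }
  Fstat <- rowMeans(t2)
  p <- stats::pf(Fstat, J, d0 + df_pool, lower.tail = FALSE)
  profiles <- vapply(fits, function(f) f$log2fc, numeric(length(genes)))
  if (!is.matrix(profiles)) profiles <- matrix(profiles, nrow = length(genes))
  dimnames(profiles) <- list(genes, tps)
  stats <- data.frame(gene = genes, F_moderated = Fstat, p_raw = p,
                      selected = p < thresholds$alpha_timecourse,
                      stringsAsFactors = FALSE)
  list(stats = stats, profiles = profiles, params = params,
       selected = genes[stats$selected],
       method = "moderated_F_timecourse")
}

#' Cross-cell-type overlap of DE gene sets at one timepoint
#'
#' Reports, for the up-regulated, down-regulated and combined DE sets of
#' two cell types at one timepoint, the shared and exclusive genes plus
#' three overlap ratios. Because a "percent common" statistic is
#' ambiguous about its denominator, all three candidates are emitted:
#' `|A∩B|/|A∪B|`, `|A∩B|/|A|` and `|A∩B|/|B|` (0 when the denominator is
#' empty).
#'
#' @param de_sets nested list from [select_de_genes()].
#' @param timepoint timepoint label.
#' @param cell_types the two cell types to compare (default first two in
#'   `de_sets`).
#' @return list with `members` (per category: `intersection`, `a_only`,
#'   `b_only`) and `summary` (data.frame of counts and the three ratios
#'   per category).
#' @export
overlap_sets <- function(de_sets, timepoint, cell_types = names(de_sets)[1:2]) {
  a_ct <- cell_types[1]; b_ct <- cell_types[2]
  if (is.null(de_sets[[a_ct]][[timepoint]]) || is.null(de_sets[[b_ct]][[timepoint]]))
    stop_config("both cell types must be analyzed at timepoint '%s'", timepoint)
  ratio <- function(num, den) if (den == 0) 0 else num / den
  members <- list(); rows <- list()
  for (cat in c("up", "down", "combined")) {
    a <- if (cat == "combined") de_sets[[a_ct]][[timepoint]]$all else
      de_sets[[a_ct]][[timepoint]][[cat]]
    b <- if (cat == "combined") de_sets[[b_ct]][[timepoint]]$all else
      de_sets[[b_ct]][[timepoint]][[cat]]
    int <- intersect(a, b)
    members[[cat]] <- list(intersection = int,
                           a_only = setdiff(a, b), b_only = setdiff(b, a))
    rows[[cat]] <- data.frame(
      category = cat, n_a = length(a), n_b = length(b),
      n_intersection = length(int), n_union = length(union(a, b)),
      ratio_union = ratio(length(int), length(union(a, b))),
      ratio_a = ratio(length(int), length(a)),
      ratio_b = ratio(length(int), length(b)),
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(members = members, summary = summary,
       cell_types = c(a = a_ct, b = b_ct), timepoint = timepoint)
}

#' K-means clustering of temporal fold-change profiles
#'
#' Profiles (per-gene log2 fold change over the ordered timepoints) are
#' z-scored per gene and clustered by Euclidean K-means, keeping the best
#' of `nstart` restarts by total within-cluster sum of squares. Genes
#' with a flat profile (zero variance) z-score to the zero vector. The
#' result is deterministic given the seed.
#'
#' @param profiles numeric gene x timepoint matrix (rownames = genes),
#'   e.g. the `profiles` element of [timecourse_moderated_F()] restricted
#'   to the selected genes.
#' @param k number of clusters (`k <= nrow(profiles)`).
#' @param seed RNG seed for the restarts; default 17.
#' @param nstart number of random restarts; default 50.
#' @return A `TemporalClusterResult` list: `k`, `labels` (named integer
#'   vector in `1..k`), `centers` (k x timepoint centroid matrix on the
#'   z scale), `tot_withinss`, `profiles_z`.
#' @export
kmeans_temporal <- function(profiles, k, seed = 17, nstart = 50) {
  if (!is.matrix(profiles)) stop_config("profiles must be a matrix")
  if (k > nrow(profiles))
    stop_config("k = %d exceeds the %d available genes", k, nrow(profiles))
  mu <- rowMeans(profiles)
  sd <- apply(profiles, 1, stats::sd)
  z <- (profiles - mu) / ifelse(sd > 0, sd, 1)
  km <- with_seed(seed, stats::kmeans(z, centers = k, nstart = nstart,
                                      iter.max = 100))
  labels <- km$cluster
  names(labels) <- rownames(profiles)
  structure(list(k = k, labels = labels, centers = km$centers,
                 tot_withinss = km$tot.withinss, withinss = km$withinss,
                 profiles_z = z),
            class = "TemporalClusterResult")
}
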
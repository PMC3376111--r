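#' Expression matrix with sample annotations
#'
#' Container for a gene x sample matrix of normalized log2 expression
#' values together with per-sample metadata. All downstream statistics
#' (differential expression, time-course selection, clustering, QC)
#' operate on this object.
#'
#' @param values numeric matrix, genes in rows (rownames = unique gene
#'   symbols), samples in columns (colnames = sample ids).
#' @param sample_meta data.frame with one row per sample and columns
#'   `sample`, `cell_type`, `condition`, `timepoint`, `animal`.
#'   `condition` must be one of `"control"`, `"graft"`.
#' @param timepoints character vector giving the ordered timepoint labels
#'   of the study design (earliest first). Defaults to the labels present
#'   in `sample_meta`, in order of first appearance.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix, metadata-ordered columns), `samples` (the
#'   metadata data.frame) and `timepoints` (ordered labels).
#' @export
expression_matrix <- function(values, sample_meta, timepoints = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_config("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_config("`values` must have gene rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop_config("duplicate gene symbols: %s", paste(unique(dup), collapse = ", "))
  req <- c("sample", "cell_type", "condition", "timepoint", "animal")
  miss_col <- setdiff(req, names(sample_meta))
  if (length(miss_col))
    stop_config("sample metadata lacks columns: %s", paste(miss_col, collapse = ", "))
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  missing_meta <- setdiff(colnames(values), sample_meta$sample)
  if (length(missing_meta))
    stop_config("samples missing from metadata: %s", paste(missing_meta, collapse = ", "))
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), , drop = FALSE]
  rownames(sample_meta) <- NULL
  if (anyNA(sample_meta[req]))
    stop_config("sample metadata contains missing values")
  bad_cond <- setdiff(unique(sample_meta$condition), c("control", "graft"))
  if (length(bad_cond))
    stop_config("unknown condition labels: %s", paste(bad_cond, collapse = ", "))
  if (is.null(timepoints)) timepoints <- unique(sample_meta$timepoint)
  bad_tp <- setdiff(unique(sample_meta$timepoint), timepoints)
  if (length(bad_tp))
    stop_config("timepoint labels not in configured order: %s", paste(bad_tp, collapse = ", "))
  structure(
    list(values = values, samples = sample_meta, timepoints = timepoints),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d samples\n", nrow(x$values), ncol(x$values)))
  cat(sprintf("  cell types: %s\n", paste(unique(x$samples$cell_type), collapse = ", ")))
  cat(sprintf("  timepoints: %s\n", paste(x$timepoints, collapse = " < ")))
  cat(sprintf("  conditions: %s\n", paste(sort(unique(x$samples$condition)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# Subset the samples of an ExpressionMatrix by metadata predicate values.
subset_samples <- function(em, cell_type = NULL, condition = NULL, timepoint = NULL) {
  keep <- rep(TRUE, nrow(em$samples))
  if (!is.null(cell_type)) keep <- keep & em$samples$cell_type %in% cell_type
  if (!is.null(condition)) keep <- keep & em$samples$condition %in% condition
  if (!is.null(timepoint)) keep <- keep & em$samples$timepoint %in% timepoint
  expression_matrix(em$values[, keep, drop = FALSE],
                    em$samples[keep, , drop = FALSE],
                    timepoints = em$timepoints)
}

#' Read an expression matrix and its sample metadata from TSV files
#'
#' The expression TSV has a header row of sample ids and a first column of
#' gene symbols; the metadata TSV has columns `sample`, `cell_type`,
#' `condition`, `timepoint`, `animal`. Readers validate rather than
#' repair: duplicate genes, samples without metadata and non-numeric
#' cells are errors naming the offending row or column.
#'
#' @param path path to the expression TSV.
#' @param meta_path path to the sample-metadata TSV.
#' @param timepoints optional ordered timepoint labels (see
#'   [expression_matrix()]).
#' @return An [expression_matrix()] object.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, meta_path, timepoints = NULL) {
  if (!file.exists(path)) stop_config("expression file not found: %s", path)
  if (!file.exists(meta_path)) stop_config("metadata file not found: %s", meta_path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop_config("expression TSV needs a gene column plus >=1 sample")
  genes <- tab[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop_config("duplicate gene rows in %s: %s", path, paste(dup, collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(genes, colnames(vals))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_config("non-numeric value at gene '%s', sample '%s'",
                genes[bad[1]], colnames(vals)[bad[2]])
  }
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
  expression_matrix(num, meta, timepoints = timepoints)
}

#' Write an expression matrix and its sample metadata to TSV files
#'
#' @param em an [expression_matrix()] object.
#' @param path output path for the expression TSV.
#' @param meta_path output path for the metadata TSV.
#' @return invisibly, `em`. Round-trip through [read_expression()]
#'   reproduces values to full precision and metadata exactly.
#' @export
write_expression <- function(em, path, meta_path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  num <- apply(em$values, 2, function(col) sprintf("%.17g", col))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(em$values))
  tab <- data.frame(gene = rownames(em$values), num,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("gene", colnames(em$values))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(em$samples, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(em)
}
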
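#' Gene-set collection
#'
#' A named collection of gene sets (pathways, GO terms, ...) with one
#' description per set. Set names must be unique and every set must have
#' at least one member; member lists are deduplicated with order
#' preserved.
#'
#' @param sets named list of character vectors of gene symbols.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled empty string if absent).
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop_config("every gene set must be named")
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup))
    stop_config("duplicate gene-set names: %s", paste(dup, collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  empty <- names(sets)[vapply(sets, length, 0L) == 0L]
  if (length(empty))
    stop_config("gene sets with no members: %s", paste(empty, collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- as.character(descriptions)
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  sizes <- vapply(x$sets, length, 0L)
  cat(sprintf("GeneSetCollection: %d sets, sizes %d-%d\n",
              length(x$sets), min(sizes), max(sizes)))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-separated format `name<TAB>description<TAB>gene1<TAB>...`,
#' one set per line, at least one member gene per set. Duplicate genes
#' within a line are stored once (first occurrence kept).
#'
#' @param path path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_config("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_config("GMT file is empty: %s", path)
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_config("GMT line %d has %d fields; need name, description, >=1 gene",
                  i, length(f))
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  if (length(sets) < length(lines))
    stop_config("duplicate set names in %s", path)
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return invisibly, the collection.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(collection)
}
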
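#' Feature-by-sample measurement table
#'
#' Container for an omics measurement matrix (proteins or metabolites as
#' rows, samples as columns) together with per-sample group labels and
#' standard-sample (pooled QC replicate) flags. Intensities are stored on the
#' raw (positive) scale; missing values are allowed and represented as `NA`.
#'
#' @param intensity numeric matrix, features x samples, with unique rownames
#'   (feature ids) and colnames (sample ids). Non-missing entries must be > 0.
#' @param group character vector of group labels, one per sample column
#'   (e.g. `"CCQS"`, `"QSBS"`, `"HC"`, `"STD"`).
#' @param is_standard logical vector flagging standard-sample replicates;
#'   defaults to `group == "STD"`.
#' @param feature_meta optional data.frame of per-feature annotation (first
#'   column is matched against rownames of `intensity`), e.g. metabolite
#'   chemical categories.
#'
#' @return An object of class `omics_table`: a list with elements
#'   `intensity`, `samples` (data.frame: sample_id, group, is_standard) and
#'   `feature_meta`.
#' @export
omics_table <- function(intensity, group, is_standard = NULL,
                        feature_meta = NULL) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  if (is.null(rownames(intensity)) || anyDuplicated(rownames(intensity)))
    stop("intensity must have unique rownames (feature ids)")
  if (is.null(colnames(intensity)) || anyDuplicated(colnames(intensity)))
    stop("intensity must have unique colnames (sample ids)")
  if (length(group) != ncol(intensity))
    stop("one group label per sample column is required")
  if (is.null(is_standard)) is_standard <- group == "STD"
  if (length(is_standard) != ncol(intensity))
    stop("one is_standard flag per sample column is required")
  ok <- intensity[!is.na(intensity)]
  if (any(ok <= 0)) stop("non-missing intensities must be positive")
  if (!is.null(feature_meta)) {
    feature_meta <- as.data.frame(feature_meta)
    if (!all(rownames(intensity) %in% feature_meta[[1L]]))
      stop("feature_meta must cover every feature id")
  }
  structure(
    list(
      intensity = intensity,
      samples = data.frame(
        sample_id = colnames(intensity),
        group = as.character(group),
        is_standard = as.logical(is_standard),
        stringsAsFactors = FALSE
      ),
      feature_meta = feature_meta
    ),
    class = "omics_table"
  )
}

#' @export
print.omics_table <- function(x, ...) {
  tab <- table(x$samples$group)
  cat(sprintf(
    "<omics_table> %d features x %d samples (%.1f%% missing)\n",
    nrow(x$intensity), ncol(x$intensity),
    100 * mean(is.na(x$intensity))
  ))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.omics_table <- function(x) dim(x$intensity)

#' Subset the sample columns of an omics table
#'
#' @param table an [omics_table].
#' @param groups character vector of group labels to keep.
#' @param drop_standards drop standard-sample replicates (default `TRUE`).
#' @return An [omics_table] restricted to the requested samples.
#' @export
subset_samples <- function(table, groups = NULL, drop_standards = TRUE) {
  stopifnot(inherits(table, "omics_table"))
  keep <- rep(TRUE, ncol(table$intensity))
  if (!is.null(groups)) keep <- keep & table$samples$group %in% groups
  if (drop_standards) keep <- keep & !table$samples$is_standard
  omics_table(table$intensity[, keep, drop = FALSE],
              table$samples$group[keep],
              table$samples$is_standard[keep],
              table$feature_meta)
}

# ---- plain-text readers/writers (TSV / GMT / SIF dialects) ----

#' Write an omics table as TSV (matrix + sample metadata)
#'
#' The matrix file has features as rows, a `feature_id` first column and one
#' column per sample; the metadata file has columns `sample_id`, `group`,
#' `is_standard`.
#'
#' @param table an [omics_table].
#' @param matrix_path,meta_path output file paths.
#' @return Invisibly, the matrix path.
#' @export
write_omics_tsv <- function(table, matrix_path, meta_path) {
  stopifnot(inherits(table, "omics_table"))
  df <- data.frame(feature_id = rownames(table$intensity),
                   table$intensity, check.names = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(table$samples, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(matrix_path)
}

#' Read an omics table written by [write_omics_tsv()]
#'
#' @param matrix_path,meta_path input file paths.
#' @param feature_meta optional per-feature annotation data.frame.
#' @return An [omics_table].
#' @export
read_omics_tsv <- function(matrix_path, meta_path, feature_meta = NULL) {
  df <- read.delim(matrix_path, check.names = FALSE)
  meta <- read.delim(meta_path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat <- mat[, meta$sample_id, drop = FALSE]
  omics_table(mat, meta$group, meta$is_standard, feature_meta)
}

#' Read/write gene-set collections in GMT format
#'
#' GMT is the conventional tab-separated set format: one set per line,
#' `set_id<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path file path.
#' @return `read_gmt`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    unique(f[-c(1L, 2L)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  out
}

#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @rdname read_gmt
#' @return `write_gmt`: invisibly, the path.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read/write molecular networks as SIF edge lists
#'
#' SIF lines are `node1<TAB>relation<TAB>node2`; edge weights travel in a
#' parallel TSV (`from`, `to`, `weight`) and node kinds in a node-attribute
#' TSV (`id`, `kind`).
#'
#' @param sif_path,weights_path,nodes_path file paths.
#' @return `read_sif`: a [molecular_network].
#' @export
read_sif <- function(sif_path, weights_path = NULL, nodes_path = NULL) {
  ed <- read.delim(sif_path, header = FALSE,
                   col.names = c("from", "relation", "to"))
  w <- if (!is.null(weights_path)) read.delim(weights_path)$weight
       else rep(1, nrow(ed))
  nodes <- if (!is.null(nodes_path)) read.delim(nodes_path) else NULL
  molecular_network(
    data.frame(from = ed$from, to = ed$to, weight = w,
               stringsAsFactors = FALSE),
    nodes
  )
}

#' @param net a [molecular_network].
#' @rdname read_sif
#' @export
write_sif <- function(net, sif_path, weights_path = NULL,
                      nodes_path = NULL) {
  g <- net$graph
  ed <- igraph::as_data_frame(g, what = "edges")
  write.table(
    data.frame(node1 = ed$from, relation = "link", node2 = ed$to),
    sif_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  if (!is.null(weights_path))
    write.table(data.frame(from = ed$from, to = ed$to, weight = ed$weight),
                weights_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(nodes_path))
    write.table(
      data.frame(id = igraph::V(g)$name, kind = igraph::V(g)$kind),
      nodes_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  invisible(sif_path)
}
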
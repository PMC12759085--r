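#' Cluster-labeled expression input for pseudo-bulk correlation
#'
#' Bundles a cells x genes expression matrix (normalized scale, dense or
#' sparse) with per-cell cluster labels and gene identifiers.
#'
#' @param expression Cells x genes numeric matrix or `Matrix` sparse matrix,
#'   non-negative.
#' @param cluster_labels Per-cell cluster labels (length = number of rows).
#' @param gene_ids Gene identifiers (length = number of columns); defaults
#'   to `colnames(expression)`.
#' @param markers Optional data.frame (`cluster`, `gene`) of per-cluster
#'   marker genes.
#'
#' @return An object of class `pseudobulk_input`.
#' @export
pseudobulk_input <- function(expression, cluster_labels, gene_ids = NULL,
                             markers = NULL) {
  if (is.null(gene_ids)) gene_ids <- colnames(expression)
  if (is.null(gene_ids))
    stop("gene_ids must be given when expression has no column names")
  gene_ids <- as.character(gene_ids)
  cluster_labels <- as.character(cluster_labels)
  if (length(cluster_labels) != nrow(expression))
    stop("cluster_labels length (", length(cluster_labels),
         ") must equal the number of cells (", nrow(expression), ")")
  if (length(gene_ids) != ncol(expression))
    stop("gene_ids length must equal the number of genes")
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  if (min(expression) < 0)
    warning("expression contains negative values; a non-negative ",
            "normalized scale is expected")
  colnames(expression) <- gene_ids
  structure(list(expression = expression, cluster_labels = cluster_labels,
                 gene_ids = gene_ids, markers = markers),
            class = "pseudobulk_input")
}

#' @exportS3Method base::print
print.pseudobulk_input <- function(x, ...) {
  cat("pseudobulk_input: ", nrow(x$expression), " cells x ",
      length(x$gene_ids), " genes, ", length(unique(x$cluster_labels)),
      " clusters\n", sep = "")
  invisible(x)
}

#' Aggregate expression into per-cluster pseudo-bulk profiles
#'
#' Collapses the cells x genes matrix to a clusters x genes profile matrix.
#' The default aggregation is the mean over the cluster's cells (invariant
#' to cluster size); `"sum"` is offered for count-like workflows.
#'
#' @param input A [pseudobulk_input].
#' @param method `"mean"` (default) or `"sum"`.
#'
#' @return Numeric matrix, clusters x genes, with cluster row names.
#' @export
aggregate_pseudobulk <- function(input, method = c("mean", "sum")) {
  stopifnot(inherits(input, "pseudobulk_input"))
  method <- match.arg(method)
  labels <- input$cluster_labels
  sizes <- table(labels)
  if (any(sizes == 0))
    stop("empty cluster: ", paste(names(sizes)[sizes == 0], collapse = ", "))
  expr <- as.matrix(input$expression)
  sums <- rowsum(expr, group = labels)
  if (method == "mean")
    sums <- sums / as.numeric(sizes[rownames(sums)])
  colnames(sums) <- input$gene_ids
  sums
}

#' Pearson correlation of pseudo-bulk profiles over marker genes
#'
#' For every (query cluster, reference cluster) pair, the Pearson
#' correlation of their pseudo-bulk profiles restricted to a shared marker
#' gene set. Gene identifiers can be harmonized through an explicit mapping
#' table (e.g. cross-species symbol pairs); no implicit orthology inference
#' is attempted. Profiles with zero variance over the markers yield an
#' undefined (`NA`) correlation rather than 0.
#'
#' @param query,reference Clusters x genes profile matrices from
#'   [aggregate_pseudobulk()].
#' @param markers Character vector of marker genes, or a data.frame with a
#'   `gene` column (as from per-cluster marker lists; the union is used).
#' @param mapping Optional data.frame (`query_gene`, `reference_gene`)
#'   translating query gene ids to reference gene ids before intersecting.
#'
#' @return A `similarity_matrix`: query clusters x reference clusters matrix
#'   of correlations in `[-1, 1]` (NA where undefined), with attributes
#'   `markers` (the shared marker genes used, in query id space) and
#'   `n_genes`.
#' @export
marker_correlation <- function(query, reference, markers, mapping = NULL) {
  if (is.data.frame(markers)) {
    if (!"gene" %in% names(markers))
      stop("marker data.frame must have a 'gene' column")
    markers <- markers$gene
  }
  markers <- unique(as.character(markers))
  q_genes <- colnames(query)
  r_genes <- colnames(reference)
  if (is.null(q_genes) || is.null(r_genes))
    stop("profile matrices must have gene column names")

  if (!is.null(mapping)) {
    stopifnot(all(c("query_gene", "reference_gene") %in% names(mapping)))
    ref_as_query <- mapping$query_gene[match(r_genes,
                                             mapping$reference_gene)]
  } else {
    ref_as_query <- r_genes
  }
  shared <- intersect(intersect(markers, q_genes),
                      ref_as_query[!is.na(ref_as_query)])
  if (length(shared) < 3L)
    stop("need >= 3 shared marker genes after harmonization, found ",
         length(shared))

  qm <- query[, shared, drop = FALSE]
  rm_ <- reference[, match(shared, ref_as_query), drop = FALSE]
  sim <- suppressWarnings(stats::cor(t(qm), t(rm_), method = "pearson"))
  dimnames(sim) <- list(rownames(query), rownames(reference))
  structure(sim, markers = shared, n_genes = length(shared),
            class = c("similarity_matrix", "matrix", "array"))
}

#' @exportS3Method base::print
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix: ", nrow(x), " query x ", ncol(x),
      " reference clusters, ", attr(x, "n_genes"), " marker genes\n",
      sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Heatmap of a similarity matrix
#'
#' @param x A `similarity_matrix`.
#' @param ... Passed to [stats::heatmap()].
#' @export
plot.similarity_matrix <- function(x, ...) {
  stats::heatmap(unclass(x), scale = "none", ...)
  invisible(x)
}

#' Best-matching reference cluster per query cluster
#'
#' The argmax over each row of the similarity matrix. Undefined (`NA`)
#' entries are excluded; exact ties are broken by reference column order and
#' flagged.
#'
#' @param sim A [marker_correlation()] result.
#' @return data.frame (`query`, `reference`, `correlation`, `tie`); the
#'   reference is `NA` for a query whose correlations are all undefined.
#' @export
best_match <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (length(sim) == 0L) stop("similarity matrix is empty")
  rows <- lapply(seq_len(nrow(sim)), function(i) {
    v <- sim[i, ]
    if (all(is.na(v)))
      return(data.frame(query = rownames(sim)[i], reference = NA_character_,
                        correlation = NA_real_, tie = FALSE,
                        stringsAsFactors = FALSE))
    best <- max(v, na.rm = TRUE)
    hits <- which(!is.na(v) & v == best)
    data.frame(query = rownames(sim)[i],
               reference = colnames(sim)[hits[1L]],
               correlation = best, tie = length(hits) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
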
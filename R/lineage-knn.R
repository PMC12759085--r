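#' Construct a single-timepoint slice of a time-series single-cell dataset
#'
#' A `timepoint_slice` bundles the cells observed at one developmental stage:
#' their low-dimensional embedding coordinates (for example a batch-corrected
#' PCA or UMAP space shared with an adjacent stage) and their cluster labels.
#' It is the unit consumed by [assign_source_states()] and friends.
#'
#' @param timepoint_label Stage identifier, e.g. an hpf value. Coerced to
#'   character; slices are ordered by the order in which they are supplied to
#'   [chain_timepoints()], not by this label.
#' @param cell_ids Character vector of unique cell identifiers.
#' @param embedding Numeric matrix, cells x D, rows aligned with `cell_ids`.
#' @param cluster_labels Vector (coerced to character) of per-cell cluster
#'   labels, same length as `cell_ids`.
#'
#' @return An object of class `timepoint_slice`.
#' @export
#' @examples
#' sl <- timepoint_slice("6", c("c1", "c2"), rbind(c(0, 0), c(1, 1)),
#'                       c("A", "B"))
#' sl
timepoint_slice <- function(timepoint_label, cell_ids, embedding,
                            cluster_labels) {
  cell_ids <- as.character(cell_ids)
  cluster_labels <- as.character(cluster_labels)
  embedding <- as.matrix(embedding)
  storage.mode(embedding) <- "double"
  if (anyDuplicated(cell_ids))
    stop("cell_ids must be unique within a timepoint_slice")
  if (nrow(embedding) != length(cell_ids))
    stop("embedding must have one row per cell id (",
         nrow(embedding), " rows vs ", length(cell_ids), " ids)")
  if (length(cluster_labels) != length(cell_ids))
    stop("cluster_labels must match cell_ids in length")
  if (ncol(embedding) < 1L) stop("embedding must have at least 1 dimension")
  if (anyNA(embedding)) stop("embedding contains missing values")
  rownames(embedding) <- cell_ids
  structure(
    list(timepoint_label = as.character(timepoint_label)[1L],
         cell_ids = cell_ids,
         embedding = embedding,
         cluster_labels = cluster_labels),
    class = "timepoint_slice"
  )
}

#' @exportS3Method base::print
print.timepoint_slice <- function(x, ...) {
  cat("timepoint_slice '", x$timepoint_label, "': ",
      length(x$cell_ids), " cells, ", ncol(x$embedding), "-D embedding, ",
      length(unique(x$cluster_labels)), " clusters\n", sep = "")
  invisible(x)
}

# Full squared Euclidean cross-distance matrix (rows of a vs rows of b).
# Sizes here are a few thousand cells at most, so the dense O(n m) matrix is
# the right tool; clamping guards tiny negative round-off.
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Assign a source cluster to each later-timepoint cell by KNN
#'
#' For every cell of the later timepoint, finds its `k` nearest cells in the
#' earlier timepoint (Euclidean distance in the shared embedding) and assigns
#' the modal cluster among those neighbors as the cell's source state. When
#' two or more clusters are equally frequent among the neighbors, the cluster
#' of the single nearest neighbor is used and the assignment is flagged
#' `tie_broken`. Exact distance ties at the k-th neighbor are resolved
#' deterministically by ascending cell-id order. If `k` exceeds the number of
#' earlier cells, all earlier cells are used.
#'
#' @param earlier,later [timepoint_slice] objects sharing an embedding space
#'   (same dimensionality and coordinate system, e.g. from a joint
#'   batch-corrected embedding of the two stages).
#' @param k Number of nearest earlier neighbors to vote (default 10).
#'
#' @return A data.frame of class `source_assignment` with one row per later
#'   cell: `later_cell_id`, `assigned_source_cluster`, `tie_broken`, and a
#'   list-column `neighbor_ids` holding the earlier cell ids used.
#' @seealso [build_lineage_graph()], [chain_timepoints()]
#' @export
assign_source_states <- function(earlier, later, k = 10) {
  stopifnot(inherits(earlier, "timepoint_slice"),
            inherits(later, "timepoint_slice"))
  if (length(earlier$cell_ids) < 1L)
    stop("earlier timepoint_slice has no cells")
  if (ncol(earlier$embedding) != ncol(later$embedding))
    stop("embedding dimensionality differs between slices (",
         ncol(earlier$embedding), " vs ", ncol(later$embedding), ")")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")

  n_earlier <- length(earlier$cell_ids)
  k_use <- min(k, n_earlier)

  # order earlier cells by id once so that equal distances break ties by
  # ascending cell id (order() is stable)
  id_rank <- order(earlier$cell_ids)
  emb_e <- earlier$embedding[id_rank, , drop = FALSE]
  ids_e <- earlier$cell_ids[id_rank]
  lab_e <- earlier$cluster_labels[id_rank]

  d2 <- cross_dist2(later$embedding, emb_e)

  res <- vector("list", nrow(d2))
  assigned <- character(nrow(d2))
  tie_broken <- logical(nrow(d2))
  for (i in seq_len(nrow(d2))) {
    ord <- order(d2[i, ])[seq_len(k_use)]
    labs <- lab_e[ord]
    tab <- table(labs)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      assigned[i] <- labs[1L]   # cluster of the single nearest neighbor
      tie_broken[i] <- TRUE
    } else {
      assigned[i] <- top
    }
    res[[i]] <- ids_e[ord]
  }
  out <- data.frame(later_cell_id = later$cell_ids,
                    assigned_source_cluster = assigned,
                    tie_broken = tie_broken,
                    stringsAsFactors = FALSE)
  out$neighbor_ids <- res
  attr(out, "k") <- k
  attr(out, "embedding_dim") <- ncol(earlier$embedding)
  class(out) <- c("source_assignment", "data.frame")
  out
}

#' Build a cluster-level lineage graph from per-cell source assignments
#'
#' Aggregates per-cell source-state assignments into cluster-to-cluster
#' transition fractions: for each pair (earlier cluster c, later cluster c'),
#' the fraction of c' cells whose assigned source is c (denominator: the full
#' size of c', since every later cell receives an assignment). An edge is
#' retained when its fraction is strictly greater than `threshold`; all
#' candidate fractions remain in the edge table for audit.
#'
#' @param assignments Result of [assign_source_states()].
#' @param earlier,later The [timepoint_slice] objects the assignments came
#'   from.
#' @param threshold Retention threshold on the transition fraction, in
#'   `[0, 1)`; default 0.20, kept strictly (a fraction of exactly 0.20 is
#'   dropped).
#'
#' @return A `lineage_graph`: list with `nodes` (data.frame `cluster`,
#'   `timepoint`) and `edges` (data.frame `earlier_cluster`, `earlier_tp`,
#'   `later_cluster`, `later_tp`, `n_cells`, `fraction`, `retained`).
#' @export
build_lineage_graph <- function(assignments, earlier, later,
                                threshold = 0.20) {
  stopifnot(inherits(assignments, "source_assignment"),
            inherits(earlier, "timepoint_slice"),
            inherits(later, "timepoint_slice"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold >= 1)
    stop("threshold must be a single number in [0, 1)")
  if (!all(assignments$later_cell_id %in% later$cell_ids))
    stop("assignments refer to cell ids absent from the later slice")

  later_cluster <- later$cluster_labels[
    match(assignments$later_cell_id, later$cell_ids)]
  counts <- table(earlier_cluster = assignments$assigned_source_cluster,
                  later_cluster = later_cluster)
  cl_sizes <- table(later$cluster_labels)

  edges <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(edges) <- c("earlier_cluster", "later_cluster", "n_cells")
  edges <- edges[edges$n_cells > 0, , drop = FALSE]
  edges$fraction <- edges$n_cells /
    as.numeric(cl_sizes[edges$later_cluster])
  edges$earlier_tp <- earlier$timepoint_label
  edges$later_tp <- later$timepoint_label
  edges$retained <- edges$fraction > threshold
  edges <- edges[, c("earlier_cluster", "earlier_tp", "later_cluster",
                     "later_tp", "n_cells", "fraction", "retained")]
  edges <- edges[order(edges$later_cluster, -edges$fraction,
                       edges$earlier_cluster), , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- unique(rbind(
    data.frame(cluster = sort(unique(earlier$cluster_labels)),
               timepoint = earlier$timepoint_label,
               stringsAsFactors = FALSE),
    data.frame(cluster = sort(unique(later$cluster_labels)),
               timepoint = later$timepoint_label,
               stringsAsFactors = FALSE)))
  rownames(nodes) <- NULL

  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 k = attr(assignments, "k")),
            class = "lineage_graph")
}

#' @exportS3Method base::print
print.lineage_graph <- function(x, ...) {
  cat("lineage_graph: ", nrow(x$nodes), " (cluster, timepoint) nodes, ",
      sum(x$edges$retained), " retained / ", nrow(x$edges),
      " candidate edges (threshold > ", format(x$threshold), ")\n", sep = "")
  invisible(x)
}

#' Chain KNN source-state assignment across an ordered timepoint series
#'
#' Runs [assign_source_states()] and [build_lineage_graph()] on each pair of
#' adjacent timepoints and unions the per-pair graphs. Accepts either an
#' ordered list of [timepoint_slice] objects sharing one embedding space, or
#' a list of adjacent pairs, each `list(earlier = , later = )`, when every
#' pair was embedded separately (as when adjacent stages are batch-integrated
#' pair by pair); [simulate_timepoint_series()] returns the latter form.
#'
#' @param slices Ordered list of `timepoint_slice` objects (earliest first),
#'   or a list of `list(earlier, later)` pairs in stage order.
#' @param k Neighbors per cell (default 10).
#' @param threshold Strict retention threshold on transition fractions
#'   (default 0.20).
#'
#' @return A `lineage_graph` spanning the whole series; its node set covers
#'   every (cluster, timepoint) observed.
#' @export
chain_timepoints <- function(slices, k = 10, threshold = 0.20) {
  if (!is.list(slices)) stop("slices must be a list")
  is_pair <- function(x) is.list(x) && !inherits(x, "timepoint_slice") &&
    all(c("earlier", "later") %in% names(x))
  if (all(vapply(slices, is_pair, logical(1))) && length(slices) >= 1L) {
    pairs <- slices
  } else {
    if (length(slices) < 2L)
      stop("need at least 2 timepoint slices to chain")
    if (!all(vapply(slices, inherits, logical(1), "timepoint_slice")))
      stop("slices must all be timepoint_slice objects")
    pairs <- lapply(seq_len(length(slices) - 1L), function(i)
      list(earlier = slices[[i]], later = slices[[i + 1L]]))
  }

  graphs <- lapply(pairs, function(p) {
    a <- assign_source_states(p$earlier, p$later, k = k)
    build_lineage_graph(a, p$earlier, p$later, threshold = threshold)
  })
  nodes <- unique(do.call(rbind, lapply(graphs, `[[`, "nodes")))
  edges <- do.call(rbind, lapply(graphs, `[[`, "edges"))
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold, k = k),
            class = "lineage_graph")
}

#' Retained edges of a lineage graph
#'
#' @param graph A `lineage_graph`.
#' @return The edge data.frame restricted to retained edges.
#' @export
retained_edges <- function(graph) {
  stopifnot(inherits(graph, "lineage_graph"))
  e <- graph$edges[graph$edges$retained, , drop = FALSE]
  rownames(e) <- NULL
  e
}
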
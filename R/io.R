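#' @importFrom Matrix readMM writeMM
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a timepoint slice to embedding + label TSV files
#'
#' Produces `<prefix>_embedding.tsv` (`cell_id`, `dim_1` ... `dim_D`) and
#' `<prefix>_labels.tsv` (`cell_id`, `cluster`).
#'
#' @param slice A [timepoint_slice].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix; defaults to `tp<label>`.
#' @return Invisibly, the two file paths.
#' @export
write_timepoint_slice <- function(slice, dir, prefix = NULL) {
  stopifnot(inherits(slice, "timepoint_slice"))
  if (is.null(prefix)) prefix <- paste0("tp", slice$timepoint_label)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emb <- as.data.frame(slice$embedding)
  names(emb) <- paste0("dim_", seq_len(ncol(emb)))
  emb <- cbind(cell_id = slice$cell_ids, emb)
  p1 <- file.path(dir, paste0(prefix, "_embedding.tsv"))
  p2 <- file.path(dir, paste0(prefix, "_labels.tsv"))
  write_tsv(emb, p1)
  write_tsv(data.frame(cell_id = slice$cell_ids,
                       cluster = slice$cluster_labels), p2)
  invisible(c(embedding = p1, labels = p2))
}

#' Read a timepoint slice from embedding + label TSV files
#'
#' @param embedding_path TSV with `cell_id` and `dim_*` columns.
#' @param labels_path TSV with `cell_id` and `cluster` columns.
#' @param timepoint_label Stage label for the slice.
#' @return A [timepoint_slice].
#' @export
read_timepoint_slice <- function(embedding_path, labels_path,
                                 timepoint_label) {
  emb <- utils::read.delim(embedding_path, stringsAsFactors = FALSE)
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  dims <- grep("^dim_", names(emb), value = TRUE)
  if (!"cell_id" %in% names(emb) || length(dims) == 0L)
    stop("embedding TSV must have cell_id and dim_* columns")
  if (!all(c("cell_id", "cluster") %in% names(lab)))
    stop("label TSV must have cell_id and cluster columns")
  labels <- lab$cluster[match(emb$cell_id, lab$cell_id)]
  if (anyNA(labels)) stop("label TSV is missing some embedding cell ids")
  timepoint_slice(timepoint_label, emb$cell_id,
                  as.matrix(emb[, dims, drop = FALSE]), labels)
}

#' Write cell tracks to a spots-export style CSV
#'
#' Columns `track_id`, `time_index`, `x`, `y`, `z`, `role`.
#'
#' @param tracks List of [cell_track] objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "cell_track")) tracks <- list(tracks)
  long <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(track_id = tr$track_id,
               tr$samples[, c("time_index", "x", "y", "z")],
               role = tr$role, stringsAsFactors = FALSE)))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cell tracks from a spots-export style CSV
#'
#' Expects columns `track_id`, `time_index`, `x`, `y`, `z` and optionally
#' `role` (defaults to `deep` when absent). Rows may be unsorted; they are
#' ordered by frame within each track.
#'
#' @param path CSV path.
#' @return Named list of [cell_track] objects.
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "time_index", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("track CSV is missing columns: ", paste(miss, collapse = ", "))
  if (!"role" %in% names(df)) df$role <- "deep"
  out <- lapply(split(df, df$track_id), function(part) {
    part <- part[order(part$time_index), , drop = FALSE]
    cell_track(part$track_id[1L], part$time_index, part$x, part$y, part$z,
               role = part$role[1L])
  })
  out[unique(df$track_id)]
}

#' Write a cluster-labeled expression dataset as Matrix Market + sidecars
#'
#' Writes `matrix.mtx` (genes x cells, sparse), `genes.tsv` (one gene id per
#' line), `cells.tsv` (one cell id per line) and `labels.tsv`
#' (`cell_id`, `cluster`).
#'
#' @param input A [pseudobulk_input].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_pseudobulk_input <- function(input, dir) {
  stopifnot(inherits(input, "pseudobulk_input"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(Matrix::Matrix(t(as.matrix(input$expression)),
                                              sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  cells <- rownames(input$expression)
  if (is.null(cells)) cells <- sprintf("cell%05d", seq_len(nrow(input$expression)))
  writeLines(input$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(cells, file.path(dir, "cells.tsv"))
  write_tsv(data.frame(cell_id = cells, cluster = input$cluster_labels),
            file.path(dir, "labels.tsv"))
  invisible(dir)
}

#' Read a cluster-labeled expression dataset from Matrix Market + sidecars
#'
#' Counterpart of [write_pseudobulk_input()].
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`,
#'   `labels.tsv`.
#' @return A [pseudobulk_input].
#' @export
read_pseudobulk_input <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "cells.tsv"))
  lab <- utils::read.delim(file.path(dir, "labels.tsv"),
                           stringsAsFactors = FALSE)
  if (nrow(m) != length(genes))
    stop("matrix.mtx row count does not match genes.tsv")
  if (ncol(m) != length(cells))
    stop("matrix.mtx column count does not match cells.tsv")
  expr <- t(as.matrix(m))
  rownames(expr) <- cells
  labels <- lab$cluster[match(cells, lab$cell_id)]
  if (anyNA(labels)) stop("labels.tsv is missing some cell ids")
  pseudobulk_input(expr, labels, genes)
}

#' Write the edge table of a lineage graph as TSV
#'
#' All candidate edges with their fractions and retention flags, for audit.
#'
#' @param graph A `lineage_graph`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_lineage_edges <- function(graph, path) {
  stopifnot(inherits(graph, "lineage_graph"))
  write_tsv(graph$edges, path)
}

#' Serialize a lineage graph to JSON
#'
#' @param graph A `lineage_graph`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
lineage_to_json <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "lineage_graph"))
  js <- jsonlite::toJSON(list(nodes = graph$nodes, edges = graph$edges,
                              threshold = graph$threshold, k = graph$k),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Serialize the retained edges of a lineage graph as Graphviz DOT
#'
#' Node names are `cluster@timepoint`; edge labels carry the transition
#' fraction.
#'
#' @param graph A `lineage_graph`.
#' @param path Optional output path; when `NULL` the DOT string is returned.
#' @return The DOT string (invisibly when written to `path`).
#' @export
lineage_to_dot <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "lineage_graph"))
  node_name <- function(cl, tp) paste0("\"", cl, "@", tp, "\"")
  e <- retained_edges(graph)
  lines <- c("digraph lineage {",
             "  rankdir=LR;",
             paste0("  ", node_name(graph$nodes$cluster,
                                    graph$nodes$timepoint), ";"),
             sprintf("  %s -> %s [label=\"%.3f\"];",
                     node_name(e$earlier_cluster, e$earlier_tp),
                     node_name(e$later_cluster, e$later_tp), e$fraction),
             "}")
  dot <- paste(lines, collapse = "\n")
  if (is.null(path)) return(dot)
  writeLines(dot, path)
  invisible(dot)
}

#' Write a trajectory decomposition table as TSV
#'
#' @param decompositions A single `trajectory_decomposition` or a list of
#'   them (as from [decompose_tracks()]).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_decomposition_tsv <- function(decompositions, path) {
  if (inherits(decompositions, "trajectory_decomposition"))
    decompositions <- list(decompositions)
  long <- do.call(rbind, lapply(decompositions, function(d)
    cbind(track_id = attr(d, "track_id"), as.data.frame(d))))
  write_tsv(long, path)
}
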
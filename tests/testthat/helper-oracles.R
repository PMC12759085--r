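# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive every quantity with naive loops, not via the
# package's own code paths.

make_slice <- function(label, positions, clusters, ids = NULL) {
  positions <- as.matrix(positions)
  if (is.null(ids)) ids <- sprintf("%s_%03d", label, seq_len(nrow(positions)))
  timepoint_slice(label, ids, positions, clusters)
}

random_slice <- function(label, n, n_clusters, dim = 2) {
  make_slice(label,
             matrix(runif(n * dim, 0, 10), n, dim),
             sample(paste0("K", seq_len(n_clusters)), n, replace = TRUE))
}

# O(n^2) KNN source-state oracle: per later cell, full distance scan,
# order by (distance, earlier cell id), modal vote, nearest-spot tie rule.
oracle_assignments <- function(earlier, later, k) {
  n_l <- length(later$cell_ids)
  assigned <- character(n_l)
  tie <- logical(n_l)
  neigh <- vector("list", n_l)
  for (i in seq_len(n_l)) {
    d <- numeric(length(earlier$cell_ids))
    for (j in seq_along(d))
      d[j] <- sqrt(sum((later$embedding[i, ] - earlier$embedding[j, ])^2))
    ord <- order(d, earlier$cell_ids)[seq_len(min(k, length(d)))]
    labs <- earlier$cluster_labels[ord]
    freq <- table(labs)
    winners <- names(freq)[freq == max(freq)]
    if (length(winners) > 1L) {
      assigned[i] <- labs[1L]
      tie[i] <- TRUE
    } else assigned[i] <- winners
    neigh[[i]] <- earlier$cell_ids[ord]
  }
  list(assigned = assigned, tie_broken = tie, neighbor_ids = neigh)
}

# cluster-by-cluster edge fractions by direct counting
oracle_edges <- function(assigned, earlier, later, threshold) {
  out <- NULL
  for (cl in unique(later$cluster_labels)) {
    members <- which(later$cluster_labels == cl)
    for (src in unique(assigned[members])) {
      n <- sum(assigned[members] == src)
      out <- rbind(out, data.frame(
        earlier_cluster = src, later_cluster = cl, n_cells = n,
        fraction = n / length(members),
        retained = n / length(members) > threshold,
        stringsAsFactors = FALSE))
    }
  }
  out[order(out$earlier_cluster, out$later_cluster), , drop = FALSE]
}

# naive pairwise neighbor sets
oracle_neighbors <- function(frame, radius) {
  ids <- as.character(frame$cell_id)
  pos <- as.matrix(frame[, c("x", "y", "z")])
  out <- list()
  for (i in seq_along(ids)) {
    hits <- character(0)
    for (j in seq_along(ids)) {
      if (i == j) next
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) <= radius)
        hits <- c(hits, ids[j])
    }
    out[[ids[i]]] <- hits
  }
  out
}

# textbook one-way ANOVA F from sums of squares
oracle_anova_F <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  k <- length(groups)
  n <- length(all_v)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# naive angle binning over [0, 360), right-open equal bins
oracle_direction_counts <- function(disp2d, bins) {
  counts <- integer(bins)
  edges <- seq(0, 360, length.out = bins + 1L)
  for (i in seq_len(nrow(disp2d))) {
    v <- disp2d[i, ]
    if (sqrt(sum(v^2)) == 0) next
    a <- (atan2(v[2L], v[1L]) * 180 / pi) %% 360
    for (b in seq_len(bins)) {
      if (a >= edges[b] && a < edges[b + 1L]) {
        counts[b] <- counts[b] + 1L
        break
      }
    }
  }
  counts
}

edge_key <- function(e)
  paste(e$earlier_cluster, e$earlier_tp, e$later_cluster, e$later_tp)
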
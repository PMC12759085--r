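#' Specification for a synthetic time-series single-cell simulation
#'
#' Defines the study conditions for [simulate_timepoint_series()]: a series
#' of timepoints, each holding the same number of Gaussian-blob clusters in a
#' low-dimensional embedding, with a known row-stochastic cluster-to-cluster
#' transition matrix (rows = later clusters, columns = earlier clusters: the
#' fraction of each later cluster's cells whose parent population is each
#' earlier cluster).
#'
#' The default transition matrix mimics progressive differentiation among
#' four populations, with both merging and branching and two entries at
#' exactly 0.20 (useful for exercising the strict retention rule):
#' \preformatted{
#'        C1   C2   C3   C4
#'   C1' 0.5  0.3  0.2  0.0
#'   C2' 0.0  0.6  0.2  0.2
#'   C3' 0.0  0.0  0.8  0.2
#'   C4' 0.0  0.0  0.0  1.0
#' }
#'
#' @param n_timepoints Number of stages (default 6).
#' @param clusters_per_timepoint Clusters per stage (default 4).
#' @param cells_per_cluster Cells per cluster per stage (default 100).
#' @param embedding_dim Embedding dimensionality (default 2).
#' @param cluster_separation Distance between adjacent cluster centers in
#'   embedding units (default 10).
#' @param cluster_sd Isotropic within-cluster standard deviation (default 1).
#' @param transition_matrix Row-stochastic K x K matrix as described above;
#'   `NULL` selects the default (requires `clusters_per_timepoint = 4`).
#' @param seed Integer seed; the simulation is fully reproducible from it.
#'
#' @return A validated list of class `time_series_sim_spec`.
#' @export
time_series_sim_spec <- function(n_timepoints = 6,
                                 clusters_per_timepoint = 4,
                                 cells_per_cluster = 100,
                                 embedding_dim = 2,
                                 cluster_separation = 10,
                                 cluster_sd = 1,
                                 transition_matrix = NULL,
                                 seed = 1) {
  K <- as.integer(clusters_per_timepoint)
  if (is.null(transition_matrix)) {
    if (K != 4L)
      stop("transition_matrix: no default for clusters_per_timepoint != 4; ",
           "supply one explicitly")
    transition_matrix <- rbind(c(0.5, 0.3, 0.2, 0.0),
                               c(0.0, 0.6, 0.2, 0.2),
                               c(0.0, 0.0, 0.8, 0.2),
                               c(0.0, 0.0, 0.0, 1.0))
  }
  transition_matrix <- as.matrix(transition_matrix)
  spec <- list(n_timepoints = as.integer(n_timepoints),
               clusters_per_timepoint = K,
               cells_per_cluster = as.integer(cells_per_cluster),
               embedding_dim = as.integer(embedding_dim),
               cluster_separation = as.numeric(cluster_separation),
               cluster_sd = as.numeric(cluster_sd),
               transition_matrix = transition_matrix,
               seed = as.integer(seed))
  validate_time_series_sim_spec(spec)
  class(spec) <- "time_series_sim_spec"
  spec
}

validate_time_series_sim_spec <- function(spec) {
  if (is.na(spec$n_timepoints) || spec$n_timepoints < 2L)
    stop("n_timepoints: must be an integer >= 2")
  if (is.na(spec$clusters_per_timepoint) || spec$clusters_per_timepoint < 1L)
    stop("clusters_per_timepoint: must be an integer >= 1")
  if (is.na(spec$cells_per_cluster) || spec$cells_per_cluster < 1L)
    stop("cells_per_cluster: must be an integer >= 1")
  if (is.na(spec$embedding_dim) || spec$embedding_dim < 2L)
    stop("embedding_dim: must be an integer >= 2")
  if (!is.finite(spec$cluster_sd) || spec$cluster_sd <= 0)
    stop("cluster_sd: must be > 0")
  if (!is.finite(spec$cluster_separation) || spec$cluster_separation <= 0)
    stop("cluster_separation: must be > 0")
  P <- spec$transition_matrix
  K <- spec$clusters_per_timepoint
  if (!is.numeric(P) || nrow(P) != K || ncol(P) != K)
    stop("transition_matrix: must be a numeric ", K, " x ", K, " matrix")
  if (any(P < 0))
    stop("transition_matrix: entries must be non-negative")
  if (any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition_matrix: each row must sum to 1 (tolerance 1e-9)")
  invisible(spec)
}

# Apportion n into integer counts proportional to p (sum(p) = 1) by the
# largest-remainder rule; ties go to the lower index. Guarantees
# sum(counts) == n, so realized transition fractions match p exactly when
# n * p is integral.
largest_remainder <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    give <- order(-frac, seq_along(p))[seq_len(rem)]
    counts[give] <- counts[give] + 1L
  }
  as.integer(counts)
}

# Well-separated cluster centers: K points on a circle whose adjacent chord
# length equals `separation`, embedded in the first two of `dim` coordinates.
cluster_centers <- function(K, separation, dim) {
  centers <- matrix(0, K, dim)
  if (K > 1L) {
    R <- separation / (2 * sin(pi / K))
    ang <- 2 * pi * (seq_len(K) - 1L) / K
    centers[, 1L] <- R * cos(ang)
    centers[, 2L] <- R * sin(ang)
  }
  centers
}

#' Simulate a clustered time-series with a known lineage ground truth
#'
#' Generates, for each pair of adjacent timepoints, a shared embedding in
#' which the earlier stage's clusters sit at well-separated centers and each
#' later cell is drawn around the center of its assigned parent cluster.
#' Parent populations are apportioned by exact largest-remainder counts from
#' the transition matrix, so the realized transition fractions equal the
#' matrix entries whenever `cells_per_cluster * entry` is integral. Each
#' adjacent pair has its own embedding space — mirroring pipelines that
#' batch-integrate adjacent stages pair by pair — so a given timepoint's
#' coordinates differ between the pair where it is the later member and the
#' pair where it is the earlier member; cell ids, cluster labels and parent
#' assignments are consistent throughout.
#'
#' @param spec A [time_series_sim_spec()].
#'
#' @return A list with elements
#'   \describe{
#'     \item{pairs}{list of `list(earlier, later)` [timepoint_slice] pairs in
#'       stage order, directly consumable by [chain_timepoints()];}
#'     \item{truth}{a `lineage_graph` whose edges carry the exact realized
#'       parent fractions (all positive-fraction edges, `threshold = 0`);}
#'     \item{assignments}{data.frame of the generator's per-cell parent
#'       bookkeeping (`timepoint`, `cell_id`, `cluster`, `parent_cluster`),
#'       from which the truth edges are recomputable by counting;}
#'     \item{spec}{the input spec.}
#'   }
#' @export
#' @examples
#' sim <- simulate_timepoint_series(time_series_sim_spec(
#'   n_timepoints = 3, cells_per_cluster = 20, seed = 42))
#' g <- chain_timepoints(sim$pairs, k = 10, threshold = 0.2)
#' retained_edges(g)
simulate_timepoint_series <- function(spec) {
  if (!inherits(spec, "time_series_sim_spec"))
    spec <- do.call(time_series_sim_spec, spec)
  validate_time_series_sim_spec(spec)
  set.seed(spec$seed)

  K <- spec$clusters_per_timepoint
  m <- spec$cells_per_cluster
  Tn <- spec$n_timepoints
  D <- spec$embedding_dim
  P <- spec$transition_matrix
  centers <- cluster_centers(K, spec$cluster_separation, D)
  cl_names <- paste0("C", seq_len(K))

  cell_ids <- lapply(seq_len(Tn), function(t)
    sprintf("t%d_c%04d", t, seq_len(K * m)))
  labels <- rep(cl_names, each = m)   # same layout every timepoint

  # parent cluster per cell, for timepoints 2..Tn (largest-remainder counts)
  parents <- vector("list", Tn)
  for (t in 2:Tn) {
    parents[[t]] <- unlist(lapply(seq_len(K), function(kk) {
      cnt <- largest_remainder(P[kk, ], m)
      rep(cl_names, cnt)
    }), use.names = FALSE)
  }

  noise <- function(n) matrix(stats::rnorm(n * D, sd = spec$cluster_sd), n, D)

  pairs <- vector("list", Tn - 1L)
  for (t in seq_len(Tn - 1L)) {
    emb_e <- centers[match(labels, cl_names), , drop = FALSE] + noise(K * m)
    earlier <- timepoint_slice(as.character(t), cell_ids[[t]], emb_e, labels)
    par_t1 <- parents[[t + 1L]]
    emb_l <- centers[match(par_t1, cl_names), , drop = FALSE] + noise(K * m)
    later <- timepoint_slice(as.character(t + 1L), cell_ids[[t + 1L]],
                             emb_l, labels)
    pairs[[t]] <- list(earlier = earlier, later = later)
  }

  assignments <- do.call(rbind, lapply(2:Tn, function(t)
    data.frame(timepoint = as.character(t), cell_id = cell_ids[[t]],
               cluster = labels, parent_cluster = parents[[t]],
               stringsAsFactors = FALSE)))

  edges <- do.call(rbind, lapply(2:Tn, function(t) {
    tab <- table(parent = parents[[t]], cluster = labels)
    e <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(e) <- c("earlier_cluster", "later_cluster", "n_cells")
    e <- e[e$n_cells > 0, , drop = FALSE]
    e$fraction <- e$n_cells / m
    e$earlier_tp <- as.character(t - 1L)
    e$later_tp <- as.character(t)
    e[, c("earlier_cluster", "earlier_tp", "later_cluster", "later_tp",
          "n_cells", "fraction")]
  }))
  edges$retained <- edges$fraction > 0
  rownames(edges) <- NULL
  nodes <- expand.grid(cluster = cl_names,
                       timepoint = as.character(seq_len(Tn)),
                       stringsAsFactors = FALSE)
  truth <- structure(list(nodes = nodes, edges = edges, threshold = 0,
                          k = NA_integer_),
                     class = "lineage_graph")

  list(pairs = pairs, truth = truth, assignments = assignments, spec = spec)
}

#' Specification for a synthetic explant track simulation
#'
#' Conditions for [simulate_explant_tracks()]: an elongating tissue in which
#' anchor cells (the non-migrating outer epithelial layer) follow the shared
#' elongation drift only, while deep cells add a circular migration in the
#' plane orthogonal to the elongation axis — emulating the local rotational
#' movements of tailbud progenitors. Frames default to a 3-minute imaging
#' cadence; coordinates are micrometres.
#'
#' @param n_anchor Number of anchor tracks (>= 3; default 3).
#' @param n_deep Number of deep-cell tracks (default 20).
#' @param n_frames Frames per track (default 60, i.e. 3 h at 3 min/frame).
#' @param frame_interval Minutes per frame (default 3).
#' @param elongation_velocity Length-3 drift vector, um/frame
#'   (default `c(0.5, 0, 0)`).
#' @param rotation_radius Radius of the deep-cell migration circle, um
#'   (default 10).
#' @param rotation_period Frames per full rotation (default 20, about 1 h).
#' @param noise_sd Isotropic Gaussian positional noise per coordinate, um
#'   (default 0.5).
#' @param seed Integer seed.
#'
#' @return A validated list of class `track_sim_spec`.
#' @export
track_sim_spec <- function(n_anchor = 3, n_deep = 20, n_frames = 60,
                           frame_interval = 3,
                           elongation_velocity = c(0.5, 0, 0),
                           rotation_radius = 10, rotation_period = 20,
                           noise_sd = 0.5, seed = 1) {
  spec <- list(n_anchor = as.integer(n_anchor),
               n_deep = as.integer(n_deep),
               n_frames = as.integer(n_frames),
               frame_interval = as.numeric(frame_interval),
               elongation_velocity = as.numeric(elongation_velocity),
               rotation_radius = as.numeric(rotation_radius),
               rotation_period = as.numeric(rotation_period),
               noise_sd = as.numeric(noise_sd),
               seed = as.integer(seed))
  if (is.na(spec$n_anchor) || spec$n_anchor < 3L)
    stop("n_anchor: need at least 3 anchor cells (the decomposition ",
         "requires >= 3)")
  if (spec$n_deep < 0L) stop("n_deep: must be >= 0")
  if (spec$n_frames < 2L) stop("n_frames: must be >= 2")
  if (length(spec$elongation_velocity) != 3L)
    stop("elongation_velocity: must be a length-3 vector")
  if (!is.finite(spec$rotation_radius) || spec$rotation_radius < 0)
    stop("rotation_radius: must be >= 0")
  if (spec$rotation_period <= 0) stop("rotation_period: must be > 0")
  if (!is.finite(spec$noise_sd) || spec$noise_sd < 0)
    stop("noise_sd: must be >= 0")
  class(spec) <- "track_sim_spec"
  spec
}

# Orthonormal basis (u, v) of the plane orthogonal to e; xy plane if e ~ 0.
rotation_plane_basis <- function(e) {
  if (sqrt(sum(e^2)) < 1e-12)
    return(list(u = c(1, 0, 0), v = c(0, 1, 0)))
  e <- e / sqrt(sum(e^2))
  ref <- if (abs(e[3L]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  u <- c(e[2L] * ref[3L] - e[3L] * ref[2L],
         e[3L] * ref[1L] - e[1L] * ref[3L],
         e[1L] * ref[2L] - e[2L] * ref[1L])
  u <- u / sqrt(sum(u^2))
  v <- c(e[2L] * u[3L] - e[3L] * u[2L],
         e[3L] * u[1L] - e[1L] * u[3L],
         e[1L] * u[2L] - e[2L] * u[1L])
  list(u = u, v = v / sqrt(sum(v^2)))
}

#' Simulate 3D tracks of an elongating explant with migrating deep cells
#'
#' Anchor tracks follow `start + t * elongation_velocity + noise`; deep
#' tracks add a circle of `rotation_radius` (period `rotation_period` frames,
#' random phase per cell) in the plane orthogonal to the elongation axis.
#' The noiseless ground-truth components are returned alongside the observed
#' tracks.
#'
#' @param spec A [track_sim_spec()].
#'
#' @return A list with elements
#'   \describe{
#'     \item{tracks}{list of [cell_track] objects (roles `anchor`/`deep`);}
#'     \item{et_true}{data.frame (`time_index`, `x`, `y`, `z`): the noiseless
#'       anchor-centroid elongation trajectory;}
#'     \item{mt_true}{named list (by deep track id) of noiseless migration
#'       trajectories, each starting at the cell's start position;}
#'     \item{spec}{the input spec.}
#'   }
#' @export
simulate_explant_tracks <- function(spec) {
  if (!inherits(spec, "track_sim_spec")) spec <- do.call(track_sim_spec, spec)
  set.seed(spec$seed)

  tt <- 0:(spec$n_frames - 1L)
  drift <- outer(tt, spec$elongation_velocity)   # frames x 3
  basis <- rotation_plane_basis(spec$elongation_velocity)

  noise <- function() matrix(stats::rnorm(length(tt) * 3L,
                                          sd = spec$noise_sd),
                             ncol = 3L)
  rand_start <- function() stats::runif(3L, 0, 50)

  tracks <- list()
  anchor_true <- vector("list", spec$n_anchor)
  for (i in seq_len(spec$n_anchor)) {
    s <- rand_start()
    true_pos <- sweep(drift, 2L, s, "+")
    anchor_true[[i]] <- true_pos
    pos <- true_pos + noise()
    tracks[[paste0("A", i)]] <- cell_track(
      paste0("A", i), tt, pos[, 1L], pos[, 2L], pos[, 3L], role = "anchor")
  }
  centroid_true <- Reduce(`+`, anchor_true) / spec$n_anchor
  et_true <- data.frame(time_index = tt, x = centroid_true[, 1L],
                        y = centroid_true[, 2L], z = centroid_true[, 3L])

  mt_true <- list()
  for (i in seq_len(spec$n_deep)) {
    s <- rand_start()
    phase <- stats::runif(1L, 0, 2 * pi)
    theta <- phase + 2 * pi * tt / spec$rotation_period
    circ <- spec$rotation_radius *
      (outer(cos(theta), basis$u) + outer(sin(theta), basis$v))
    circ <- sweep(circ, 2L, circ[1L, ], "-")   # migration starts at 0
    mt <- sweep(circ, 2L, s, "+")
    id <- paste0("D", i)
    mt_true[[id]] <- data.frame(time_index = tt, x = mt[, 1L],
                                y = mt[, 2L], z = mt[, 3L])
    pos <- mt + drift + noise()
    tracks[[id]] <- cell_track(id, tt, pos[, 1L], pos[, 2L], pos[, 3L],
                               role = "deep")
  }

  list(tracks = tracks, et_true = et_true, mt_true = mt_true, spec = spec)
}

#' Simulate a matched query/reference expression-dataset pair
#'
#' Builds two cluster-labeled expression datasets sharing the same marker
#' structure: cluster k in either dataset up-regulates its own disjoint block
#' of `markers_per_cluster` genes by `marker_effect` above `base_level`, plus
#' independent Gaussian noise (clamped at zero to keep expression
#' non-negative). The true query-to-reference correspondence is the identity.
#'
#' @param n_clusters Clusters in each dataset.
#' @param n_genes Total genes (must be at least
#'   `n_clusters * markers_per_cluster`).
#' @param markers_per_cluster Marker genes per cluster.
#' @param noise_sd Gaussian noise standard deviation on expression values.
#' @param seed Integer seed.
#' @param cells_per_cluster Cells per cluster in each dataset (default 30).
#' @param base_level Baseline expression (default 1).
#' @param marker_effect Marker up-regulation above baseline (default 5).
#'
#' @return A list with `query` and `reference` [pseudobulk_input] objects,
#'   `markers` (data.frame `cluster`, `gene`), and `correspondence`
#'   (data.frame `query`, `reference`; the identity).
#' @export
simulate_expression_pair <- function(n_clusters, n_genes,
                                     markers_per_cluster, noise_sd, seed,
                                     cells_per_cluster = 30,
                                     base_level = 1, marker_effect = 5) {
  n_clusters <- as.integer(n_clusters)
  n_genes <- as.integer(n_genes)
  markers_per_cluster <- as.integer(markers_per_cluster)
  if (markers_per_cluster * n_clusters > n_genes)
    stop("marker blocks exceed gene count: need n_genes >= ",
         markers_per_cluster * n_clusters)
  set.seed(as.integer(seed))

  genes <- sprintf("g%04d", seq_len(n_genes))
  cl_names <- paste0("C", seq_len(n_clusters))
  marker_idx <- lapply(seq_len(n_clusters), function(k)
    ((k - 1L) * markers_per_cluster + 1L):(k * markers_per_cluster))
  markers <- data.frame(
    cluster = rep(cl_names, each = markers_per_cluster),
    gene = genes[unlist(marker_idx)],
    stringsAsFactors = FALSE)

  means <- matrix(base_level, n_clusters, n_genes)
  for (k in seq_len(n_clusters))
    means[k, marker_idx[[k]]] <- base_level + marker_effect

  make_one <- function(prefix) {
    labels <- rep(cl_names, each = cells_per_cluster)
    n_cells <- length(labels)
    expr <- means[match(labels, cl_names), , drop = FALSE] +
      matrix(stats::rnorm(n_cells * n_genes, sd = noise_sd),
             n_cells, n_genes)
    expr <- pmax(expr, 0)
    rownames(expr) <- sprintf("%s_cell%04d", prefix, seq_len(n_cells))
    colnames(expr) <- genes
    pseudobulk_input(expr, labels, genes)
  }

  list(query = make_one("q"), reference = make_one("r"), markers = markers,
       correspondence = data.frame(query = cl_names, reference = cl_names,
                                   stringsAsFactors = FALSE))
}

#' Simulate Brownian cell positions as tracks
#'
#' Independent 3D random walks (Gaussian increments) from uniform starts in
#' a cube — a null model of purely dispersive movement used to probe how
#' neighbor retention decays with interval length.
#'
#' @param n_cells Number of cells.
#' @param n_frames Frames per track.
#' @param step_sd Per-coordinate step standard deviation, um/frame.
#' @param box Side of the starting cube, um (default 50).
#' @param seed Integer seed.
#'
#' @return A list of [cell_track] objects (role `deep`).
#' @export
simulate_brownian_tracks <- function(n_cells, n_frames, step_sd, box = 50,
                                     seed = 1) {
  set.seed(as.integer(seed))
  tt <- 0:(n_frames - 1L)
  out <- list()
  for (i in seq_len(n_cells)) {
    steps <- matrix(stats::rnorm((n_frames - 1L) * 3L, sd = step_sd),
                    ncol = 3L)
    pos <- rbind(stats::runif(3L, 0, box), steps)
    pos <- apply(pos, 2L, cumsum)
    id <- sprintf("B%03d", i)
    out[[id]] <- cell_track(id, tt, pos[, 1L], pos[, 2L], pos[, 3L],
                            role = "deep")
  }
  out
}
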
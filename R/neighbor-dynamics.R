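#' Per-frame cell positions from a set of tracks
#'
#' Reshapes a list of [cell_track] objects into per-frame position tables,
#' the input of [find_neighbors()] and [neighbor_rate()].
#'
#' @param tracks List of [cell_track] objects.
#' @return Named list (by frame index, as character) of data.frames
#'   (`cell_id`, `x`, `y`, `z`); each carries a `time_index` attribute.
#' @export
tracks_to_frames <- function(tracks) {
  if (inherits(tracks, "cell_track")) tracks <- list(tracks)
  stopifnot(all(vapply(tracks, inherits, logical(1), "cell_track")))
  long <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(cell_id = tr$track_id, tr$samples[, c("time_index", "x",
                                                     "y", "z")],
               stringsAsFactors = FALSE)))
  frames <- split(long[, c("cell_id", "x", "y", "z")], long$time_index)
  for (nm in names(frames)) {
    rownames(frames[[nm]]) <- NULL
    attr(frames[[nm]], "time_index") <- as.integer(nm)
  }
  frames
}

#' Neighboring cells within a fixed radius
#'
#' Neighbors of a cell are all other cells at Euclidean distance less than
#' or equal to `radius` (boundary inclusive) in the same frame; the relation
#' is symmetric and never includes the cell itself. The 15 um default is a
#' typical one-to-two cell-diameter contact radius.
#'
#' @param frame A data.frame (`cell_id`, `x`, `y`, `z`), e.g. one element of
#'   [tracks_to_frames()].
#' @param radius Neighborhood radius in the coordinate units, > 0
#'   (default 15).
#'
#' @return Named list: for each cell id, the character vector of its
#'   neighbors' ids.
#' @export
find_neighbors <- function(frame, radius = 15) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("radius must be a single positive number")
  stopifnot(is.data.frame(frame),
            all(c("cell_id", "x", "y", "z") %in% names(frame)))
  ids <- as.character(frame$cell_id)
  if (anyDuplicated(ids)) stop("cell ids must be unique within a frame")
  pos <- as.matrix(frame[, c("x", "y", "z")])
  d2 <- cross_dist2(pos, pos)
  within <- d2 <= radius^2
  diag(within) <- FALSE
  out <- lapply(seq_along(ids), function(i) ids[within[i, ]])
  names(out) <- ids
  out
}

#' Shared-neighbor retention rate between two timepoints
#'
#' For every cell present in both frames, computes its neighbor set at each
#' timepoint (fresh, from the cells present in that frame) and the rate
#' \eqn{|N_{t_\mathrm{start}} \cap N_{t_\mathrm{end}}| /
#' |N_{t_\mathrm{start}}|}: the fraction of a cell's initial neighbors it
#' still has at the later timepoint. A rate of 1 means fully conserved
#' neighborhoods (collective movement); low rates mean neighbor exchange
#' (dispersive movement). Cells with no neighbor at `t_start` have an
#' undefined rate; they are excluded from the table and tallied in the
#' `n_isolated` attribute.
#'
#' @param frames Named list of frames from [tracks_to_frames()], or a list
#'   of [cell_track] objects (converted automatically).
#' @param t_start,t_end Frame indices of the interval.
#' @param radius Neighborhood radius (default 15).
#'
#' @return A data.frame of class `neighbor_rate_table` with columns
#'   `cell_id`, `t_start`, `t_end`, `n_neighbors_start`, `n_shared`, `rate`,
#'   and attributes `n_isolated` / `isolated_ids`.
#' @export
neighbor_rate <- function(frames, t_start, t_end, radius = 15) {
  if (is.list(frames) && length(frames) &&
      inherits(frames[[1L]], "cell_track"))
    frames <- tracks_to_frames(frames)
  fs <- frames[[as.character(t_start)]]
  fe <- frames[[as.character(t_end)]]
  if (is.null(fs)) stop("no frame at t_start = ", t_start)
  if (is.null(fe)) stop("no frame at t_end = ", t_end)

  ns <- find_neighbors(fs, radius)
  ne <- find_neighbors(fe, radius)
  common <- intersect(names(ns), names(ne))

  n_start <- lengths(ns[common])
  isolated <- common[n_start == 0L]
  keep <- common[n_start > 0L]
  shared <- vapply(keep, function(id)
    length(intersect(ns[[id]], ne[[id]])), integer(1))

  out <- data.frame(cell_id = keep,
                    t_start = rep(as.integer(t_start), length(keep)),
                    t_end = rep(as.integer(t_end), length(keep)),
                    n_neighbors_start = as.integer(n_start[keep]),
                    n_shared = as.integer(shared),
                    rate = as.numeric(shared / n_start[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "radius") <- radius
  attr(out, "n_isolated") <- length(isolated)
  attr(out, "isolated_ids") <- isolated
  class(out) <- c("neighbor_rate_table", "data.frame")
  out
}

#' Compare neighbor-retention rates across interval groups
#'
#' Group means and standard deviations, an omnibus one-way ANOVA, and Tukey
#' HSD pairwise comparisons with adjusted p-values — the standard analysis
#' for asking whether neighbor retention differs between short and long
#' intervals (e.g. frames 1-5 vs 1-10 vs 1-20 vs 1-44).
#'
#' @param values Either a named list of numeric vectors (one per group) or a
#'   data.frame with columns `value` and `group` (e.g. stacked
#'   [neighbor_rate()] `rate` columns labeled by interval).
#'
#' @return A list of class `interval_group_comparison`: `group_stats`
#'   (data.frame `group`, `n`, `mean`, `sd`), `anova` (list `F`, `p`,
#'   `df_between`, `df_within`), and `tukey` (data.frame `comparison`,
#'   `diff`, `lwr`, `upr`, `p_adj`).
#' @export
compare_interval_groups <- function(values) {
  if (is.data.frame(values)) {
    stopifnot(all(c("value", "group") %in% names(values)))
    df <- data.frame(value = as.numeric(values$value),
                     group = as.character(values$group),
                     stringsAsFactors = FALSE)
  } else if (is.list(values)) {
    if (is.null(names(values)) || any(names(values) == ""))
      stop("group list must be named")
    df <- data.frame(
      value = unlist(values, use.names = FALSE),
      group = rep(names(values), lengths(values)),
      stringsAsFactors = FALSE)
  } else stop("values must be a named list or a value/group data.frame")

  sizes <- table(df$group)
  if (length(sizes) < 2L)
    stop("need at least 2 groups, got ", length(sizes))
  if (any(sizes < 2L))
    stop("every group needs >= 2 observations; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))

  df$group <- factor(df$group)
  fit <- stats::aov(value ~ group, data = df)
  s <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      stringsAsFactors = FALSE)
  rownames(tukey) <- NULL

  gs <- do.call(rbind, lapply(levels(df$group), function(g) {
    v <- df$value[df$group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = stats::sd(v), stringsAsFactors = FALSE)
  }))

  structure(list(group_stats = gs,
                 anova = list(F = s[["F value"]][1L],
                              p = s[["Pr(>F)"]][1L],
                              df_between = s[["Df"]][1L],
                              df_within = s[["Df"]][2L]),
                 tukey = tukey),
            class = "interval_group_comparison")
}

#' @exportS3Method base::print
print.interval_group_comparison <- function(x, ...) {
  cat("one-way ANOVA: F(", x$anova$df_between, ", ", x$anova$df_within,
      ") = ", format(x$anova$F, digits = 5), ", p = ",
      format.pval(x$anova$p, digits = 4), "\n", sep = "")
  print(x$group_stats, row.names = FALSE)
  cat("Tukey HSD:\n")
  print(x$tukey, row.names = FALSE)
  invisible(x)
}
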
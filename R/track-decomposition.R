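#' Construct a 3D cell track
#'
#' One cell's time-ordered 3D positions, as exported from a spot-tracking
#' tool (track id, frame index, x/y/z in micrometres), with an optional role
#' flag distinguishing anchor cells (non-migrating outer epithelial cells
#' that report tissue elongation) from deep cells. Frames may be missing
#' (trackers tolerate gaps); see [resample_gaps()].
#'
#' @param track_id Track identifier (coerced to character).
#' @param time_index Integer frame indices, strictly increasing.
#' @param x,y,z Numeric coordinates, same length as `time_index`.
#' @param role `"anchor"` or `"deep"` (default `"deep"`).
#'
#' @return An object of class `cell_track` with elements `track_id`, `role`
#'   and `samples` (data.frame `time_index`, `x`, `y`, `z`).
#' @export
cell_track <- function(track_id, time_index, x, y, z, role = "deep") {
  time_index <- as.integer(time_index)
  role <- match.arg(role, c("deep", "anchor"))
  if (length(time_index) < 2L)
    stop("a cell_track needs at least 2 samples")
  if (any(diff(time_index) <= 0L))
    stop("time_index must be strictly increasing")
  if (length(x) != length(time_index) || length(y) != length(time_index) ||
      length(z) != length(time_index))
    stop("x, y, z must match time_index in length")
  samples <- data.frame(time_index = time_index, x = as.numeric(x),
                        y = as.numeric(y), z = as.numeric(z))
  if (anyNA(samples)) stop("track samples contain missing values")
  structure(list(track_id = as.character(track_id)[1L], role = role,
                 samples = samples),
            class = "cell_track")
}

#' @exportS3Method base::print
print.cell_track <- function(x, ...) {
  s <- x$samples
  cat("cell_track '", x$track_id, "' (", x$role, "): ", nrow(s),
      " samples, frames ", s$time_index[1L], "-",
      s$time_index[nrow(s)], "\n", sep = "")
  invisible(x)
}

track_positions <- function(track) {
  as.matrix(track$samples[, c("x", "y", "z")])
}

#' Fill short track gaps by linear interpolation; split at long gaps
#'
#' Gaps of at most `max_gap` missing frames are filled by linear
#' interpolation per coordinate and flagged in an `interpolated` column;
#' longer gaps split the track into separate segments (ids suffixed `.1`,
#' `.2`, ...). The default of 3 matches the maximum gap a typical
#' autoregressive spot tracker is allowed to bridge.
#'
#' @param track A [cell_track].
#' @param max_gap Largest number of consecutive missing frames to bridge
#'   (default 3).
#'
#' @return A single `cell_track` when the result is one segment (identical
#'   to the input when there were no gaps), otherwise a list of `cell_track`
#'   segments.
#' @export
resample_gaps <- function(track, max_gap = 3) {
  stopifnot(inherits(track, "cell_track"))
  s <- track$samples
  gaps <- diff(s$time_index) - 1L
  if (all(gaps == 0L)) return(track)

  seg_id <- cumsum(c(0L, gaps > max_gap))
  segs <- lapply(split(seq_len(nrow(s)), seg_id), function(idx) {
    part <- s[idx, , drop = FALSE]
    if (nrow(part) < 2L) return(NULL)   # a stranded single sample
    full_t <- part$time_index[1L]:part$time_index[nrow(part)]
    out <- data.frame(
      time_index = full_t,
      x = stats::approx(part$time_index, part$x, xout = full_t)$y,
      y = stats::approx(part$time_index, part$y, xout = full_t)$y,
      z = stats::approx(part$time_index, part$z, xout = full_t)$y)
    out$interpolated <- !(full_t %in% part$time_index)
    out
  })
  segs <- Filter(Negate(is.null), segs)
  if (length(segs) == 0L)
    stop("track '", track$track_id, "' has no segment with >= 2 samples ",
         "after splitting at gaps > ", max_gap)

  build <- function(df, id) {
    tr <- cell_track(id, df$time_index, df$x, df$y, df$z, role = track$role)
    tr$samples$interpolated <- df$interpolated
    tr
  }
  if (length(segs) == 1L) return(build(segs[[1L]], track$track_id))
  out <- lapply(seq_along(segs), function(i)
    build(segs[[i]], paste0(track$track_id, ".", i)))
  names(out) <- vapply(out, `[[`, character(1), "track_id")
  out
}

#' Elongation trajectory: centroid of anchor cells over time
#'
#' The tissue-elongation reference trajectory (ET) is the per-frame centroid
#' of at least three anchor-cell tracks, evaluated on their common time
#' support. Internal anchor gaps are bridged by linear interpolation first,
#' since the centroid needs all anchors at every frame.
#'
#' @param anchors List of at least 3 anchor [cell_track] objects.
#'
#' @return An `elongation_trajectory`: data.frame (`time_index`, `x`, `y`,
#'   `z`) with an `anchor_ids` attribute.
#' @export
compute_elongation_trajectory <- function(anchors) {
  if (inherits(anchors, "cell_track")) anchors <- list(anchors)
  if (length(anchors) < 3L)
    stop("need at least 3 anchor tracks, got ", length(anchors))
  stopifnot(all(vapply(anchors, inherits, logical(1), "cell_track")))

  filled <- lapply(anchors, function(a) {
    s <- a$samples
    full_t <- s$time_index[1L]:s$time_index[nrow(s)]
    data.frame(time_index = full_t,
               x = stats::approx(s$time_index, s$x, xout = full_t)$y,
               y = stats::approx(s$time_index, s$y, xout = full_t)$y,
               z = stats::approx(s$time_index, s$z, xout = full_t)$y)
  })
  common <- Reduce(intersect, lapply(filled, `[[`, "time_index"))
  if (length(common) < 2L)
    stop("anchor tracks have no common time support (need >= 2 shared ",
         "frames)")
  common <- sort(common)
  mats <- lapply(filled, function(f)
    as.matrix(f[match(common, f$time_index), c("x", "y", "z")]))
  centroid <- Reduce(`+`, mats) / length(mats)
  et <- data.frame(time_index = common, x = centroid[, 1L],
                   y = centroid[, 2L], z = centroid[, 3L])
  attr(et, "anchor_ids") <- vapply(anchors, `[[`, character(1), "track_id")
  class(et) <- c("elongation_trajectory", "data.frame")
  et
}

#' Migration trajectory: observed track minus tissue-elongation displacement
#'
#' Removes the net tissue displacement from an observed trajectory (OT):
#' `MT(t) = OT(t) - (ET(t) - ET(t0))`, with `t0` the first frame shared by
#' track and ET. The migration trajectory thus starts at the cell's own
#' observed position and satisfies the exact identity
#' `OT(t) = MT(t) + (ET(t) - ET(t0))` at every shared frame.
#'
#' @param track A [cell_track] (the OT).
#' @param et An [compute_elongation_trajectory()] result.
#'
#' @return A `trajectory_decomposition`: data.frame with `time_index` and
#'   `ot_*`, `et_*`, `mt_*` coordinate columns, plus `track_id`, `role` and
#'   `anchor_ids` attributes.
#' @export
compute_migration_trajectory <- function(track, et) {
  stopifnot(inherits(track, "cell_track"),
            inherits(et, "elongation_trajectory"))
  common <- intersect(track$samples$time_index, et$time_index)
  if (length(common) < 2L)
    stop("track '", track$track_id,
         "' and the elongation trajectory share fewer than 2 frames")
  common <- sort(common)
  ot <- track_positions(track)[match(common, track$samples$time_index), ,
                               drop = FALSE]
  etm <- as.matrix(et[match(common, et$time_index), c("x", "y", "z")])
  det <- sweep(etm, 2L, etm[1L, ], "-")
  mt <- ot - det
  out <- data.frame(time_index = common,
                    ot_x = ot[, 1L], ot_y = ot[, 2L], ot_z = ot[, 3L],
                    et_x = etm[, 1L], et_y = etm[, 2L], et_z = etm[, 3L],
                    mt_x = mt[, 1L], mt_y = mt[, 2L], mt_z = mt[, 3L])
  attr(out, "track_id") <- track$track_id
  attr(out, "role") <- track$role
  attr(out, "anchor_ids") <- attr(et, "anchor_ids")
  class(out) <- c("trajectory_decomposition", "data.frame")
  out
}

#' Decompose a set of tracks against their anchor cells
#'
#' Convenience wrapper: selects anchors (by the `role` flag or an explicit
#' id vector), derives the elongation trajectory, and computes each track's
#' migration trajectory.
#'
#' @param tracks List of [cell_track] objects.
#' @param anchor_ids Optional character vector naming the anchor tracks;
#'   default: all tracks with `role == "anchor"`.
#' @param include_anchors Also decompose the anchor tracks themselves
#'   (default `TRUE`; useful as a self-consistency check — anchor migration
#'   should be near zero).
#'
#' @return List with `et` (the elongation trajectory) and `decompositions`
#'   (named list of [compute_migration_trajectory()] results).
#' @export
decompose_tracks <- function(tracks, anchor_ids = NULL,
                             include_anchors = TRUE) {
  stopifnot(is.list(tracks),
            all(vapply(tracks, inherits, logical(1), "cell_track")))
  ids <- vapply(tracks, `[[`, character(1), "track_id")
  names(tracks) <- ids
  if (is.null(anchor_ids)) {
    roles <- vapply(tracks, `[[`, character(1), "role")
    anchor_ids <- ids[roles == "anchor"]
  }
  if (!all(anchor_ids %in% ids))
    stop("anchor ids not found among tracks: ",
         paste(setdiff(anchor_ids, ids), collapse = ", "))
  et <- compute_elongation_trajectory(tracks[anchor_ids])
  todo <- if (include_anchors) ids else setdiff(ids, anchor_ids)
  dec <- lapply(tracks[todo], compute_migration_trajectory, et = et)
  list(et = et, decompositions = dec)
}

#' Migration positions of a decomposition as a matrix
#'
#' @param decomposition A `trajectory_decomposition`.
#' @return Numeric matrix (frames x 3) of migration coordinates.
#' @export
migration_positions <- function(decomposition) {
  stopifnot(inherits(decomposition, "trajectory_decomposition"))
  as.matrix(decomposition[, c("mt_x", "mt_y", "mt_z")])
}

#' Plane of dominant anchor displacement
#'
#' Principal plane (top two principal components) of the frame-to-frame
#' displacement vectors of the given tracks — by default the plane in which
#' tissue elongation unfolds, used as the projection plane for
#' [movement_directions()].
#'
#' @param tracks List of [cell_track] objects (typically the anchors).
#' @return A 3 x 2 orthonormal projection matrix.
#' @export
movement_plane <- function(tracks) {
  if (inherits(tracks, "cell_track")) tracks <- list(tracks)
  disp <- do.call(rbind, lapply(tracks, function(tr)
    diff(track_positions(tr))))
  if (nrow(disp) < 2L) stop("not enough displacement vectors to fit a plane")
  pc <- stats::prcomp(disp, center = TRUE, scale. = FALSE)
  basis <- pc$rotation[, 1:2, drop = FALSE]
  dimnames(basis) <- list(c("x", "y", "z"), c("axis1", "axis2"))
  basis
}

resolve_plane <- function(plane, tracks) {
  if (is.matrix(plane)) {
    if (!all(dim(plane) == c(3L, 2L)))
      stop("plane matrix must be 3 x 2 (projection onto a 2D plane)")
    return(plane)
  }
  if (is.character(plane) && length(plane) == 1L) {
    ax <- list(xy = c(1L, 2L), xz = c(1L, 3L), yz = c(2L, 3L))[[plane]]
    if (is.null(ax)) stop("unknown plane spec '", plane,
                          "' (use 'xy', 'xz', 'yz' or a 3x2 matrix)")
    b <- matrix(0, 3L, 2L)
    b[ax[1L], 1L] <- 1
    b[ax[2L], 2L] <- 1
    return(b)
  }
  if (is.null(plane)) {
    roles <- vapply(tracks, `[[`, character(1), "role")
    if (any(roles == "anchor"))
      return(movement_plane(tracks[roles == "anchor"]))
    return(resolve_plane("xy", tracks))
  }
  stop("invalid plane specification")
}

#' Histogram of cell movement directions in a projection plane
#'
#' For every track and every frame `t` such that frames `t` and
#' `t + window` are both present, the 3D displacement over the window is
#' projected onto a 2D plane and converted to an angle in degrees,
#' counter-clockwise from the plane's first axis, in `[0, 360)`. Angles are
#' binned into `bins` equal sectors (a rose plot's counts). Displacements
#' with zero projected length carry no direction; they are excluded from the
#' bins and tallied separately, so that
#' `sum(counts) + n_zero == total displacement steps`.
#'
#' @param tracks A [cell_track] or list of them.
#' @param window Displacement step in frames (default 1; at a 3-minute
#'   cadence, `window = 20` spans about an hour).
#' @param plane `"xy"`, `"xz"`, `"yz"`, a 3 x 2 projection matrix, or `NULL`
#'   (default) to use the anchor-displacement plane from [movement_plane()]
#'   when anchor tracks are present, else `"xy"`.
#' @param bins Number of equal angular bins (default 16).
#'
#' @return A `direction_histogram`: list with `counts`, `breaks` (degrees),
#'   `window`, `n_steps`, `n_zero`, `plane`.
#' @export
movement_directions <- function(tracks, window = 1, plane = NULL,
                                bins = 16) {
  if (inherits(tracks, "cell_track")) tracks <- list(tracks)
  stopifnot(all(vapply(tracks, inherits, logical(1), "cell_track")))
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be a positive integer")
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 1L) stop("bins must be a positive integer")
  basis <- resolve_plane(plane, tracks)

  angles <- numeric(0)
  n_zero <- 0L
  for (tr in tracks) {
    s <- tr$samples
    idx <- match(s$time_index + window, s$time_index)
    from <- which(!is.na(idx))
    if (length(from) == 0L) next
    disp <- track_positions(tr)[idx[from], , drop = FALSE] -
      track_positions(tr)[from, , drop = FALSE]
    proj <- disp %*% basis
    len <- sqrt(rowSums(proj^2))
    n_zero <- n_zero + sum(len == 0)
    ok <- len > 0
    if (any(ok))
      angles <- c(angles,
                  (atan2(proj[ok, 2L], proj[ok, 1L]) * 180 / pi) %% 360)
  }
  breaks <- seq(0, 360, length.out = bins + 1L)
  bin <- pmin(floor(angles / (360 / bins)) + 1L, bins)
  counts <- tabulate(bin, nbins = bins)
  structure(list(counts = counts, breaks = breaks, window = window,
                 n_steps = length(angles) + n_zero, n_zero = n_zero,
                 plane = basis),
            class = "direction_histogram")
}

#' Rose plot of a direction histogram
#'
#' @param x A `direction_histogram`.
#' @param col Sector fill color.
#' @param ... Ignored.
#' @export
plot.direction_histogram <- function(x, col = "steelblue", ...) {
  r <- sqrt(x$counts / max(1, max(x$counts)))
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = paste0("movement directions (window = ", x$window,
                               " frames)"))
  nb <- length(x$counts)
  for (i in seq_len(nb)) {
    a <- seq(x$breaks[i], x$breaks[i + 1L], length.out = 20) * pi / 180
    graphics::polygon(c(0, r[i] * cos(a)), c(0, r[i] * sin(a)),
                      col = col, border = "white")
  }
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "grey50")
  invisible(x)
}

#' Algebraic least-squares circle fit (Kasa method)
#'
#' Fits a circle to 2D points by solving the linear system of the Kasa
#' parameterisation; exact for points lying on a circle.
#'
#' @param xy Numeric matrix or data.frame with two columns.
#' @return List with `center` (length 2) and `radius`.
#' @export
fit_circle <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L)
  if (nrow(xy) < 3L) stop("circle fit needs at least 3 points")
  A <- cbind(xy, 1)
  b <- rowSums(xy^2)
  sol <- qr.solve(A, b)
  center <- sol[1:2] / 2
  radius <- sqrt(sol[3L] + sum(center^2))
  list(center = unname(center), radius = unname(radius))
}

#' Radius of rotation of a migration trajectory
#'
#' Projects 3D migration positions onto their principal plane and fits a
#' circle ([fit_circle()]); recovers the rotation radius of circling cells.
#'
#' @param positions Numeric matrix (frames x 3) of migration coordinates,
#'   e.g. from [migration_positions()], or a `trajectory_decomposition`.
#' @return List with `radius` and the 3 x 2 plane `basis` used.
#' @export
fit_rotation_radius <- function(positions) {
  if (inherits(positions, "trajectory_decomposition"))
    positions <- migration_positions(positions)
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L)
  ctr <- colMeans(positions)
  centered <- sweep(positions, 2L, ctr)
  sv <- svd(centered, nu = 0, nv = 2)
  proj <- centered %*% sv$v
  fit <- fit_circle(proj)
  list(radius = fit$radius, basis = sv$v)
}
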
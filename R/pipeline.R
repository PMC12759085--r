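#' Default pipeline configuration
#'
#' The resolved defaults used by [run_pipeline()]; a user config (YAML file
#' or list) overrides fields selectively. When no external inputs are given,
#' every analysis stage runs on the synthetic data produced by the
#' `simulate` stage, so the default configuration is a self-contained,
#' seeded end-to-end run.
#'
#' @return A nested list of defaults.
#' @export
default_config <- function() {
  list(
    stages = "all",
    out_dir = "morphlineage_run",
    seed = 1L,
    lineage = list(k = 10L, threshold = 0.2),
    decompose = list(window = 1L, bins = 16L, max_gap = 3L),
    neighbors = list(radius = 15, pairs = c("0:5", "0:10", "0:20", "0:40")),
    correlate = list(aggregation = "mean"),
    simulate = list(
      timepoints = list(),     # overrides for time_series_sim_spec()
      tracks = list(),         # overrides for track_sim_spec()
      expression = list(n_clusters = 4, n_genes = 200,
                        markers_per_cluster = 10, noise_sd = 0.5)),
    inputs = list()            # tracks_csv, timepoints, expression_query,
                               # expression_reference, markers_tsv
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid config field '", field, "': ", msg, call. = FALSE)
  known <- c("simulate", "lineage", "decompose", "neighbors", "correlate",
             "all")
  chk(all(cfg$stages %in% known), "stages",
      paste("must be among", paste(known, collapse = ", ")))
  chk(is.numeric(cfg$lineage$k) && cfg$lineage$k >= 1, "k",
      "must be a positive integer")
  chk(is.numeric(cfg$lineage$threshold) && cfg$lineage$threshold >= 0 &&
        cfg$lineage$threshold < 1, "threshold", "must lie in [0, 1)")
  chk(is.numeric(cfg$neighbors$radius) && cfg$neighbors$radius > 0,
      "radius", "must be > 0")
  chk(is.numeric(cfg$decompose$window) && cfg$decompose$window >= 1,
      "window", "must be >= 1")
  chk(is.numeric(cfg$decompose$bins) && cfg$decompose$bins >= 1,
      "bins", "must be >= 1")
  chk(is.numeric(cfg$decompose$max_gap) && cfg$decompose$max_gap >= 0,
      "max_gap", "must be >= 0")
  chk(cfg$correlate$aggregation %in% c("mean", "sum"), "aggregation",
      "must be 'mean' or 'sum'")
  chk(is.numeric(cfg$seed), "seed", "must be an integer")
  invisible(cfg)
}

#' Run the analysis pipeline
#'
#' Orchestrates the simulators and the four analysis stages (lineage graph,
#' track decomposition, neighbor dynamics, pseudo-bulk correlation) behind
#' one entry point with a shared seeded configuration. Stages run in
#' dependency order; every analytic output is a plain-text file under the
#' run directory, and a `manifest.json` (package version, resolved config,
#' input checksums, per-stage file lists and wall-clock) is written
#' atomically at the end. Re-running with an identical config and seed
#' reproduces byte-identical analytic outputs.
#'
#' @param config A config list or path to a YAML file; fields override
#'   [default_config()].
#' @param seed Optional seed override.
#' @param out_dir Optional output-directory override.
#'
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), seed = NULL, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)

  stages <- cfg$stages
  if ("all" %in% stages)
    stages <- c("simulate", "lineage", "decompose", "neighbors", "correlate")
  # analysis stages with no external input need the simulator
  needs_sim <- (("lineage" %in% stages && is.null(cfg$inputs$timepoints)) ||
    (any(c("decompose", "neighbors") %in% stages) &&
       is.null(cfg$inputs$tracks_csv)) ||
    ("correlate" %in% stages && is.null(cfg$inputs$expression_query)))
  if (needs_sim && !"simulate" %in% stages)
    stages <- c("simulate", stages)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t_run <- Sys.time()
  files <- list()
  timings <- list()
  state <- new.env(parent = emptyenv())

  add_files <- function(stage, paths)
    files[[stage]] <<- c(files[[stage]], unname(paths))
  out_path <- function(...) file.path(cfg$out_dir, ...)

  input_checksums <- list()
  for (p in unlist(cfg$inputs))
    if (is.character(p) && file.exists(p))
      input_checksums[[p]] <- unname(tools::md5sum(p))

  run_stage <- function(stage, fun) {
    t0 <- Sys.time()
    fun()
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0,
                                             units = "secs"))
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    tp_spec <- do.call(time_series_sim_spec,
                       merge_config(list(seed = cfg$seed),
                                    cfg$simulate$timepoints))
    state$sim_tp <- simulate_timepoint_series(tp_spec)
    dir.create(out_path("simulated"), showWarnings = FALSE)
    for (i in seq_along(state$sim_tp$pairs)) {
      p <- state$sim_tp$pairs[[i]]
      add_files("simulate", write_timepoint_slice(
        p$earlier, out_path("simulated"),
        prefix = sprintf("pair%02d_earlier", i)))
      add_files("simulate", write_timepoint_slice(
        p$later, out_path("simulated"),
        prefix = sprintf("pair%02d_later", i)))
    }
    pt <- out_path("simulated", "true_edges.tsv")
    write_lineage_edges(state$sim_tp$truth, pt)
    add_files("simulate", pt)

    tr_spec <- do.call(track_sim_spec,
                       merge_config(list(seed = cfg$seed + 1L),
                                    cfg$simulate$tracks))
    state$sim_tracks <- simulate_explant_tracks(tr_spec)
    ptr <- out_path("simulated", "tracks.csv")
    write_tracks_csv(state$sim_tracks$tracks, ptr)
    add_files("simulate", ptr)

    ex <- cfg$simulate$expression
    state$sim_expr <- simulate_expression_pair(
      ex$n_clusters, ex$n_genes, ex$markers_per_cluster, ex$noise_sd,
      seed = cfg$seed + 2L)
    write_pseudobulk_input(state$sim_expr$query,
                           out_path("simulated", "query"))
    write_pseudobulk_input(state$sim_expr$reference,
                           out_path("simulated", "reference"))
    pm <- out_path("simulated", "markers.tsv")
    write_tsv(state$sim_expr$markers, pm)
    add_files("simulate",
              c(file.path(out_path("simulated", "query"), "matrix.mtx"),
                file.path(out_path("simulated", "reference"), "matrix.mtx"),
                pm))
  })

  if ("lineage" %in% stages) run_stage("lineage", function() {
    if (!is.null(cfg$inputs$timepoints)) {
      slices <- lapply(cfg$inputs$timepoints, function(tp)
        read_timepoint_slice(tp$embedding, tp$labels, tp$label))
      graph <- chain_timepoints(slices, k = cfg$lineage$k,
                                threshold = cfg$lineage$threshold)
    } else {
      graph <- chain_timepoints(state$sim_tp$pairs, k = cfg$lineage$k,
                                threshold = cfg$lineage$threshold)
    }
    state$graph <- graph
    p1 <- out_path("lineage_edges.tsv")
    p2 <- out_path("lineage_graph.json")
    p3 <- out_path("lineage_graph.dot")
    write_lineage_edges(graph, p1)
    lineage_to_json(graph, p2)
    lineage_to_dot(graph, p3)
    add_files("lineage", c(p1, p2, p3))
  })

  get_tracks <- function() {
    if (is.null(state$tracks)) {
      raw <- if (!is.null(cfg$inputs$tracks_csv))
        read_tracks_csv(cfg$inputs$tracks_csv)
      else state$sim_tracks$tracks
      filled <- lapply(raw, resample_gaps, max_gap = cfg$decompose$max_gap)
      state$tracks <- unlist(lapply(filled, function(x)
        if (inherits(x, "cell_track")) list(x) else x), recursive = FALSE)
      names(state$tracks) <- vapply(state$tracks, `[[`, character(1),
                                    "track_id")
    }
    state$tracks
  }

  if ("decompose" %in% stages) run_stage("decompose", function() {
    tracks <- get_tracks()
    dec <- decompose_tracks(tracks)
    p1 <- out_path("decomposition.tsv")
    write_decomposition_tsv(dec$decompositions, p1)
    hist <- movement_directions(tracks, window = cfg$decompose$window,
                                bins = cfg$decompose$bins)
    p2 <- out_path("direction_histogram.tsv")
    write_tsv(data.frame(bin_start_deg = hist$breaks[-length(hist$breaks)],
                         bin_end_deg = hist$breaks[-1L],
                         count = hist$counts), p2)
    add_files("decompose", c(p1, p2))
  })

  if ("neighbors" %in% stages) run_stage("neighbors", function() {
    frames <- tracks_to_frames(get_tracks())
    tabs <- list()
    for (pair in cfg$neighbors$pairs) {
      tt <- as.integer(strsplit(pair, ":", fixed = TRUE)[[1L]])
      tab <- neighbor_rate(frames, tt[1L], tt[2L],
                           radius = cfg$neighbors$radius)
      tabs[[pair]] <- tab
    }
    all_rates <- do.call(rbind, lapply(names(tabs), function(nm)
      cbind(interval = nm, as.data.frame(tabs[[nm]]))))
    p1 <- out_path("neighbor_rates.tsv")
    write_tsv(all_rates, p1)
    add_files("neighbors", p1)
    groups <- lapply(tabs, `[[`, "rate")
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) >= 2L) {
      cmp <- compare_interval_groups(groups)
      p2 <- out_path("neighbor_group_stats.tsv")
      write_tsv(cmp$group_stats, p2)
      p3 <- out_path("neighbor_anova.json")
      jsonlite::write_json(list(anova = cmp$anova,
                                tukey = cmp$tukey), p3,
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      add_files("neighbors", c(p2, p3))
    }
  })

  if ("correlate" %in% stages) run_stage("correlate", function() {
    if (!is.null(cfg$inputs$expression_query)) {
      qu <- read_pseudobulk_input(cfg$inputs$expression_query)
      re <- read_pseudobulk_input(cfg$inputs$expression_reference)
      mk <- utils::read.delim(cfg$inputs$markers_tsv,
                              stringsAsFactors = FALSE)
    } else {
      qu <- state$sim_expr$query
      re <- state$sim_expr$reference
      mk <- state$sim_expr$markers
    }
    qp <- aggregate_pseudobulk(qu, method = cfg$correlate$aggregation)
    rp <- aggregate_pseudobulk(re, method = cfg$correlate$aggregation)
    sim <- marker_correlation(qp, rp, mk)
    p1 <- out_path("similarity.tsv")
    write_tsv(cbind(query_cluster = rownames(sim),
                    as.data.frame(unclass(sim))), p1)
    p2 <- out_path("best_match.tsv")
    write_tsv(best_match(sim), p2)
    add_files("correlate", c(p1, p2))
  })

  manifest <- list(
    package = "morphlineage",
    version = as.character(utils::packageVersion("morphlineage")),
    config = cfg[setdiff(names(cfg), "stages")],
    stages = stages,
    input_checksums = input_checksums,
    outputs = lapply(files, function(ps)
      lapply(ps, function(p) list(path = p,
                                  md5 = unname(tools::md5sum(p))))),
    seconds_per_stage = timings,
    finished = format(t_run, "%Y-%m-%dT%H:%M:%S"))
  tmp <- tempfile(tmpdir = cfg$out_dir, fileext = ".json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  file.rename(tmp, out_path("manifest.json"))
  invisible(manifest)
}

#' Validate input files without failing
#'
#' Checks each path for existence, recognized format (by name and
#' extension), required columns and consistent sidecar lengths. Problems are
#' reported, never thrown.
#'
#' @param paths Character vector of file paths (a Matrix Market directory is
#'   referenced by its `matrix.mtx`).
#'
#' @return data.frame (`file`, `format`, `ok`, `message`) — one row per
#'   check performed; `message` is empty for passing checks.
#' @export
validate_inputs <- function(paths) {
  check_one <- function(p) {
    row <- function(format, ok, message = "")
      data.frame(file = p, format = format, ok = ok, message = message,
                 stringsAsFactors = FALSE)
    if (!file.exists(p)) return(row("unknown", FALSE, "file does not exist"))
    tryCatch({
      if (grepl("\\.csv$", p)) {
        df <- utils::read.csv(p, nrows = 50, stringsAsFactors = FALSE)
        need <- c("track_id", "time_index", "x", "y", "z")
        miss <- setdiff(need, names(df))
        if (length(miss))
          return(row("track_csv", FALSE,
                     paste("missing column(s):",
                           paste(miss, collapse = ", "))))
        return(row("track_csv", TRUE))
      }
      if (grepl("\\.mtx$", p)) {
        m <- Matrix::readMM(p)
        dir <- dirname(p)
        for (side in c("genes.tsv", "cells.tsv")) {
          sp <- file.path(dir, side)
          if (!file.exists(sp))
            return(row("matrix_market", FALSE,
                       paste("missing sidecar", side)))
        }
        n_genes <- length(readLines(file.path(dir, "genes.tsv")))
        n_cells <- length(readLines(file.path(dir, "cells.tsv")))
        if (nrow(m) != n_genes || ncol(m) != n_cells)
          return(row("matrix_market", FALSE, sprintf(
            "matrix is %d x %d but sidecars list %d genes, %d cells",
            nrow(m), ncol(m), n_genes, n_cells)))
        return(row("matrix_market", TRUE))
      }
      if (grepl("embedding.*\\.tsv$", p)) {
        df <- utils::read.delim(p, nrows = 50, stringsAsFactors = FALSE)
        if (!"cell_id" %in% names(df) ||
            !length(grep("^dim_", names(df))))
          return(row("embedding_tsv", FALSE,
                     "needs cell_id and dim_* columns"))
        return(row("embedding_tsv", TRUE))
      }
      if (grepl("\\.tsv$", p)) {
        df <- utils::read.delim(p, nrows = 50, stringsAsFactors = FALSE)
        if (all(c("cell_id", "cluster") %in% names(df)))
          return(row("label_tsv", TRUE))
        if (all(c("cluster", "gene") %in% names(df)))
          return(row("marker_tsv", TRUE))
        return(row("tsv", FALSE, "unrecognized TSV column set"))
      }
      if (grepl("\\.ya?ml$", p)) {
        yaml::read_yaml(p)
        return(row("yaml", TRUE))
      }
      row("unknown", FALSE, "unrecognized file type")
    }, error = function(e) row("unknown", FALSE, conditionMessage(e)))
  }
  out <- do.call(rbind, lapply(paths, check_one))
  rownames(out) <- NULL
  out
}
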
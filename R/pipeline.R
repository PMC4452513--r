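#' Pipeline configuration
#'
#' Bundles every tunable parameter of the analysis pipeline. All lengths
#' are in mm unless stated otherwise. The configuration (with the RNG
#' seed) is written verbatim into every run's output, so a run can be
#' reproduced exactly.
#'
#' @param edge_length voxel edge (mm).
#' @param R seed-detection PCA neighbourhood radius in voxels; choose
#'   between one and two average branch radii.
#' @param sphericity seed-detection eigenvalue-ratio threshold.
#' @param max_fraction seed-detection fall-back fraction.
#' @param merge_threshold branch absorb threshold (mm); `NULL` = twice
#'   the estimated average branch radius of each shape.
#' @param icp_max_iter,icp_tol ICP iteration cap and RMS tolerance (mm).
#' @param fourpcs_bases number of 4PCS bases to try.
#' @param max_rotation largest plausible rotation between acquisitions
#'   (degrees); the coarse search discards larger candidate motions.
#' @param overlap_fraction expected target overlap for 4PCS.
#' @param delta 4PCS congruence tolerance (mm); `NULL` = one voxel edge.
#' @param coarse_trigger skip the coarse stage when the identity already
#'   brings the sampled distance below this many voxel edges.
#' @param tip_gate time-function tip match gate in voxel edges.
#' @param exclude_threshold alignment exclusion threshold in voxel edges.
#' @param point_cap registration subsampling cap (points).
#' @param seed RNG seed used (with fixed offsets) by every random step.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(edge_length, R = 3, sphericity = 0.6,
                            max_fraction = 0.25, merge_threshold = NULL,
                            icp_max_iter = 50L, icp_tol = 1e-3,
                            fourpcs_bases = 32L, overlap_fraction = NULL,
                            max_rotation = 60, delta = NULL,
                            coarse_trigger = 3,
                            tip_gate = 5, exclude_threshold = 10.0,
                            point_cap = 20000L, seed = 1L) {
  stopifnot(edge_length > 0, R >= 1, sphericity > 0, sphericity <= 1,
            max_fraction > 0, icp_tol > 0, tip_gate > 0,
            exclude_threshold > 0)
  structure(list(edge_length = edge_length, R = R, sphericity = sphericity,
                 max_fraction = max_fraction,
                 merge_threshold = merge_threshold,
                 icp_max_iter = as.integer(icp_max_iter), icp_tol = icp_tol,
                 fourpcs_bases = as.integer(fourpcs_bases),
                 overlap_fraction = overlap_fraction,
                 max_rotation = max_rotation, delta = delta,
                 coarse_trigger = coarse_trigger, tip_gate = tip_gate,
                 exclude_threshold = exclude_threshold,
                 point_cap = as.integer(point_cap), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full growth-record pipeline on a time-series
#'
#' Stages: reduce each shape to its largest connected component, align
#' all shapes into the frame of the first, detect the seed area on the
#' last shape and propagate it backwards, compute geodesic depth and a
#' branch decomposition for every shape, reconstruct the time function on
#' the final shape, repair depth/time conflicts by switches, and compute
#' the trait tables.
#'
#' @param series a [time_series()], or list of `voxel_shape` objects.
#' @param config a [pipeline_config()].
#' @return object of class `root_analysis`: `aligned`, `record`
#'   (a [growth_record()] after repair), `seed` (final-shape seed area),
#'   `traits` (per-branch per-time table), `totals` (per-time aggregates),
#'   `increments`, `seed_traits`, `classes`, `qc` (alignment quality
#'   table), `config`, `runtime_s`.
#' @export
analyze_series <- function(series, config = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (!inherits(series, "time_series")) series <- time_series(series)
  if (is.null(config)) config <- pipeline_config(series$shapes[[1L]]$edge_length)
  stopifnot(inherits(config, "pipeline_config"))
  # connectivity (largest component per shape)
  graphs <- vector("list", series$T + 1L)
  for (t in 0:series$T) {
    g <- largest_component(build_graph(series$shapes[[t + 1L]]))
    graphs[[t + 1L]] <- g
    series$shapes[[t + 1L]] <- g$shape
  }
  series <- time_series(series$shapes)
  aligned <- align_series(series, config)
  T <- series$T
  final_graph <- graphs[[T + 1L]]
  seed_T <- detect_seed(final_graph$shape, R = config$R,
                        sphericity = config$sphericity,
                        max_fraction = config$max_fraction)
  depth_T <- compute_depth(final_graph, seed_T)
  hier_T <- decompose(final_graph, depth_T, config$merge_threshold)
  per_t <- vector("list", max(T, 0L))
  if (T >= 1L) {
    seeds <- propagate_seed(seed_T, aligned)
    for (t in seq_len(T) - 1L) {
      if (aligned$excluded[t + 1L]) next
      d_t <- compute_depth(graphs[[t + 1L]], seeds[[t + 1L]])
      per_t[[t + 1L]] <- decompose(graphs[[t + 1L]], d_t,
                                   config$merge_threshold)
    }
  }
  tf <- compute_time(aligned, hier_T, depth_T, per_t,
                     tip_gate = config$tip_gate)
  record <- growth_record(final_graph, depth_T, hier_T, tf, T)
  record <- repair_switches(record)
  traits <- trait_table(record)
  totals <- do.call(rbind, lapply(0:T, aggregate_traits, record = record,
                                  traits = traits))
  qc <- if (T >= 1L) {
    data.frame(time_index = 0:T,
               avg_distance_edges = aligned$quality,
               excluded = aligned$excluded)
  } else {
    data.frame(time_index = 0L, avg_distance_edges = NA_real_,
               excluded = FALSE)
  }
  structure(list(
    aligned = aligned, record = record, seed = seed_T,
    traits = traits, totals = totals,
    increments = growth_increments(record, traits),
    seed_traits = seed_traits(seed_T, final_graph$shape),
    classes = classify_branches(record, seed_T),
    qc = qc, config = config,
    runtime_s = proc.time()[["elapsed"]] - t0
  ), class = "root_analysis")
}

#' @export
print.root_analysis <- function(x, ...) {
  cat(sprintf(
    "<root_analysis> T = %d, %d branches, %d switch event(s), %.1f s\n",
    x$record$T, nrow(x$record$hierarchy$branches),
    x$record$switch_events, x$runtime_s))
  print(x$totals, row.names = FALSE)
  invisible(x)
}

#' Write the full output bundle of an analysis
#'
#' Writes, under `dir`: per-timepoint and combined long-format trait
#' tables (TSV), the branch hierarchy (TSV), depth and time fields (TSV),
#' colored PLY point clouds of the branch decomposition and the time
#' function, per-timepoint motion sidecars (12 numbers: row-major
#' rotation then translation), a QC/stats file, and the configuration as
#' JSON.
#'
#' @param analysis an [analyze_series()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- analysis$record
  edge <- rec$shape$edge_length
  tsv <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(analysis$traits, "traits_long.tsv")
  for (t in 0:rec$T) {
    tsv(analysis$traits[analysis$traits$t == t, , drop = FALSE],
        sprintf("traits_t%02d.tsv", t))
  }
  tsv(analysis$totals, "totals.tsv")
  if (!is.null(analysis$increments)) tsv(analysis$increments, "increments.tsv")
  tsv(analysis$seed_traits, "seed_traits.tsv")
  tsv(analysis$classes, "branch_classes.tsv")
  h <- rec$hierarchy
  v <- rec$shape$voxels
  hier <- data.frame(
    branch_id = h$branches$id,
    parent_id = h$branches$parent,
    tip_x = v[h$branches$tip, 1L], tip_y = v[h$branches$tip, 2L],
    tip_z = v[h$branches$tip, 3L],
    fork_x = ifelse(is.na(h$branches$fork), NA, v[pmax(h$branches$fork, 1L), 1L]),
    fork_y = ifelse(is.na(h$branches$fork), NA, v[pmax(h$branches$fork, 1L), 2L]),
    fork_z = ifelse(is.na(h$branches$fork), NA, v[pmax(h$branches$fork, 1L), 3L]),
    n_voxels = h$branches$n_voxels
  )
  tsv(hier, "hierarchy.tsv")
  tsv(data.frame(x = v[, 1L], y = v[, 2L], z = v[, 3L],
                 depth_mm = rec$depth$depth), "depth.tsv")
  tsv(data.frame(x = v[, 1L], y = v[, 2L], z = v[, 3L], tau = rec$tau),
      "time.tsv")
  write_branch_ply(rec, file.path(dir, "branches.ply"))
  write_time_ply(rec, file.path(dir, "time.ply"))
  for (t in 0:rec$T) {
    m <- analysis$aligned$motions[[t + 1L]]
    writeLines(paste(format(c(t(m$R), m$t), digits = 17), collapse = " "),
               file.path(dir, sprintf("motion_t%02d.txt", t)))
  }
  tsv(analysis$qc, "qc.tsv")
  stats <- data.frame(
    runtime_s = analysis$runtime_s,
    avg_alignment_distance_edges =
      mean(analysis$qc$avg_distance_edges, na.rm = TRUE),
    switch_events = rec$switch_events,
    skipped_tips = rec$skipped_tips,
    loop_candidates = rec$hierarchy$loop_count
  )
  tsv(stats, "stats.tsv")
  cfg <- analysis$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

# qualitative color table (recycled) for branch ids
.branch_colors <- function(k) {
  base <- grDevices::col2rgb(rep(c(
    "#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00", "#A65628",
    "#F781BF", "#1B9E77", "#66A61E", "#E6AB02"), length.out = k))
  t(base)
}

.write_ply <- function(pts, rgb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(pts)),
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    "end_header"), con)
  writeLines(sprintf("%.4f %.4f %.4f %d %d %d",
                     pts[, 1L], pts[, 2L], pts[, 3L],
                     rgb[, 1L], rgb[, 2L], rgb[, 3L]), con)
}

#' Export the branch decomposition as a colored PLY point cloud
#' @param record a [growth_record()].
#' @param path output `.ply` file (ASCII, per-vertex RGB).
#' @return `path`, invisibly.
#' @export
write_branch_ply <- function(record, path) {
  cols <- .branch_colors(nrow(record$hierarchy$branches))
  rgb <- cols[record$hierarchy$branch_of, , drop = FALSE]
  .write_ply(voxel_centers(record$shape), rgb, path)
  invisible(path)
}

#' Export the time function as a colored PLY point cloud
#' @param record a [growth_record()].
#' @param path output `.ply` file.
#' @return `path`, invisibly.
#' @export
write_time_ply <- function(record, path) {
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  x <- record$tau / max(record$T, 1L)
  rgb <- round(ramp(x))
  .write_ply(voxel_centers(record$shape), rgb, path)
  invisible(path)
}
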
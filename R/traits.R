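# major PCA axis of a voxel coordinate matrix (mm); NULL if degenerate
.major_axis <- function(pts) {
  if (nrow(pts) < 3L) return(NULL)
  C <- cov(pts)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[1L] <= 1e-12) return(NULL)
  e$vectors[, 1L]
}

# angle between two orientation-less axes, folded into [0, 90] degrees
.axis_angle <- function(a, b) {
  ca <- abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# sublevel member indices of branch b at time t
.sublevel <- function(record, b, t) {
  mem <- record$hierarchy$members[[b]]
  mem[record$tau[mem] <= t]
}

# branch length at time t: geodesic depth of the current tip minus the
# depth of the fork (the full depth of the tip for the root branch)
.branch_length <- function(record, b, t) {
  sub <- .sublevel(record, b, t)
  if (length(sub) == 0L) return(NA_real_)
  d <- record$depth$depth
  tipd <- max(d[sub])
  fk <- record$hierarchy$branches$fork[b]
  if (is.na(fk)) tipd else tipd - d[fk]
}

#' Traits of one branch at one time
#'
#' Computes the full per-branch trait record from the growth record. The
#' branch at time `t` is the sublevel set of the time field on its
#' members; its tip is the member of maximal geodesic depth (ties go to
#' the lexicographically smallest voxel).
#'
#' Traits: `volume` (voxel count; `volume_mm3` = count x edge^3),
#' `depth_of_tip` (geodesic, mm), `tip_x/y/z` (mm), `length` (depth of tip
#' minus depth of fork, mm), `switch_event` (is the branch longer than its
#' parent at `t`), `tortuosity` (length / Euclidean tip-fork chord),
#' `average_radius` (`sqrt(volume_mm3 / (pi * length))`, mm),
#' `angle_to_gravity` (major PCA axis of the sublevel vs vertical, folded
#' to [0, 90] degrees), `angle_to_parent` (between major PCA axes, 0 for
#' the root branch), `n_children` (branches forking from it that exist at
#' `t`). For the root branch the fork is absent: length is the full tip
#' depth and the chord runs from the tip to the shallowest member.
#'
#' @param record a [growth_record()] (after [repair_switches()]).
#' @param branch_id branch id.
#' @param t time index in `[0, T]`.
#' @return one-row data.frame, or `NULL` when the branch does not exist
#'   yet at `t`.
#' @export
branch_traits <- function(record, branch_id, t) {
  h <- record$hierarchy
  b <- branch_id
  sub <- .sublevel(record, b, t)
  if (length(sub) == 0L) return(NULL)
  edge <- record$shape$edge_length
  d <- record$depth$depth
  v <- record$shape$voxels
  tip <- sub[which.max(d[sub])]
  fk <- h$branches$fork[b]
  pid <- h$branches$parent[b]
  is_root <- is.na(fk)
  tipd <- d[tip]
  len <- if (is_root) tipd else tipd - d[fk]
  vol <- length(sub)
  vol_mm3 <- vol * edge^3
  chord_from <- if (is_root) sub[which.min(d[sub])] else fk
  chord <- sqrt(sum((v[tip, ] - v[chord_from, ])^2)) * edge
  tortuosity <- if (chord > 0) len / chord else NA_real_
  avg_radius <- if (len > 0) sqrt(vol_mm3 / (pi * len)) else NA_real_
  pts <- v[sub, , drop = FALSE] * edge
  ax <- .major_axis(pts)
  ang_grav <- if (is.null(ax)) NA_real_ else .axis_angle(ax, c(0, 0, 1))
  if (is_root) {
    ang_parent <- 0
  } else {
    psub <- .sublevel(record, pid, t)
    pax <- if (length(psub)) .major_axis(v[psub, , drop = FALSE] * edge) else NULL
    ang_parent <- if (is.null(ax) || is.null(pax)) NA_real_ else
      .axis_angle(ax, pax)
  }
  plen <- if (is_root) NA_real_ else .branch_length(record, pid, t)
  switch_event <- !is_root && is.finite(plen) && len > plen
  kids <- h$branches$id[!is.na(h$branches$parent) & h$branches$parent == b]
  n_children <- sum(vapply(kids, function(k)
    length(.sublevel(record, k, t)) > 0L, logical(1L)))
  data.frame(
    branch_id = b, t = t, volume = vol, volume_mm3 = vol_mm3,
    depth_of_tip = tipd,
    tip_x = v[tip, 1L] * edge, tip_y = v[tip, 2L] * edge,
    tip_z = v[tip, 3L] * edge,
    length = len, switch_event = switch_event, tortuosity = tortuosity,
    average_radius = avg_radius, angle_to_gravity = ang_grav,
    angle_to_parent = ang_parent, n_children = n_children
  )
}

#' Trait table for all branches and times
#'
#' @param record a [growth_record()].
#' @return data.frame with one row per (branch, t) for which the branch
#'   exists; columns as in [branch_traits()].
#' @export
trait_table <- function(record) {
  rows <- list()
  for (t in 0:record$T) {
    for (b in record$hierarchy$branches$id) {
      r <- branch_traits(record, b, t)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

#' Aggregate whole-system traits at one time
#'
#' @param record a [growth_record()].
#' @param t time index.
#' @param traits optional precomputed [trait_table()].
#' @return one-row data.frame: `t`, `n_branches`, `total_volume` (voxels),
#'   `total_volume_mm3`, `total_length` (mm), `total_average_radius` (mm),
#'   `switch_event_count`.
#' @export
aggregate_traits <- function(record, t, traits = NULL) {
  if (is.null(traits)) traits <- trait_table(record)
  tt <- traits[traits$t == t, , drop = FALSE]
  tot_vol <- sum(tt$volume)
  tot_vol_mm3 <- sum(tt$volume_mm3)
  tot_len <- sum(tt$length, na.rm = TRUE)
  data.frame(
    t = t, n_branches = nrow(tt), total_volume = tot_vol,
    total_volume_mm3 = tot_vol_mm3, total_length = tot_len,
    total_average_radius = if (tot_len > 0)
      sqrt(tot_vol_mm3 / (pi * tot_len)) else NA_real_,
    switch_event_count = sum(tt$switch_event)
  )
}

#' Growth increments between consecutive timepoints
#'
#' @param record a [growth_record()].
#' @param traits optional precomputed [trait_table()].
#' @return data.frame of differences of the aggregate traits between t and
#'   t+1 (`volume_growth` in voxels, `length_growth` in mm, plus
#'   `new_branches`).
#' @export
growth_increments <- function(record, traits = NULL) {
  if (is.null(traits)) traits <- trait_table(record)
  ag <- do.call(rbind, lapply(0:record$T, aggregate_traits,
                              record = record, traits = traits))
  if (nrow(ag) < 2L) return(NULL)
  data.frame(
    from = ag$t[-nrow(ag)], to = ag$t[-1L],
    volume_growth = diff(ag$total_volume),
    length_growth = diff(ag$total_length),
    new_branches = diff(ag$n_branches)
  )
}

#' Traits of the seed area
#'
#' @param seed a `seed_area`.
#' @param shape the [voxel_shape()] it belongs to.
#' @return one-row data.frame: `seed_volume` (voxels), `seed_orientation`
#'   (major PCA axis vs vertical, degrees in [0, 90]; 0 with
#'   `degenerate = TRUE` when the eigenvalue spread is below 5%),
#'   `volume_fraction`.
#' @export
seed_traits <- function(seed, shape) {
  stopifnot(nrow(seed$voxels) >= 1L)
  vol <- nrow(seed$voxels)
  frac <- vol / n_voxels(shape)
  degenerate <- FALSE
  orientation <- 0
  if (vol >= 3L) {
    C <- cov(seed$voxels * shape$edge_length)
    e <- eigen(C, symmetric = TRUE, only.values = FALSE)
    ev <- pmax(e$values, 0)
    if (ev[1L] <= 0 || (ev[1L] - ev[3L]) / ev[1L] < 0.05) {
      degenerate <- TRUE
    } else {
      orientation <- .axis_angle(e$vectors[, 1L], c(0, 0, 1))
    }
  } else {
    degenerate <- TRUE
  }
  data.frame(seed_volume = vol, seed_orientation = orientation,
             volume_fraction = frac, degenerate = degenerate)
}

#' Geometric classification of branches into root classes
#'
#' A provisional, purely geometric classification: the topmost branch is
#' the primary root; branches whose fork lies inside the seed area are
#' seminal; branches whose fork lies above the bounding box of the seed
#' area are crown; all remaining branches are lateral. Crown roots that
#' emerge above the reconstructed volume cannot be identified this way,
#' so the labels are flagged provisional.
#'
#' @param record a [growth_record()].
#' @param seed the seed area of the final shape.
#' @return data.frame `branch_id`, `class`
#'   (primary/seminal/crown/lateral), with attribute
#'   `"provisional" = TRUE`.
#' @export
classify_branches <- function(record, seed) {
  h <- record$hierarchy
  v <- record$shape$voxels
  seed_idx <- seed$indices
  top_z <- max(seed$voxels[, 3L])
  cls <- character(nrow(h$branches))
  for (i in seq_len(nrow(h$branches))) {
    b <- h$branches$id[i]
    fk <- h$branches$fork[b]
    if (b == h$root_branch) {
      cls[i] <- "primary"
    } else if (fk %in% seed_idx) {
      cls[i] <- "seminal"
    } else if (v[fk, 3L] > top_z) {
      cls[i] <- "crown"
    } else {
      cls[i] <- "lateral"
    }
  }
  out <- data.frame(branch_id = h$branches$id, class = cls)
  attr(out, "provisional") <- TRUE
  out
}
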
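#' Specification of one synthetic branch
#'
#' A branch is a ball of fixed radius swept along a cubic-spline curve
#' through control points; growth is prescribed by a per-timepoint tip
#' arc-length schedule. Children attach to a parent at a given arc-length
#' position: the child curve starts on the parent's surface (the attach
#' point offset by the parent radius along the child's initial direction),
#' so swept tubes of parent and child overlap only marginally.
#'
#' @param name branch name (unique within a system).
#' @param ctrl k x 3 matrix of control points (mm). Absolute coordinates
#'   for a top-level branch; relative to the computed attach origin for a
#'   child (first row must then be c(0, 0, 0)).
#' @param radius sweep radius in mm (> 0).
#' @param appear first time index at which the branch exists.
#' @param schedule numeric vector of tip arc-lengths (mm) for
#'   t = appear, ..., T; must be non-decreasing (growth only elongates).
#' @param parent name of the parent spec, or NULL for a top-level branch.
#' @param attach_s arc-length position (mm) on the parent where the branch
#'   emerges (required with `parent`).
#' @return object of class `branch_spec`.
#' @export
branch_spec <- function(name, ctrl, radius, appear = 0L, schedule,
                        parent = NULL, attach_s = NULL) {
  ctrl <- as.matrix(ctrl)
  stopifnot(ncol(ctrl) == 3L, nrow(ctrl) >= 2L, radius > 0,
            length(schedule) >= 1L, all(diff(schedule) >= 0),
            all(schedule > 0))
  if (!is.null(parent) && is.null(attach_s)) {
    stop("a child spec needs attach_s")
  }
  structure(list(name = name, ctrl = ctrl, radius = radius,
                 appear = as.integer(appear), schedule = schedule,
                 parent = parent, attach_s = attach_s),
            class = "branch_spec")
}

# cubic spline through control points, chord-length parameterized,
# densely sampled; returns points (mm) and cumulative arc length
.spline_polyline <- function(ctrl, n_samples = 2000L) {
  u <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
  if (u[length(u)] <= 0) stop("degenerate control polygon")
  uu <- seq(0, u[length(u)], length.out = n_samples)
  pts <- vapply(1:3, function(j) {
    if (nrow(ctrl) == 2L) {
      # two control points: straight segment
      ctrl[1L, j] + (ctrl[2L, j] - ctrl[1L, j]) * uu / u[length(u)]
    } else {
      splinefun(u, ctrl[, j], method = "natural")(uu)
    }
  }, numeric(length(uu)))
  cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  list(pts = pts, cum = cum)
}

# point on a polyline at arc length s
.polyline_point <- function(poly, s) {
  s <- max(0, min(s, poly$cum[length(poly$cum)]))
  i <- findInterval(s, poly$cum, all.inside = TRUE)
  w <- (s - poly$cum[i]) / max(poly$cum[i + 1L] - poly$cum[i], 1e-12)
  poly$pts[i, ] + w * (poly$pts[i + 1L, ] - poly$pts[i, ])
}

#' Resolve branch specs into absolute, densely sampled curves
#'
#' Positions child curves on their parent's surface, samples every curve
#' densely (arc-length tolerance well below a voxel edge), and validates
#' the assumptions the simulator guarantees: specs form a tree, each
#' schedule fits on its curve, a child at first appearance is shorter than
#' its parent (time-series dense enough to observe the hierarchy), and
#' non-adjacent branches do not touch (no loops).
#'
#' @param specs list of [branch_spec()] objects, parents before children.
#' @return the specs, each augmented with `$poly` (dense polyline) and
#'   `$origin`.
#' @export
resolve_branch_specs <- function(specs) {
  names(specs) <- vapply(specs, `[[`, character(1L), "name")
  if (anyDuplicated(names(specs))) stop("duplicate spec names")
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (is.null(sp$parent)) {
      abs_ctrl <- sp$ctrl
    } else {
      if (!sp$parent %in% names(specs)[seq_len(i - 1L)]) {
        stop("parent '", sp$parent, "' must be resolved before '",
             sp$name, "' (specs must form a tree, parents first)")
      }
      par <- specs[[sp$parent]]
      P <- .polyline_point(par$poly, sp$attach_s)
      d0 <- sp$ctrl[2L, ] - sp$ctrl[1L, ]
      d0 <- d0 / sqrt(sum(d0^2))
      origin <- P + par$radius * d0
      abs_ctrl <- sweep(sp$ctrl, 2L, -origin)
      # A3: at first appearance the child is shorter than its parent
      pa_t <- sp$appear - par$appear + 1L
      if (pa_t < 1L || pa_t > length(par$schedule)) {
        stop("child '", sp$name, "' appears before its parent")
      }
      if (sp$schedule[1L] >= par$schedule[pa_t]) {
        stop("spec violates growth-order assumption: '", sp$name,
             "' is not shorter than its parent at first appearance")
      }
    }
    sp$poly <- .spline_polyline(abs_ctrl)
    total <- sp$poly$cum[length(sp$poly$cum)]
    if (max(sp$schedule) > total + 1e-6) {
      stop("schedule of '", sp$name, "' exceeds its curve length (",
           sprintf("%.2f > %.2f", max(sp$schedule), total), ")")
    }
    sp$origin <- sp$poly$pts[1L, ]
    specs[[i]] <- sp
  }
  .check_no_contacts(specs)
  specs
}

# non-adjacent branch curves must stay further apart than the sum of
# radii (touching branches would create loops in the voxelization)
.check_no_contacts <- function(specs) {
  n <- length(specs)
  if (n < 2L) return(invisible())
  sub <- function(sp, skip) {
    keep <- which(sp$poly$cum >= skip)
    idx <- keep[unique(round(seq(1L, length(keep), length.out = 120L)))]
    sp$poly$pts[idx, , drop = FALSE]
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (identical(specs[[j]]$parent, specs[[i]]$name) ||
          identical(specs[[i]]$parent, specs[[j]]$name)) next
      lim <- specs[[i]]$radius + specs[[j]]$radius
      # skip the emergence zone: siblings legitimately start close to a
      # shared parent without touching along their free length
      a <- sub(specs[[i]], 3 * lim)
      b <- sub(specs[[j]], 3 * lim)
      if (nrow(a) == 0L || nrow(b) == 0L) next
      d <- min(nn_nearest(a, b, cell = lim)$distance)
      if (d < lim) {
        stop("specs violate A2: branches '", specs[[i]]$name, "' and '",
             specs[[j]]$name, "' touch (distance ",
             sprintf("%.2f < %.2f", d, lim), " mm)")
      }
    }
  }
  invisible()
}

# tip arc length of a spec at time t (NA before appearance)
.tip_arclength <- function(sp, t) {
  if (t < sp$appear) return(NA_real_)
  k <- min(t - sp$appear + 1L, length(sp$schedule))
  sp$schedule[k]
}

#' Sweep a ball along a branch curve, truncated at time t
#'
#' A voxel belongs to the branch if its center lies within the sweep
#' radius of the curve truncated at the tip arc length scheduled for time
#' `t`. The curve is sampled at a spacing of a quarter voxel edge, so the
#' surface is reproduced to well under half an edge. Sample positions for
#' a shorter truncation are a prefix of those for a longer one, so growth
#' is nested by construction.
#'
#' @param spec a resolved [branch_spec()] (see [resolve_branch_specs()];
#'   a top-level spec can also be passed unresolved).
#' @param t time index.
#' @param edge_length voxel edge in mm.
#' @return integer matrix of voxel grid coordinates (possibly 0 rows if
#'   the branch has not appeared at `t`).
#' @export
sweep_branch <- function(spec, t, edge_length) {
  if (is.null(spec$poly)) {
    if (!is.null(spec$parent)) {
      stop("child specs must be resolved with resolve_branch_specs()")
    }
    spec$poly <- .spline_polyline(spec$ctrl)
  }
  if (spec$radius < edge_length / 2) {
    warning("sweep radius below half a voxel edge: branch may disconnect",
            call. = FALSE)
  }
  L <- .tip_arclength(spec, t)
  if (is.na(L)) return(matrix(integer(0), 0L, 3L))
  .stamp_tube(spec$poly, L, spec$radius, edge_length)
}

.stamp_tube <- function(poly, L, radius, edge_length) {
  total <- poly$cum[length(poly$cum)]
  L <- min(L, total)
  delta <- edge_length / 4
  s_grid <- seq(0, total, by = delta)
  s_grid <- s_grid[s_grid <= L]
  samples <- t(vapply(s_grid, function(s) .polyline_point(poly, s),
                      numeric(3L)))
  offs <- .ball_offsets(radius / edge_length + sqrt(3) / 2)
  base <- round(samples / edge_length)
  ns <- nrow(samples); no <- nrow(offs)
  si <- rep(seq_len(ns), each = no)
  cand <- base[si, , drop = FALSE] + offs[rep(seq_len(no), times = ns), ,
                                          drop = FALSE]
  d2 <- rowSums((cand * edge_length - samples[si, , drop = FALSE])^2)
  cand <- cand[d2 <= radius^2, , drop = FALSE]
  unique(cand)
}

#' Voxelized ball (used for the synthetic seed)
#' @param center center in mm.
#' @param radius radius in mm.
#' @param edge_length voxel edge in mm.
#' @return integer matrix of grid coordinates.
#' @export
voxel_ball <- function(center, radius, edge_length) {
  offs <- .ball_offsets(radius / edge_length)
  sweep(offs, 2L, -round(center / edge_length))
}

#' Generate a ground-truthed synthetic root time-series
#'
#' Builds the union of swept branches (plus an optional seed ball at the
#' top) for every timepoint. Growth is nested by construction, and the
#' spec validation guarantees a loop-free tree in which every child is
#' shorter than its parent when it first appears. Optionally each
#' timepoint t >= 1 is perturbed by a random rigid motion (re-voxelized on
#' the grid), to exercise the registration; the true motions are
#' returned.
#'
#' @param specs list of [branch_spec()] objects.
#' @param T last time index.
#' @param edge_length voxel edge in mm.
#' @param seed_ball_radius optional radius (mm) of a ball stamped at
#'   `seed_ball_center`.
#' @param seed_ball_center center of the seed ball (mm); default the
#'   origin of the first spec.
#' @param perturb apply random rigid motions to t >= 1.
#' @param max_angle,max_shift_edges perturbation bounds (degrees; voxel
#'   edges).
#' @param seed RNG seed for the perturbations.
#' @return list with `series` (a [time_series()]), `truth` (ground-truth
#'   data.frame, one row per branch per existing timepoint: arc `length`,
#'   `chord`, `tortuosity`, `volume_mm3` incl. end-cap correction,
#'   `angle_deg` of the chord to vertical, tip coordinates in the frame of
#'   shape 0), `motions` (list of true motions carrying each perturbed
#'   shape back to the base frame; identity when `perturb = FALSE`), and
#'   `seed_ball_volume_mm3` (analytic seed-ball volume, 0 when absent).
#' @export
generate_series <- function(specs, T, edge_length,
                            seed_ball_radius = NULL,
                            seed_ball_center = NULL,
                            perturb = FALSE, max_angle = 20,
                            max_shift_edges = 10, seed = 1L) {
  specs <- resolve_branch_specs(specs)
  stopifnot(T >= 0L)
  if (min(vapply(specs, `[[`, integer(1L), "appear")) > 0L) {
    stop("at least one branch must exist at t = 0")
  }
  ball <- NULL
  if (!is.null(seed_ball_radius)) {
    ctr <- seed_ball_center %||% specs[[1L]]$origin
    ball <- voxel_ball(ctr, seed_ball_radius, edge_length)
  }
  shapes <- vector("list", T + 1L)
  motions <- vector("list", T + 1L)
  motions[[1L]] <- rigid_motion()
  set.seed(seed)
  for (t in 0:T) {
    vox <- do.call(rbind, c(lapply(specs, sweep_branch, t = t,
                                   edge_length = edge_length),
                            list(ball)))
    vox <- unique(vox)
    if (t >= 1L) {
      if (perturb) {
        ax <- rnorm(3L); ax <- ax / sqrt(sum(ax^2))
        ang <- runif(1L, -max_angle, max_angle)
        tr <- runif(3L, -1, 1) * max_shift_edges * edge_length
        m <- axis_rotation(ax, ang, tr)       # base frame -> perturbed frame
        motions[[t + 1L]] <- invert_motion(m) # maps shape t back to base
        vox <- unique(round(apply_motion(m, vox * edge_length) / edge_length))
      } else {
        motions[[t + 1L]] <- rigid_motion()
      }
    }
    shapes[[t + 1L]] <- voxel_shape(vox, edge_length, t)
  }
  truth <- .ground_truth(specs, T)
  list(series = time_series(shapes), truth = truth, motions = motions,
       seed_ball_volume_mm3 = if (is.null(seed_ball_radius)) 0 else
         (4 / 3) * pi * seed_ball_radius^3)
}

.ground_truth <- function(specs, T) {
  rows <- list()
  for (sp in specs) {
    for (t in 0:T) {
      L <- .tip_arclength(sp, t)
      if (is.na(L)) next
      tip <- .polyline_point(sp$poly, L)
      chordv <- tip - sp$origin
      chord <- sqrt(sum(chordv^2))
      r <- sp$radius
      # tip end-cap always free; the start cap of a child is buried in
      # its parent, a top-level branch keeps both caps
      caps <- if (is.null(sp$parent)) 2 else 1
      vol <- pi * r^2 * L + caps * (2 / 3) * pi * r^3
      rows[[length(rows) + 1L]] <- data.frame(
        branch = sp$name, t = t, length = L, chord = chord,
        tortuosity = if (chord > 0) L / chord else NA_real_,
        volume_mm3 = vol, radius = r,
        angle_deg = if (chord > 0)
          acos(min(1, abs(chordv[3L]) / chord)) * 180 / pi else NA_real_,
        parent = sp$parent %||% NA_character_,
        tip_x = tip[1L], tip_y = tip[2L], tip_z = tip[3L]
      )
    }
  }
  do.call(rbind, rows)
}

#' Compare a computed trait table against generator ground truth
#'
#' Matches computed branches to ground-truth branches by tip proximity at
#' each timepoint and reports relative errors of length, volume, and
#' tortuosity, per branch and overall. Unmatched ground-truth rows are
#' reported as misses.
#'
#' @param traits a [trait_table()] result.
#' @param truth the `truth` element from [generate_series()].
#' @param match_gate maximal tip-tip distance (mm) for a match.
#' @return list: `per_row` (matched rows with relative errors), `misses`
#'   (unmatched truth rows), `overall` (mean relative error per trait;
#'   `NA` with `undefined = TRUE` when nothing matched).
#' @export
evaluate_against_truth <- function(traits, truth, match_gate = 6) {
  per <- list(); misses <- list()
  for (t in sort(unique(truth$t))) {
    tr <- traits[traits$t == t, , drop = FALSE]
    th <- truth[truth$t == t, , drop = FALSE]
    if (nrow(tr) == 0L) { misses[[length(misses) + 1L]] <- th; next }
    tips <- as.matrix(tr[, c("tip_x", "tip_y", "tip_z")])
    qs <- as.matrix(th[, c("tip_x", "tip_y", "tip_z")])
    nn <- nn_nearest(tips, qs)
    for (i in seq_len(nrow(th))) {
      if (nn$distance[i] > match_gate) {
        misses[[length(misses) + 1L]] <- th[i, , drop = FALSE]
        next
      }
      cr <- tr[nn$index[i], ]
      per[[length(per) + 1L]] <- data.frame(
        branch = th$branch[i], t = t, branch_id = cr$branch_id,
        tip_distance = nn$distance[i],
        length_rel_err = abs(cr$length - th$length[i]) / th$length[i],
        volume_rel_err = abs(cr$volume_mm3 - th$volume_mm3[i]) /
          th$volume_mm3[i],
        tortuosity_rel_err = abs(cr$tortuosity - th$tortuosity[i]) /
          th$tortuosity[i]
      )
    }
  }
  per <- if (length(per)) do.call(rbind, per) else NULL
  misses <- if (length(misses)) do.call(rbind, misses) else NULL
  overall <- if (is.null(per)) {
    data.frame(length = NA_real_, volume = NA_real_, tortuosity = NA_real_,
               undefined = TRUE)
  } else {
    data.frame(length = mean(per$length_rel_err),
               volume = mean(per$volume_rel_err),
               tortuosity = mean(per$tortuosity_rel_err),
               undefined = FALSE)
  }
  list(per_row = per, misses = misses, overall = overall)
}
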
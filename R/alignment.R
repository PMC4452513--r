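# nearest neighbours of `query` among `target` rows (both n x 3, mm);
# `cell` is the hash-grid cell size, defaulting to a scale-appropriate value
nn_nearest <- function(target, query, cell = NULL) {
  target <- rbind(target); query <- rbind(query)
  if (is.null(cell)) {
    span <- max(apply(target, 2L, function(c) diff(range(c))), 1e-9)
    cell <- max(span / max(8, ceiling(nrow(target)^(1 / 3))), 1e-9)
  }
  .nn_query(target, query, cell)
}

.subsample_rows <- function(x, cap, seed) {
  if (nrow(x) <= cap) return(x)
  set.seed(seed)
  x[sample.int(nrow(x), cap), , drop = FALSE]
}

# fraction of (sampled) target points within delta of a source point,
# after moving target by `motion`
.overlap_score <- function(source, target_sample, motion, delta, cell) {
  moved <- apply_motion(motion, target_sample)
  mean(.nn_query(source, moved, cell)$distance <= delta)
}

#' Coarse rigid registration by 4-point congruent sets
#'
#' Randomized global registration: wide, approximately coplanar 4-point
#' bases are drawn from `source`; for each base, congruent 4-point
#' configurations are extracted from `target` using the affine invariance
#' of the two intersection ratios of the base, and each candidate rigid
#' motion is scored by the fraction of target points that land within
#' `delta` of a source point. The best-scoring motion (mapping `target`
#' onto `source`) is returned. Designed for nested growth series where the
#' source (earlier) shape is contained in the target (later) shape.
#'
#' @param source n x 3 matrix of source points (mm) - the reference frame.
#' @param target m x 3 matrix of target points (mm) to be moved onto
#'   `source`.
#' @param overlap_fraction expected fraction of target points with a source
#'   counterpart; used for early termination and failure detection.
#' @param delta congruence / scoring tolerance in mm (default: estimated
#'   point spacing).
#' @param seed RNG seed for base selection and subsampling.
#' @param max_bases number of 4-point bases to try.
#' @param max_rotation reject candidate motions rotating by more than
#'   this many degrees (`Inf` disables the filter). Successive
#'   acquisitions of a fixed imaging platform differ by small
#'   repositioning motions, so large rotations indicate a spurious
#'   near-symmetry match.
#' @return a [rigid_motion()] with attribute `"score"`.
#' @export
coarse_align_4pcs <- function(source, target, overlap_fraction = 0.5,
                              delta = NULL, seed = 1L, max_bases = 32L,
                              max_rotation = Inf) {
  source <- rbind(source); target <- rbind(target)
  if (nrow(source) < 4L || nrow(target) < 4L) {
    stop("4PCS needs at least 4 points in each set")
  }
  .check_noncollinear(source); .check_noncollinear(target)
  spacing <- .point_spacing(source)
  if (is.null(delta)) delta <- spacing
  set.seed(seed)
  src <- .subsample_rows(source, 1000L, seed)
  tgt <- .subsample_rows(target, 1000L, seed + 1L)
  # fixed scoring sets: a small probe for triage, larger sets to rank
  score_src <- .subsample_rows(source, 1500L, seed + 3L)
  score_tgt <- .subsample_rows(target, 1500L, seed + 5L)
  probe <- .subsample_rows(target, 80L, seed + 4L)
  tgt_sample <- .subsample_rows(target, 400L, seed + 2L)
  src_sample <- .subsample_rows(source, 400L, seed + 6L)
  # tolerances must match the sparser subsampled clouds, not the raw
  # voxel spacing
  eps <- max(1.5 * delta, 1.25 * .point_spacing(tgt))
  delta_ts <- max(delta, 1.5 * .point_spacing(score_src))
  delta_st <- max(delta, 1.5 * .point_spacing(score_tgt))
  cell <- max(delta_ts, spacing)
  dt <- as.matrix(dist(tgt))
  diam <- max(dist(src))
  # symmetric score: (a) fraction of target points within delta of a
  # source point (bounded by overlap_fraction under growth) and (b)
  # fraction of source points covered by the moved target (near 1 for the
  # correct motion of a nested series, low for spurious overlays)
  full_score <- function(m) {
    a <- .overlap_score(score_src, tgt_sample, m, delta_ts, cell)
    moved_tgt <- apply_motion(m, score_tgt)
    b <- mean(.nn_query(moved_tgt, src_sample, cell)$distance <= delta_st)
    0.5 * (a + b)
  }
  ceiling_score <- 0.5 * (overlap_fraction + 1)
  accept <- 0.85 * ceiling_score

  best <- NULL; best_score <- -Inf
  for (trial in seq_len(max_bases)) {
    base <- .pick_coplanar_base(src, diam, eps)
    if (is.null(base)) next
    cand <- .congruent_sets(tgt, dt, base, eps)
    if (is.null(cand) || nrow(cand) == 0L) next
    take <- head(order(cand[, 5L]), 20L)
    for (ci in take) {
      q <- tgt[cand[ci, 1:4], , drop = FALSE]
      m <- tryCatch(.fit_rigid(q, base$pts), error = function(e) NULL)
      if (is.null(m)) next
      # require the 4 base points to actually match
      res <- apply_motion(m, q) - base$pts
      if (max(sqrt(rowSums(res^2))) > 2 * eps) next
      if (motion_angle(m) > max_rotation) next
      sc <- .overlap_score(score_src, probe, m, delta_ts, cell)
      if (sc <= 0.1) next
      sc <- full_score(m)
      if (sc > best_score) { best_score <- sc; best <- m }
    }
    if (best_score >= accept) break
  }
  if (is.null(best) || best_score < 0.3 * ceiling_score) {
    stop("4PCS failed: no congruent base found (best score ",
         sprintf("%.3f", max(best_score, 0)), ")")
  }
  attr(best, "score") <- best_score
  best
}

.check_noncollinear <- function(pts) {
  if (nrow(pts) >= 3L) {
    s <- svd(sweep(pts, 2L, colMeans(pts)))$d
    if (s[2L] < 1e-9 * max(s[1L], 1e-12)) stop("degenerate (collinear) point set")
  }
}

# typical nearest-neighbour spacing: distance from a scattered subsample
# to the rest of the cloud (the subsample is excluded so points cannot
# match themselves)
.point_spacing <- function(pts) {
  n <- nrow(pts)
  if (n < 5L) return(1)
  idx <- unique(round(seq(1L, n, length.out = min(200L, n %/% 2L))))
  d <- nn_nearest(pts[-idx, , drop = FALSE], pts[idx, , drop = FALSE])$distance
  max(stats::median(d), 1e-9)
}

# pick a wide approximately coplanar base a,b,c,d from `src` such that
# segments (a,b) and (c,d) intersect; returns the 4 points, the two
# intersection ratios and the segment lengths
.pick_coplanar_base <- function(src, diam, eps) {
  n <- nrow(src)
  for (k in 1:25) {
    ids <- sample.int(n, 3L)
    a <- src[ids[1L], ]; b <- src[ids[2L], ]; c <- src[ids[3L], ]
    ab <- b - a
    if (sqrt(sum(ab^2)) < 0.25 * diam) next
    nrm <- .cross3(ab, c - a)
    if (sqrt(sum(nrm^2)) < 1e-8) next
    nrm <- nrm / sqrt(sum(nrm^2))
    # coplanar candidates for d
    dist_pl <- abs(as.numeric(sweep(src, 2L, a) %*% nrm))
    cand <- which(dist_pl <= eps)
    cand <- setdiff(cand, ids)
    if (length(cand) == 0L) next
    d_id <- cand[sample.int(length(cand), 1L)]
    d <- src[d_id, ]
    seg <- .segment_intersection(a, b, c, d)
    if (is.null(seg)) next
    return(list(pts = rbind(a, b, c, d), r1 = seg$r1, r2 = seg$r2,
                d1 = sqrt(sum((b - a)^2)), d2 = sqrt(sum((d - c)^2))))
  }
  NULL
}

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

# closest-approach parameters of lines a+s(b-a), c+t(d-c); accept if the
# approach is tight and both parameters fall inside the segments
.segment_intersection <- function(a, b, c, d) {
  u <- b - a; v <- d - c; w <- a - c
  uu <- sum(u * u); vv <- sum(v * v); uv <- sum(u * v)
  den <- uu * vv - uv^2
  if (den < 1e-10 * uu * vv) return(NULL)
  s <- (uv * sum(v * w) - vv * sum(u * w)) / den
  t <- (uu * sum(v * w) - uv * sum(u * w)) / den
  if (s < 0.05 || s > 0.95 || t < 0.05 || t > 0.95) return(NULL)
  p1 <- a + s * u; p2 <- c + t * v
  if (sqrt(sum((p1 - p2)^2)) > 0.2 * sqrt(min(uu, vv))) return(NULL)
  list(r1 = s, r2 = t)
}

# candidate congruent 4-tuples in the target: pairs matching the base
# segment lengths generate putative intersection points e1/e2; matching
# e1 ~ e2 yields candidates, returned with the e-distance as quality
.congruent_sets <- function(tgt, dt, base, eps) {
  m <- nrow(tgt)
  p1 <- .pairs_with_length(dt, base$d1, eps)
  p2 <- .pairs_with_length(dt, base$d2, eps)
  if (is.null(p1) || is.null(p2)) return(NULL)
  if (nrow(p1) > 4000L) p1 <- p1[sample.int(nrow(p1), 4000L), , drop = FALSE]
  if (nrow(p2) > 4000L) p2 <- p2[sample.int(nrow(p2), 4000L), , drop = FALSE]
  e1 <- tgt[p1[, 1L], , drop = FALSE] +
    base$r1 * (tgt[p1[, 2L], , drop = FALSE] - tgt[p1[, 1L], , drop = FALSE])
  e2 <- tgt[p2[, 1L], , drop = FALSE] +
    base$r2 * (tgt[p2[, 2L], , drop = FALSE] - tgt[p2[, 1L], , drop = FALSE])
  hit <- .nn_query(e1, e2, max(eps, 1e-6))
  ok <- which(hit$distance <= eps)
  if (length(ok) == 0L) return(NULL)
  cbind(p1[hit$index[ok], 1L], p1[hit$index[ok], 2L],
        p2[ok, 1L], p2[ok, 2L], hit$distance[ok])
}

.pairs_with_length <- function(dt, len, eps) {
  hit <- which(abs(dt - len) <= eps & upper.tri(dt), arr.ind = TRUE)
  if (nrow(hit) == 0L) return(NULL)
  # both orderings of each pair
  rbind(hit, hit[, 2:1, drop = FALSE])
}

#' Refine a rigid registration by iterative closest point
#'
#' Point-to-point ICP. Correspondences are drawn from a fixed, seeded
#' sample of the source side (the earlier, smaller shape), so growth
#' voxels present only in the target do not bias the fit. Each iteration
#' pairs every sampled source point with its nearest moved target point
#' and solves the least-squares rigid fit; the RMS residual is
#' non-increasing across iterations.
#'
#' @param source n x 3 source points (mm), the reference.
#' @param target m x 3 target points (mm), moved onto the source.
#' @param initial starting [rigid_motion()] (e.g. from
#'   [coarse_align_4pcs()]).
#' @param max_iter iteration cap.
#' @param tol stop when the RMS improvement drops below this (mm).
#' @param sample_cap maximum number of source correspondences.
#' @param seed RNG seed for the source sample.
#' @return the refined [rigid_motion()], with attributes `"rms"` (final
#'   RMS residual, mm) and `"rms_trace"` (per-iteration RMS).
#' @export
refine_icp <- function(source, target, initial = rigid_motion(),
                       max_iter = 50L, tol = 1e-3, sample_cap = 5000L,
                       seed = 1L) {
  source <- rbind(source); target <- rbind(target)
  if (nrow(source) == 0L || nrow(target) == 0L) stop("empty point set")
  stopifnot(inherits(initial, "rigid_motion"))
  src <- .subsample_rows(source, sample_cap, seed)
  cell0 <- .point_spacing(target)
  motion <- initial
  trace <- numeric(0)
  prev <- Inf
  span <- max(apply(target, 2L, function(x) diff(range(x))))
  for (it in seq_len(max_iter)) {
    moved <- apply_motion(motion, target)
    # match the search cell to the current residual scale: early
    # iterations query far from the cloud, late ones sit on it
    cell <- if (is.finite(prev)) max(cell0, prev / 2) else
      max(cell0, span / 30)
    nn <- .nn_query(moved, src, cell)
    rms <- sqrt(mean(nn$distance^2))
    trace <- c(trace, rms)
    if (prev - rms < tol && it > 1L) break
    prev <- rms
    corr <- target[nn$index, , drop = FALSE]
    motion <- .fit_rigid(corr, src)
  }
  attr(motion, "rms") <- trace[length(trace)]
  attr(motion, "rms_trace") <- trace
  motion
}

#' Align a whole time-series into the frame of the first shape
#'
#' Computes the motion `M_0t` that carries shape `t` into the coordinate
#' frame of shape 0, for every `t`. When the shapes already overlap well
#' at identity (the usual case for a fixed imaging platform) the coarse
#' stage is skipped and ICP refines from the identity; otherwise a 4PCS
#' search provides the starting motion. Shapes whose post-alignment
#' average sample distance exceeds `exclude_threshold` voxel edges are
#' flagged as excluded.
#'
#' @param series a [time_series()].
#' @param config a [pipeline_config()] (controls 4PCS/ICP parameters,
#'   sampling caps, seeds, exclusion threshold).
#' @return object of class `aligned_series`: the series, a list of
#'   `motions` (`M_0t`, index t+1; `M_00` = identity), per-timepoint
#'   `quality` (average sampled nearest-neighbour distance in voxel-edge
#'   units, `NA` for t = 0), logical `excluded`, and a list of per-t
#'   `errors` (message or NULL).
#' @export
align_series <- function(series, config = pipeline_config(series$shapes[[1L]]$edge_length)) {
  stopifnot(inherits(series, "time_series"))
  T <- series$T
  edge <- series$shapes[[1L]]$edge_length
  src <- voxel_centers(series$shapes[[1L]])
  src_cap <- .subsample_rows(src, config$point_cap, config$seed)
  motions <- vector("list", T + 1L)
  errors <- vector("list", T + 1L)
  motions[[1L]] <- rigid_motion()
  probe <- .subsample_rows(src_cap, 500L, config$seed + 31L)
  for (t in seq_len(T)) {
    tgt <- voxel_centers(series$shapes[[t + 1L]])
    tgt_cap <- .subsample_rows(tgt, config$point_cap, config$seed + t)
    # nested growth: the attainable target overlap is the size ratio
    of <- config$overlap_fraction %||%
      min(1, n_voxels(series$shapes[[1L]]) /
            n_voxels(series$shapes[[t + 1L]]))
    attempt <- function(try_id) {
      init <- rigid_motion()
      d0 <- mean(nn_nearest(tgt_cap, probe)$distance)
      if (d0 > config$coarse_trigger * edge || try_id > 1L) {
        init <- coarse_align_4pcs(src_cap, tgt_cap,
                                  overlap_fraction = of,
                                  delta = config$delta %||% edge,
                                  seed = config$seed + 101L * t +
                                    1009L * try_id,
                                  max_bases = config$fourpcs_bases,
                                  max_rotation = config$max_rotation)
      }
      m <- refine_icp(src_cap, tgt_cap, init,
                      max_iter = config$icp_max_iter,
                      tol = config$icp_tol, sample_cap = 5000L,
                      seed = config$seed + 7L * t)
      # residual from the source side: small iff registration succeeded
      moved <- apply_motion(m, tgt_cap)
      attr(m, "src_resid") <- mean(nn_nearest(moved, probe,
                                              cell = edge)$distance)
      m
    }
    m <- tryCatch(attempt(1L), error = function(e) e)
    # a failed global search shows up as a large source-side residual;
    # retry the coarse stage with fresh bases before giving up
    for (retry in 2:3) {
      ok <- !inherits(m, "error") &&
        attr(m, "src_resid") <= 1.0 * edge
      if (ok) break
      m2 <- tryCatch(attempt(retry), error = function(e) e)
      better <- inherits(m2, "rigid_motion") &&
        (inherits(m, "error") ||
           attr(m2, "src_resid") < attr(m, "src_resid"))
      if (better) m <- m2
    }
    if (inherits(m, "error")) {
      errors[[t + 1L]] <- conditionMessage(m)
      motions[[t + 1L]] <- rigid_motion()
    } else {
      motions[[t + 1L]] <- m
    }
  }
  aligned <- structure(
    list(series = series, motions = motions, quality = rep(NA_real_, T + 1L),
         excluded = rep(FALSE, T + 1L), errors = errors, edge_length = edge),
    class = "aligned_series"
  )
  if (T >= 1L) {
    q <- alignment_quality(aligned, sample_fraction = 0.10,
                           seed = config$seed,
                           exclude_threshold = config$exclude_threshold)
    aligned$quality <- c(NA_real_, q$avg_distance_edges)
    aligned$excluded <- c(FALSE, q$excluded)
    failed <- which(!vapply(errors, is.null, logical(1L)))
    aligned$excluded[failed] <- TRUE
  }
  aligned
}

#' @export
print.aligned_series <- function(x, ...) {
  cat(sprintf("<aligned_series> T = %d; avg NN distance (edges): %s\n",
              x$series$T,
              paste(sprintf("%.2f", x$quality[-1L]), collapse = ", ")))
  if (any(x$excluded)) {
    cat("  excluded timepoints:",
        paste(which(x$excluded) - 1L, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rigid motion between two timepoints of an aligned series
#'
#' `M_st = M_0s^{-1} . M_0t` maps shape `t` into the frame of shape `s`.
#'
#' @param aligned an [align_series()] result.
#' @param s,t timepoint indices (0-based).
#' @return a [rigid_motion()].
#' @export
motion_between <- function(aligned, s, t) {
  compose_motion(invert_motion(aligned$motions[[s + 1L]]),
                 aligned$motions[[t + 1L]])
}

#' Alignment quality: average sampled distance per timepoint
#'
#' Samples a fraction of the voxels of the first shape and, for every
#' later timepoint, averages the Euclidean distance from each sampled
#' voxel center to the closest voxel of the aligned later shape,
#' expressed in voxel-edge units. Timepoints beyond `exclude_threshold`
#' edges are flagged for exclusion.
#'
#' @param aligned an [align_series()] result (>= 2 shapes).
#' @param sample_fraction fraction of first-shape voxels to sample.
#' @param seed RNG seed for the sample.
#' @param exclude_threshold flag threshold in voxel-edge units.
#' @return data.frame with columns `time_index`, `avg_distance_edges`,
#'   `excluded`.
#' @export
alignment_quality <- function(aligned, sample_fraction = 0.10, seed = 1L,
                              exclude_threshold = 10.0) {
  stopifnot(inherits(aligned, "aligned_series"))
  series <- aligned$series
  if (series$T < 1L) stop("alignment_quality needs at least 2 shapes")
  edge <- aligned$edge_length
  src <- voxel_centers(series$shapes[[1L]])
  k <- max(1L, round(sample_fraction * nrow(src)))
  set.seed(seed)
  sample_pts <- src[sample.int(nrow(src), k), , drop = FALSE]
  avg <- vapply(seq_len(series$T), function(t) {
    moved <- apply_motion(aligned$motions[[t + 1L]],
                          voxel_centers(series$shapes[[t + 1L]]))
    mean(nn_nearest(moved, sample_pts, cell = edge)$distance) / edge
  }, numeric(1L))
  data.frame(time_index = seq_len(series$T),
             avg_distance_edges = avg,
             excluded = avg > exclude_threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
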
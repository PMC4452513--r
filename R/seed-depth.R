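#' Detect the seed area of a shape
#'
#' Performs principal component analysis on the voxels within Euclidean
#' radius `R` (in voxel units) of every voxel. A voxel whose neighbourhood
#' covariance has three similar eigenvalues (smallest/largest >=
#' `sphericity`) sits in a locally spherical region. The seed area is the
#' largest connected component of such voxels, dilated by all shape voxels
#' within offset `R` of it. If no voxel qualifies, or the spherical region
#' exceeds `max_fraction` of the total volume (as in a compact blob-like
#' shape), the fall-back seed is the voxel nearest the centroid of the
#' topmost horizontal slice. What matters downstream is not the biological
#' truth of this region but that its location is consistent across the
#' series, which propagation ensures.
#'
#' @param shape a [voxel_shape()].
#' @param R neighbourhood radius in voxels; a good choice is between one
#'   and two average branch radii.
#' @param sphericity eigenvalue-ratio threshold (smallest/largest).
#' @param max_fraction maximal allowed fraction of spherical voxels before
#'   falling back.
#' @return object of class `seed_area`: `voxels` (integer matrix, subset
#'   of the shape), `indices` (rows into `shape$voxels`),
#'   `detection_mode` (`"pca"` or `"fallback_top_slice"`).
#' @export
detect_seed <- function(shape, R = 3, sphericity = 0.6, max_fraction = 0.25) {
  stopifnot(R >= 1)
  v <- shape$voxels
  n <- nrow(v)
  offs <- .ball_offsets(R)
  present <- .offset_membership(v, offs)
  # neighbourhood covariance from offset coordinates (centering removes
  # the voxel's own position)
  ratio <- .eigen_ratio(present, offs)
  spherical <- which(ratio >= sphericity)
  mode <- "pca"
  idx <- integer(0)
  if (length(spherical) == 0L || length(spherical) > max_fraction * n) {
    mode <- "fallback_top_slice"
  } else {
    comp_idx <- .largest_voxel_subset_component(v, spherical)
    # dilate: all shape voxels within Euclidean R of the component
    near <- nn_nearest(v[comp_idx, , drop = FALSE], v, cell = 1)
    idx <- which(near$distance <= R)
  }
  if (mode == "fallback_top_slice") {
    top <- which(v[, 3L] == max(v[, 3L]))
    centroid <- colMeans(v[top, , drop = FALSE])
    d2 <- rowSums(sweep(v[top, , drop = FALSE], 2L, centroid)^2)
    idx <- top[which.min(d2)]
  }
  structure(list(voxels = v[idx, , drop = FALSE], indices = idx,
                 detection_mode = mode),
            class = "seed_area")
}

#' @export
print.seed_area <- function(x, ...) {
  cat(sprintf("<seed_area> %d voxels (%s)\n", nrow(x$voxels),
              x$detection_mode))
  invisible(x)
}

.ball_offsets <- function(R) {
  r <- ceiling(R)
  g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  g[rowSums(g^2) <= R^2, , drop = FALSE]
}

# n x k logical matrix: is voxel i + offset j present in the shape?
.offset_membership <- function(v, offs) {
  box <- vox_box(v, pad = max(abs(offs)) + 1L)
  key <- vox_key(v, box)
  keytab <- key
  out <- matrix(FALSE, nrow(v), nrow(offs))
  for (j in seq_len(nrow(offs))) {
    skey <- key + offs[j, 1L] + offs[j, 2L] * box$n[1L] +
      offs[j, 3L] * box$n[1L] * box$n[2L]
    out[, j] <- !is.na(match(skey, keytab))
  }
  out
}

# smallest/largest covariance eigenvalue of the present offsets, per voxel
.eigen_ratio <- function(present, offs) {
  k <- rowSums(present)
  sx <- present %*% offs[, 1L]; sy <- present %*% offs[, 2L]
  sz <- present %*% offs[, 3L]
  sxx <- present %*% (offs[, 1L]^2); syy <- present %*% (offs[, 2L]^2)
  szz <- present %*% (offs[, 3L]^2)
  sxy <- present %*% (offs[, 1L] * offs[, 2L])
  sxz <- present %*% (offs[, 1L] * offs[, 3L])
  syz <- present %*% (offs[, 2L] * offs[, 3L])
  n <- nrow(present)
  ratio <- numeric(n)
  for (i in seq_len(n)) {
    ki <- k[i]
    if (ki < 4) { ratio[i] <- 0; next }
    mx <- sx[i] / ki; my <- sy[i] / ki; mz <- sz[i] / ki
    C <- matrix(c(sxx[i] / ki - mx^2, sxy[i] / ki - mx * my, sxz[i] / ki - mx * mz,
                  sxy[i] / ki - mx * my, syy[i] / ki - my^2, syz[i] / ki - my * mz,
                  sxz[i] / ki - mx * mz, syz[i] / ki - my * mz, szz[i] / ki - mz^2),
                3L, 3L)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    ratio[i] <- if (ev[1L] <= 0) 0 else max(ev[3L], 0) / ev[1L]
  }
  ratio
}

# biggest connected component (26-connectivity) within a subset of
# voxels; among components of comparable size (>= half the maximum) the
# topmost one wins, since the seed of a root system sits at the top under
# the z-up convention
.largest_voxel_subset_component <- function(v, subset_idx) {
  sub <- v[subset_idx, , drop = FALSE]
  g <- build_graph(voxel_shape(sub, 1))
  comp <- igraph::components(.as_igraph(g))
  ord <- order(sub[, 1L], sub[, 2L], sub[, 3L])
  zmax <- vapply(seq_len(comp$no), function(b)
    max(sub[ord, 3L][comp$membership == b]), numeric(1L))
  cand <- which(comp$csize >= 0.5 * max(comp$csize))
  best <- cand[which.max(zmax[cand])]
  subset_idx[ord][comp$membership == best]
}

#' Propagate the seed area backwards through an aligned series
#'
#' The seed detected on the last shape is carried to every earlier shape:
#' seed voxels are mapped by the inter-timepoint motion `M_tT` and each
#' mapped point claims its nearest voxel of the earlier shape
#' (de-duplicated), giving a consistent seed location across the series.
#'
#' @param seed_T seed area detected on the last shape.
#' @param aligned an [align_series()] result.
#' @return list of `seed_area` objects for t = 0..T-1, each with
#'   `detection_mode = "propagated"`.
#' @export
propagate_seed <- function(seed_T, aligned) {
  series <- aligned$series
  T <- series$T
  edge <- aligned$edge_length
  seed_mm <- seed_T$voxels * edge
  out <- vector("list", T)
  for (t in seq_len(T) - 1L) {
    sh <- series$shapes[[t + 1L]]
    if (n_voxels(sh) == 0L) stop("empty shape at t = ", t)
    mapped <- apply_motion(motion_between(aligned, t, T), seed_mm)
    nn <- nn_nearest(voxel_centers(sh), mapped, cell = edge)
    idx <- sort(unique(nn$index))
    out[[t + 1L]] <- structure(
      list(voxels = sh$voxels[idx, , drop = FALSE], indices = idx,
           detection_mode = "propagated"),
      class = "seed_area")
  }
  out
}

#' Geodesic depth from the seed area
#'
#' Multi-source Dijkstra shortest paths on the weighted voxel graph, with
#' every seed voxel as a zero-distance source. Depth is in mm.
#'
#' @param graph a [build_graph()] result (must be connected; see
#'   [largest_component()]).
#' @param seed a `seed_area` on the same shape.
#' @return object of class `depth_field`: numeric `depth` per voxel (mm),
#'   plus the `seed`.
#' @export
compute_depth <- function(graph, seed) {
  n <- graph$n
  stopifnot(all(seed$indices >= 1L), all(seed$indices <= n))
  g <- igraph::make_empty_graph(n = n + 1L, directed = FALSE)
  ne <- rbind(graph$arcs,
              cbind(rep.int(n + 1L, length(seed$indices)), seed$indices))
  g <- igraph::add_edges(g, t(ne))
  w <- c(graph$weights, rep.int(0, length(seed$indices)))
  d <- as.numeric(igraph::distances(g, v = n + 1L, weights = w,
                                    algorithm = "dijkstra"))[seq_len(n)]
  if (any(!is.finite(d))) {
    stop("unreachable voxels: run largest_component() first")
  }
  structure(list(depth = d, seed = seed), class = "depth_field")
}

#' @export
print.depth_field <- function(x, ...) {
  cat(sprintf("<depth_field> %d voxels, max depth %.2f mm\n",
              length(x$depth), max(x$depth)))
  invisible(x)
}
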
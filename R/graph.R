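# 26-neighbour offsets, split by adjacency class
.neighbor_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  g
}

#' Weighted 26-connected voxel graph
#'
#' Nodes are the voxels of `shape`; arcs join every pair of voxels that
#' differ by at most 1 in each grid coordinate. Arc weights are the
#' Euclidean distance between the voxel centers: `edge_length` for face
#' neighbours, `sqrt(2)`/`sqrt(3)` times `edge_length` for edge and corner
#' neighbours, so that geodesic depth approximates physical path length.
#' Set `integer_weights = TRUE` to use weights 1, 2, 3 (times
#' `edge_length`) instead, for comparison.
#'
#' @param shape a [voxel_shape()].
#' @param integer_weights use integer adjacency-class weights instead of
#'   radicals.
#' @return object of class `voxel_graph`: `shape`, `arcs` (m x 2 matrix of
#'   1-based voxel row indices), `weights` (mm), `n`.
#' @export
build_graph <- function(shape, integer_weights = FALSE) {
  v <- shape$voxels
  n <- nrow(v)
  box <- vox_box(v)
  key <- vox_key(v, box)
  idx <- integer(0)
  # half of the 26 offsets, so each arc appears once
  offs <- .neighbor_offsets()
  keep <- (offs[, 3L] > 0L) | (offs[, 3L] == 0L & offs[, 2L] > 0L) |
    (offs[, 3L] == 0L & offs[, 2L] == 0L & offs[, 1L] > 0L)
  offs <- offs[keep, , drop = FALSE]
  from <- integer(0); to <- integer(0); cls <- integer(0)
  for (k in seq_len(nrow(offs))) {
    shifted <- sweep(v, 2L, -offs[k, ])  # v + offset
    skey <- vox_key(shifted, vox_box(rbind(v, shifted)))
    vkey <- vox_key(v, vox_box(rbind(v, shifted)))
    hit <- match(skey, vkey)
    ok <- which(!is.na(hit))
    if (length(ok)) {
      from <- c(from, ok)
      to <- c(to, hit[ok])
      cls <- c(cls, rep.int(sum(abs(offs[k, ])), length(ok)))
    }
  }
  w <- if (integer_weights) cls else sqrt(cls)
  structure(
    list(shape = shape, arcs = cbind(from = from, to = to),
         weights = w * shape$edge_length, adjacency_class = cls, n = n,
         integer_weights = integer_weights),
    class = "voxel_graph"
  )
}

#' @export
print.voxel_graph <- function(x, ...) {
  cat(sprintf("<voxel_graph> %d nodes, %d arcs\n", x$n, nrow(x$arcs)))
  invisible(x)
}

.as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = graph$n, directed = FALSE)
  g <- igraph::add_edges(g, t(graph$arcs))
  igraph::E(g)$weight <- graph$weights
  g
}

#' Restrict a voxel graph to its largest connected component
#'
#' Root systems are assumed connected; disconnected reconstructions are
#' reduced to the largest component with a warning. Ties between equally
#' large components go to the component containing the lexicographically
#' smallest voxel.
#'
#' @param graph a [build_graph()] result.
#' @return a `voxel_graph` on the largest component (the contained shape is
#'   subset accordingly).
#' @export
largest_component <- function(graph) {
  comp <- igraph::components(.as_igraph(graph))
  if (comp$no <= 1L) return(graph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # voxel rows are in lexicographic order: smallest member index wins
    first <- vapply(best, function(b) min(which(comp$membership == b)),
                    integer(1L))
    best <- best[which.min(first)]
  }
  keep <- which(comp$membership == best)
  dropped <- graph$n - length(keep)
  warning(sprintf(
    "shape is disconnected: dropping %d smaller component(s), %d voxel(s)",
    comp$no - 1L, dropped), call. = FALSE)
  sub_shape <- voxel_shape(graph$shape$voxels[keep, , drop = FALSE],
                           graph$shape$edge_length, graph$shape$time_index)
  build_graph(sub_shape, integer_weights = isTRUE(graph$integer_weights))
}
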
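#' Decompose a shape into a hierarchy of branches
#'
#' Traverses the voxels in order of decreasing geodesic depth, activating
#' each arc right after its shallower endpoint. Each voxel starts as its
#' own component; when an arc merges two components, the shallower
#' component's tip either absorbs into the deeper branch (its overhang
#' below the junction is shorter than `merge_threshold`) or is
#' consolidated as a branch of its own, with the junction voxel on the
#' deeper component as its fork and the deeper branch as its parent. The
#' result is a partition of the voxels into branches, each represented by
#' (tip, fork, parent), linked into a tree rooted at the branch holding
#' the globally deepest tip.
#'
#' Arcs that join two voxels already in one component are ignored
#' (spanning-tree behaviour); those that do not close a local triangle are
#' counted as candidate loops (touching branches) and reported in
#' `loop_count`.
#'
#' @param graph a connected [build_graph()] result.
#' @param depth a [compute_depth()] result on the same graph.
#' @param merge_threshold absorb threshold in mm; side paths whose tip
#'   overhang is shorter than this are treated as surface noise. Default:
#'   twice the average branch radius estimated from the shape
#'   (see [estimate_branch_radius()]).
#' @return object of class `branch_hierarchy`: data.frame `branches`
#'   (id, tip index, fork index or NA, parent id or NA, n_voxels),
#'   list `members` (voxel indices per branch), integer `branch_of`
#'   per voxel, `root_branch` id, `loop_count`.
#' @export
decompose <- function(graph, depth, merge_threshold = NULL) {
  stopifnot(inherits(graph, "voxel_graph"), inherits(depth, "depth_field"))
  if (is.null(merge_threshold)) {
    merge_threshold <- 2 * estimate_branch_radius(graph$shape, depth)
  }
  res <- .decompose_core(graph$arcs, depth$depth, merge_threshold)
  branch_of_tip <- res$branch_of        # per voxel: tip voxel index
  tips <- sort(unique(branch_of_tip))
  # order branches by decreasing tip depth (ties lexicographic = by index);
  # the root branch holds the global depth maximum and gets id 1
  ord <- order(-depth$depth[tips], tips)
  tips <- tips[ord]
  id_of_tip <- integer(graph$n)
  id_of_tip[tips] <- seq_along(tips)
  branch_of <- id_of_tip[branch_of_tip]
  members <- split(seq_len(graph$n), branch_of)
  members <- members[as.character(seq_along(tips))]
  fork <- ifelse(res$fork[tips] > 0L, res$fork[tips], NA_integer_)
  # the recorded parent tip may itself have been absorbed later; the
  # fork voxel's final branch is the authoritative parent
  parent <- ifelse(is.na(fork), NA_integer_, branch_of[pmax(fork, 1L)])
  parent[is.na(fork)] <- NA_integer_
  branches <- data.frame(
    id = seq_along(tips), tip = tips, fork = as.integer(fork),
    parent = as.integer(parent),
    n_voxels = lengths(members)
  )
  structure(list(branches = branches, members = members,
                 branch_of = branch_of,
                 root_branch = branch_of[res$root_tip],
                 loop_count = res$loop_count,
                 merge_threshold = merge_threshold),
            class = "branch_hierarchy")
}

#' @export
print.branch_hierarchy <- function(x, ...) {
  cat(sprintf("<branch_hierarchy> %d branches over %d voxels",
              nrow(x$branches), length(x$branch_of)))
  if (x$loop_count > 0L) cat(sprintf(" (%d loop candidate(s))", x$loop_count))
  cat("\n")
  invisible(x)
}

#' Crude average branch radius of a shape
#'
#' Treats the shape as a tube of the given total volume whose centerline
#' length is approximated by the maximal geodesic depth:
#' `r = sqrt(volume / (pi * max_depth))`. Used only to scale the default
#' merge threshold; not a reported trait.
#'
#' @param shape a [voxel_shape()].
#' @param depth a [compute_depth()] result.
#' @return radius estimate in mm.
#' @export
estimate_branch_radius <- function(shape, depth) {
  vol <- n_voxels(shape) * shape$edge_length^3
  len <- max(depth$depth)
  if (len <= 0) return(shape$edge_length)
  max(sqrt(vol / (pi * len)), shape$edge_length / 2)
}
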
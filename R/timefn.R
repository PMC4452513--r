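#' Reconstruct the per-voxel creation time on the final shape
#'
#' Compresses the whole time-series onto the final shape `V = V_T`. The
#' time field starts at `T` everywhere; traversing t = T-1 down to 0, each
#' branch tip of shape t is mapped (through the alignment) to its nearest
#' voxel `v` of `V`, and all voxels of the branch of `V` containing `v`
#' whose depth does not exceed the depth of `v` receive time `t`. Because
#' t runs backwards, every voxel ends up with the earliest time at which
#' it was observed. Tips whose nearest counterpart is farther than
#' `tip_gate` voxel edges are skipped (a guard against wrong-branch
#' matches under imperfect alignment) and counted in `skipped_tips`.
#'
#' @param aligned an [align_series()] result.
#' @param hierarchy the branch hierarchy of the final shape.
#' @param depth the depth field of the final shape.
#' @param per_t_hierarchies list (length T) of `branch_hierarchy` objects
#'   for shapes 0..T-1, each computed with its own propagated seed and
#'   depth.
#' @param tip_gate match gate in voxel edges.
#' @return object of class `time_field`: integer `tau` per voxel of the
#'   final shape, plus `skipped_tips`.
#' @export
compute_time <- function(aligned, hierarchy, depth, per_t_hierarchies,
                         tip_gate = 5) {
  series <- aligned$series
  T <- series$T
  edge <- aligned$edge_length
  final <- series$shapes[[T + 1L]]
  final_mm <- voxel_centers(final)
  tau <- rep.int(T, n_voxels(final))
  skipped <- 0L
  if (T >= 1L) {
    for (t in rev(seq_len(T) - 1L)) {
      if (aligned$excluded[t + 1L]) next
      ht <- per_t_hierarchies[[t + 1L]]
      if (is.null(ht)) next
      sh <- series$shapes[[t + 1L]]
      tips_mm <- sh$voxels[ht$branches$tip, , drop = FALSE] * edge
      mapped <- apply_motion(motion_between(aligned, T, t), tips_mm)
      nn <- nn_nearest(final_mm, mapped, cell = edge)
      for (k in seq_len(nrow(mapped))) {
        if (nn$distance[k] > tip_gate * edge) { skipped <- skipped + 1L; next }
        v <- nn$index[k]
        J <- hierarchy$branch_of[v]
        mem <- hierarchy$members[[J]]
        tau[mem[depth$depth[mem] <= depth$depth[v]]] <- t
      }
    }
  }
  structure(list(tau = as.integer(tau), skipped_tips = skipped),
            class = "time_field")
}

#' Assemble a growth record
#'
#' The growth record bundles the final shape with its depth field, branch
#' hierarchy, and time field; it is the single data structure from which
#' all traits are computed.
#'
#' @param graph voxel graph of the final shape.
#' @param depth its depth field.
#' @param hierarchy its branch hierarchy.
#' @param time its time field.
#' @param T last time index.
#' @return object of class `growth_record`.
#' @export
growth_record <- function(graph, depth, hierarchy, time, T) {
  structure(list(shape = graph$shape, graph = graph, depth = depth,
                 hierarchy = hierarchy, tau = time$tau, T = as.integer(T),
                 switch_events = 0L, skipped_tips = time$skipped_tips),
            class = "growth_record")
}

#' @export
print.growth_record <- function(x, ...) {
  cat(sprintf(
    "<growth_record> %d voxels, %d branches, T = %d, %d switch event(s)\n",
    n_voxels(x$shape), nrow(x$hierarchy$branches), x$T, x$switch_events))
  invisible(x)
}

# arc neighbours of one voxel
.arc_neighbors <- function(graph, v) {
  a <- graph$arcs
  c(a[a[, 1L] == v, 2L], a[a[, 2L] == v, 1L])
}

# forks where the depth hierarchy contradicts the observed growth order:
# the side branch at fork v carries a strictly earlier creation time than
# the fork voxel itself, i.e. the through-going branch at v is younger
# than its side branch.
.find_conflicts <- function(record) {
  h <- record$hierarchy
  tau <- record$tau
  out <- integer(0)
  for (b in h$branches$id) {
    fk <- h$branches$fork[b]
    if (is.na(fk)) next
    nb <- .arc_neighbors(record$graph, fk)
    nb <- nb[h$branch_of[nb] == b]
    if (length(nb) && any(tau[nb] < tau[fk])) out <- c(out, b)
  }
  if (length(out)) {
    out[order(record$depth$depth[h$branches$fork[out]])]
  } else out
}

#' Repair depth/time inconsistencies by switch operations
#'
#' When a side branch out-grows its parent between acquisitions, the
#' depth-based decomposition of the final shape makes the younger branch
#' the through-going one at the fork, which contradicts the reconstructed
#' creation times (the side branch is older at the junction than the fork
#' voxel itself). Each such conflict is repaired by a switch: with `p` the
#' side branch at fork `v`, `q` its parent and `w` the fork of `q`, the
#' part of `q` between `v` and `w` is reassigned to `p`, the fork/parent
#' pointers are exchanged so that `p` becomes the through-going branch,
#' and the time at every reassigned voxel is lowered to at most the time
#' at `v`. Forks are processed in increasing depth and the scan repeats
#' until no conflict remains or the iteration cap is reached.
#'
#' @param record a [growth_record()].
#' @param max_passes iteration cap as a multiple of the fork count.
#' @return the repaired `growth_record`; `$switch_events` holds the number
#'   of switches performed.
#' @export
repair_switches <- function(record, max_passes = 10) {
  h <- record$hierarchy
  n_forks <- sum(!is.na(h$branches$fork))
  cap <- max(1L, ceiling(max_passes * max(n_forks, 1L)))
  switches <- 0L
  repeat {
    conflicts <- .find_conflicts(record)
    if (length(conflicts) == 0L) break
    if (switches >= cap) {
      warning("switch repair did not converge within the iteration cap; ",
              "partial repair reported", call. = FALSE)
      break
    }
    record <- .do_switch(record, conflicts[1L])
    switches <- switches + 1L
  }
  record$switch_events <- switches
  record
}

# perform one switch at the fork of branch p_id
.do_switch <- function(record, p_id) {
  h <- record$hierarchy
  depth <- record$depth$depth
  v <- h$branches$fork[p_id]
  q_id <- h$branches$parent[p_id]
  mem_q <- h$members[[q_id]]
  seg <- mem_q[depth[mem_q] <= depth[v]]
  # move the segment between v and the fork of q into p
  h$members[[q_id]] <- setdiff(mem_q, seg)
  h$members[[p_id]] <- c(h$members[[p_id]], seg)
  h$branch_of[seg] <- p_id
  tv <- record$tau[v]
  record$tau[seg] <- pmin(record$tau[seg], tv)
  # p takes over q's fork and parent; q forks from p at v
  h$branches$fork[p_id] <- h$branches$fork[q_id]
  h$branches$parent[p_id] <- h$branches$parent[q_id]
  h$branches$fork[q_id] <- v
  h$branches$parent[q_id] <- p_id
  # children of q whose fork moved with the segment now hang off p
  kids <- which(h$branches$parent == q_id & h$branches$id != q_id)
  for (k in kids) {
    if (k != p_id && h$branches$fork[k] %in% seg) h$branches$parent[k] <- p_id
  }
  if (h$root_branch == q_id) h$root_branch <- p_id
  h$branches$n_voxels <- lengths(h$members)
  record$hierarchy <- h
  record
}
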
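# shared fixtures and independent oracles for the test suite

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# straight chain of n voxels along +z starting at the origin
chain_shape <- function(n, edge = 1) {
  voxel_shape(cbind(0L, 0L, seq_len(n) - 1L), edge)
}

vox_key_str <- function(m) paste(m[, 1L], m[, 2L], m[, 3L])

jaccard_voxels <- function(a, b) {
  ka <- vox_key_str(a); kb <- vox_key_str(b)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# random connected voxel blob grown by seeded random walk
random_blob <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(0L, n, 3L)
  cur <- c(0L, 0L, 0L)
  seen <- new.env(parent = emptyenv())
  assign("0 0 0", TRUE, envir = seen)
  k <- 1L
  while (k < n) {
    step <- sample(c(-1L, 0L, 1L), 3L, replace = TRUE)
    if (all(step == 0L)) next
    cand <- cur + step
    cur <- cand
    key <- paste(cand, collapse = " ")
    if (!exists(key, envir = seen)) {
      k <- k + 1L
      pts[k, ] <- cand
      assign(key, TRUE, envir = seen)
    }
  }
  voxel_shape(pts, 1)
}

# O(n^2) reference Dijkstra on a voxel graph (multi-source)
dijkstra_oracle <- function(graph, seed_indices) {
  n <- graph$n
  adj <- vector("list", n)
  for (i in seq_len(nrow(graph$arcs))) {
    u <- graph$arcs[i, 1L]; v <- graph$arcs[i, 2L]; w <- graph$weights[i]
    adj[[u]] <- rbind(adj[[u]], c(v, w))
    adj[[v]] <- rbind(adj[[v]], c(u, w))
  }
  dist <- rep(Inf, n)
  dist[seed_indices] <- 0
  done <- rep(FALSE, n)
  for (k in seq_len(n)) {
    u <- which(!done & dist == min(dist[!done]))[1L]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    if (!is.null(adj[[u]])) {
      for (j in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][j, 1L]
        nd <- dist[u] + adj[[u]][j, 2L]
        if (nd < dist[v]) dist[v] <- nd
      }
    }
  }
  dist
}

# random abstract tree built from multi-node chains. Voxel-like
# granularity: every side path keeps at least two nodes of overhang below
# any junction (attachments avoid the last two nodes of a chain), so no
# branch degenerates to a single node; continuous weights keep depths
# tie-free. Membership of the junction (attach) nodes themselves depends
# on the order in which simultaneously activated arcs are processed, so
# comparisons should exclude them.
random_tree_graph <- function(n_chains, seed) {
  set.seed(seed)
  parent <- NA_integer_
  w <- 0
  eligible <- 1L
  junctions <- integer(0)
  for (ch in seq_len(n_chains)) {
    at <- if (ch == 1L) 1L else eligible[sample.int(length(eligible), 1L)]
    if (ch > 1L) junctions <- c(junctions, at)
    len <- sample(3:10, 1L)
    first <- length(parent) + 1L
    for (j in seq_len(len)) {
      parent <- c(parent, if (j == 1L) at else length(parent))
      w <- c(w, runif(1L, 0.2, 0.6))
    }
    last <- length(parent)
    if (last - 2L >= first) eligible <- c(eligible, first:(last - 2L))
  }
  n <- length(parent)
  arcs <- cbind(2:n, parent[2:n])
  depth <- numeric(n)
  for (i in 2:n) depth[i] <- depth[parent[i]] + w[i]
  g <- structure(list(
    shape = voxel_shape(cbind(seq_len(n), 0L, 0L), 1),
    arcs = arcs, weights = w[2:n], n = n), class = "voxel_graph")
  list(graph = g, depth = structure(list(depth = depth), class = "depth_field"),
       parent = parent, junctions = unique(junctions))
}

# deepest-path-first decomposition oracle on a tree: every node belongs
# to the branch of the deepest tip in its subtree
deepest_path_oracle <- function(tree) {
  n <- tree$graph$n
  parent <- tree$parent
  depth <- tree$depth$depth
  children <- split(seq_len(n)[-1L], parent[-1L])
  deepest <- seq_len(n)   # deepest tip in the subtree of each node
  ord <- order(depth, decreasing = TRUE)
  for (v in ord) {
    kids <- children[[as.character(v)]]
    if (!is.null(kids)) {
      cand <- c(v, deepest[kids])
      deepest[v] <- cand[which.max(depth[cand])]
    }
  }
  branch_of <- deepest
  # fork of a branch = the node where its top member attaches
  tips <- unique(branch_of)
  fork <- parent_branch <- setNames(rep(NA_integer_, length(tips)),
                                    tips)
  for (tp in tips) {
    members <- which(branch_of == tp)
    top <- members[which.min(depth[members])]
    if (!is.na(parent[top])) {
      fork[as.character(tp)] <- parent[top]
      parent_branch[as.character(tp)] <- branch_of[parent[top]]
    }
  }
  list(branch_of = branch_of, fork = fork, parent_branch = parent_branch)
}

# standard analysis configuration for swept-tube fixtures at 0.5 mm:
# the PCA radius (4 voxels = 2 mm) sits between one and two primary-axis
# radii (1.5 mm), per the neighbourhood-radius guidance
fixture_config <- function(seed = 1L) {
  pipeline_config(0.5, R = 4, seed = seed)
}

fig3_gen <- function() cached("fig3_gen", {
  generate_series(validation_root_system(), T = 2, edge_length = 0.5,
                  seed_ball_radius = 4)
})

fig3_analysis <- function() cached("fig3_analysis", {
  analyze_series(fig3_gen()$series, fixture_config())
})

straight_analysis <- function() cached("straight_analysis", {
  gen <- generate_series(straight_root_spec(), T = 0, edge_length = 0.5)
  list(gen = gen, analysis = analyze_series(gen$series, fixture_config()))
})
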
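manual_seed <- function(shape, idx) {
  structure(list(voxels = shape$voxels[idx, , drop = FALSE],
                 indices = idx, detection_mode = "manual"),
            class = "seed_area")
}

# trunk of `trunk_n` voxels along -z with a side chain of `side_n` voxels
# along +y attached at trunk depth `at`
y_shape <- function(trunk_n = 21, side_n = 8, at = 10) {
  trunk <- cbind(0L, 0L, -(0:(trunk_n - 1L)))
  side <- cbind(0L, seq_len(side_n), -at)
  voxel_shape(rbind(trunk, side), 1)
}

test_that("a straight chain is a single branch with tip at the far end", {
  sh <- chain_shape(15)
  g <- build_graph(sh)
  d <- compute_depth(g, manual_seed(sh, 1L))
  h <- decompose(g, d, merge_threshold = 1)
  expect_equal(nrow(h$branches), 1L)
  expect_true(is.na(h$branches$fork[1]))
  expect_true(is.na(h$branches$parent[1]))
  expect_equal(unname(sh$voxels[h$branches$tip[1], 3L]), 14L)
})

test_that("a Y-shape splits into trunk and side branch at the junction", {
  sh <- y_shape(trunk_n = 21, side_n = 8, at = 10)
  g <- build_graph(sh)
  top <- which(sh$voxels[, 3L] == 0L & sh$voxels[, 2L] == 0L)
  d <- compute_depth(g, manual_seed(sh, top))
  h <- decompose(g, d, merge_threshold = 1)
  expect_equal(nrow(h$branches), 2L)
  root <- h$root_branch
  side <- setdiff(h$branches$id, root)
  # the trunk is deeper, so it is the through-going (root) branch
  expect_equal(unname(sh$voxels[h$branches$tip[root], 3L]), -20L)
  expect_equal(h$branches$parent[side], root)
  fk <- h$branches$fork[side]
  expect_false(is.na(fk))
  # the fork voxel sits within one voxel of the junction, on the parent
  expect_lte(unname(sh$voxels[fk, 2L]), 1L)
  expect_lte(abs(unname(sh$voxels[fk, 3L]) + 10L), 1L)
  expect_true(fk %in% h$members[[root]])
  # member sets partition the voxels
  expect_equal(sum(h$branches$n_voxels), n_voxels(sh))
  expect_equal(sort(unname(unlist(h$members))), seq_len(n_voxels(sh)))
})

test_that("side paths shorter than the merge threshold are absorbed", {
  sh <- y_shape(trunk_n = 21, side_n = 3, at = 10)
  g <- build_graph(sh)
  top <- which(sh$voxels[, 3L] == 0L & sh$voxels[, 2L] == 0L)
  d <- compute_depth(g, manual_seed(sh, top))
  expect_equal(nrow(decompose(g, d, merge_threshold = 5)$branches), 1L)
  expect_equal(nrow(decompose(g, d, merge_threshold = 1)$branches), 2L)
})

test_that("tips are depth maxima and the root tip is the global maximum", {
  gen <- fig3_gen()
  a <- fig3_analysis()
  h <- a$record$hierarchy
  d <- a$record$depth$depth
  for (b in h$branches$id) {
    expect_equal(d[h$branches$tip[b]], max(d[h$members[[b]]]))
  }
  expect_equal(d[h$branches$tip[h$root_branch]], max(d))
  expect_equal(sum(h$branches$n_voxels), n_voxels(a$record$shape))
})

test_that("decomposition equals the deepest-path oracle on random trees", {
  for (seed in 1:20) {
    tree <- random_tree_graph(10 + 3 * (seed %% 5), seed)
    h <- decompose(tree$graph, tree$depth, merge_threshold = 1e-9)
    oracle <- deepest_path_oracle(tree)
    tips_pkg <- h$branches$tip
    expect_setequal(tips_pkg, unique(oracle$branch_of))
    # identical member partition away from the junction nodes (whose
    # assignment is ambiguous: all their arcs activate at the same moment)
    free <- setdiff(seq_len(tree$graph$n), tree$junctions)
    for (b in h$branches$id) {
      mine <- intersect(h$members[[b]], free)
      theirs <- intersect(which(oracle$branch_of == tips_pkg[b]), free)
      expect_setequal(mine, theirs)
    }
    expect_equal(sum(lengths(h$members)), tree$graph$n)
    # forks sit within one arc of the oracle junction; parents agree
    for (b in h$branches$id) {
      tp <- as.character(tips_pkg[b])
      if (is.na(h$branches$fork[b])) {
        expect_true(is.na(oracle$fork[tp]))
      } else {
        fk <- h$branches$fork[b]
        jn <- unname(oracle$fork[tp])
        expect_true(fk == jn || tree$parent[fk] %in% c(jn, NA) ||
                      tree$parent[jn] == fk)
      }
    }
  }
})

test_that("touching strands are counted as loop candidates", {
  # a thin rectangular ring: one arc must close the cycle
  ring <- rbind(cbind(0:10, 0L, 0L), cbind(0:10, 0L, 10L),
                cbind(0L, 0L, 1:9), cbind(10L, 0L, 1:9))
  sh <- voxel_shape(ring, 1)
  g <- build_graph(sh)
  d <- compute_depth(g, manual_seed(sh, 1L))
  h <- decompose(g, d, merge_threshold = 1)
  expect_gte(h$loop_count, 1L)

  # a plain straight tube has none
  gen <- straight_analysis()
  expect_equal(gen$analysis$record$hierarchy$loop_count, 0L)
})
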
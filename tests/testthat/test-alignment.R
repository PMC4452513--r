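test_that("rigid motions compose, invert and validate", {
  m <- axis_rotation(c(1, 2, 3), 25, c(1, -2, 0.5))
  id <- compose_motion(invert_motion(m), m)
  expect_lt(max(abs(id$R - diag(3))), 1e-8)
  expect_lt(max(abs(id$t)), 1e-8)
  expect_equal(motion_angle(m), 25, tolerance = 1e-8)
  expect_error(rigid_motion(matrix(1, 3, 3)), "orthonormal")
  bad <- diag(c(1, 1, -1))  # reflection
  expect_error(rigid_motion(bad), "det")
})

test_that("ICP on already-aligned sets returns the identity quickly", {
  src <- voxel_centers(random_blob(300, 5))
  m <- refine_icp(src, src, rigid_motion(), seed = 1)
  expect_lte(length(attr(m, "rms_trace")), 3L)
  expect_lt(motion_angle(m), 0.5)
  expect_lt(attr(m, "rms"), 0.2)
})

test_that("ICP residual is non-increasing across iterations", {
  gen <- generate_series(small_root_system(), T = 0, edge_length = 0.5)
  src <- voxel_centers(gen$series$shapes[[1]])
  tgt <- apply_motion(axis_rotation(c(0, 1, 0), 2, c(0.4, 0, 0)), src)
  m <- refine_icp(src, tgt, rigid_motion(), seed = 2)
  tr <- attr(m, "rms_trace")
  expect_true(all(diff(tr) <= 1e-9))
  expect_lt(attr(m, "rms"), 0.5)
})

test_that("4PCS + ICP recovers a known motion, also under growth", {
  gen <- cached("small_T2", generate_series(small_root_system(), T = 2,
                                            edge_length = 0.5))
  src <- voxel_centers(gen$series$shapes[[1]])
  m_true <- axis_rotation(c(0.2, -0.4, 1), 30, c(5, 0, 0))
  for (shape_idx in c(1L, 3L)) {   # same shape, and a grown superset
    tgt <- apply_motion(m_true, voxel_centers(gen$series$shapes[[shape_idx]]))
    mc <- coarse_align_4pcs(src, tgt, overlap_fraction = 1, seed = 4,
                            max_rotation = 60)
    m <- refine_icp(src, tgt, mc, seed = 4)
    # residual of the source under the recovered alignment, in edges
    moved <- apply_motion(m, tgt)
    res <- mean(nn_nearest(moved, src)$distance) / 0.5
    expect_lt(res, 1)
  }
})

test_that("degenerate point sets are rejected", {
  line <- cbind(seq_len(20), 0, 0)
  expect_error(coarse_align_4pcs(line, line), "collinear")
  expect_error(coarse_align_4pcs(cbind(1, 1, 1), cbind(1, 1, 1)), "4 points")
})

test_that("a trivial series aligns to identity and composition holds", {
  sh <- chain_shape(12, edge = 0.5)
  al <- align_series(time_series(list(sh)), pipeline_config(0.5))
  expect_length(al$motions, 1L)
  expect_lt(max(abs(al$motions[[1]]$R - diag(3))), 1e-12)

  gen <- cached("small_T2", generate_series(small_root_system(), T = 2,
                                            edge_length = 0.5))
  al2 <- align_series(gen$series, fixture_config(seed = 5))
  for (s in 0:2) {
    mss <- motion_between(al2, s, s)
    expect_lt(max(abs(mss$R - diag(3))), 1e-8)
    expect_lt(max(abs(mss$t)), 1e-8)
  }
})

test_that("alignment quality is ~0 for nested unmoved series and flags outliers", {
  gen <- cached("small_T2", generate_series(small_root_system(), T = 2,
                                            edge_length = 0.5))
  al <- align_series(gen$series, fixture_config(seed = 6))
  q <- alignment_quality(al, seed = 1)
  expect_true(all(q$avg_distance_edges < 1e-9))
  expect_false(any(q$excluded))

  # a shape shifted by 20 edges with the identity motion must be flagged
  sh2 <- gen$series$shapes
  sh2[[2]]$voxels <- sh2[[2]]$voxels + matrix(rep(c(20L, 0L, 0L),
                                                 each = nrow(sh2[[2]]$voxels)),
                                              ncol = 3L)
  fake <- structure(list(series = time_series(sh2),
                         motions = replicate(3, rigid_motion(),
                                             simplify = FALSE),
                         quality = rep(NA_real_, 3),
                         excluded = rep(FALSE, 3), errors = vector("list", 3),
                         edge_length = 0.5),
                    class = "aligned_series")
  q2 <- alignment_quality(fake, seed = 1)
  expect_true(q2$excluded[1])
})

test_that("motion recovery succeeds across seeded perturbation trials", {
  ok <- vapply(1:6, function(s) {
    gen <- generate_series(small_root_system(), T = 1, edge_length = 0.5,
                           perturb = TRUE, max_angle = 40,
                           max_shift_edges = 18, seed = s)
    al <- align_series(gen$series, fixture_config(seed = 300 + s))
    max(al$quality, na.rm = TRUE) < 1
  }, logical(1L))
  expect_true(all(ok))
})
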
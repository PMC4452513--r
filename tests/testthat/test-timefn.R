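test_that("a single-shape series has time zero everywhere", {
  gen <- straight_analysis()
  rec <- gen$analysis$record
  expect_true(all(rec$tau == 0L))
  expect_equal(rec$switch_events, 0L)
})

test_that("nested growth of one branch splits time at the observed depth", {
  # V_0 = top half of a straight branch, V_1 = the whole branch
  mk <- function(len, t) {
    v <- rhizotrack:::.stamp_tube(
      list(pts = rbind(c(0, 0, 0), c(0, 0, -len)), cum = c(0, len)),
      len, 1, 0.5)
    voxel_shape(v, 0.5, t)
  }
  series <- time_series(list(mk(20, 0L), mk(42, 1L)))
  a <- analyze_series(series, fixture_config(seed = 21))
  rec <- a$record
  z <- rec$shape$voxels[, 3L] * 0.5
  expect_true(all(rec$tau[z > -19] == 0L))
  expect_true(all(rec$tau[z < -24] == 1L))
})

test_that("sublevel sets of the time field reproduce the observed shapes", {
  gen <- cached("small_T2", generate_series(small_root_system(), T = 2,
                                            edge_length = 0.5))
  a <- cached("small_T2_analysis",
              analyze_series(gen$series, fixture_config(seed = 22)))
  rec <- a$record
  for (t in 0:1) {
    sub <- rec$shape$voxels[rec$tau <= t, , drop = FALSE]
    expect_gte(jaccard_voxels(sub, gen$series$shapes[[t + 1]]$voxels), 0.95)
  }
  # branches present only in the last shape keep time T
  expect_true(any(rec$tau == 2L))
})

test_that("consistent growth needs no switch; out-growth needs exactly one", {
  a0 <- cached("small_T2_analysis",
               analyze_series(cached("small_T2",
                                     generate_series(small_root_system(),
                                                     T = 2,
                                                     edge_length = 0.5))$series,
                              fixture_config(seed = 22)))
  expect_equal(a0$record$switch_events, 0L)

  # a side branch that appears short and then out-grows its parent: the
  # depth hierarchy of the final shape picks the wrong through-branch
  specs <- list(
    branch_spec("a", rbind(c(0, 0, 0), c(0, 0, -40)), 1.2, 0L, c(30, 32, 34)),
    branch_spec("c", rbind(c(0, 0, 0), c(12, 3, -12), c(24, 5, -26),
                           c(34, 6, -42)),
                1.0, 1L, c(5, 45), parent = "a", attach_s = 8))
  gen <- cached("outgrow_gen",
                generate_series(specs, T = 2, edge_length = 0.5))
  a <- cached("outgrow_analysis",
              analyze_series(gen$series, fixture_config(seed = 23)))
  rec <- a$record
  expect_equal(rec$switch_events, 1L)
  # after repair the through-going (root) branch is the older primary
  root <- rec$hierarchy$root_branch
  root_tip_depth <- rec$depth$depth[rec$hierarchy$branches$tip[root]]
  expect_lt(root_tip_depth, max(rec$depth$depth))
  # and the repaired record shows no remaining depth/time conflict
  expect_length(rhizotrack:::.find_conflicts(rec), 0L)
})

test_that("switch repair only lowers times and keeps the hierarchy a tree", {
  gen <- cached("outgrow_gen", {
    specs <- list(
      branch_spec("a", rbind(c(0, 0, 0), c(0, 0, -40)), 1.2, 0L,
                  c(30, 32, 34)),
      branch_spec("c", rbind(c(0, 0, 0), c(12, 3, -12), c(24, 5, -26),
                             c(34, 6, -42)),
                  1.0, 1L, c(5, 45), parent = "a", attach_s = 8))
    generate_series(specs, T = 2, edge_length = 0.5)
  })
  series <- gen$series
  cfg <- fixture_config(seed = 23)
  # re-run the pipeline up to the unrepaired record
  shapes <- lapply(series$shapes, function(s)
    largest_component(build_graph(s))$shape)
  series <- time_series(shapes)
  graphs <- lapply(series$shapes, build_graph)
  al <- align_series(series, cfg)
  seed_T <- detect_seed(series$shapes[[3]], R = 4)
  d <- compute_depth(graphs[[3]], seed_T)
  h <- decompose(graphs[[3]], d)
  seeds <- propagate_seed(seed_T, al)
  per_t <- lapply(1:2, function(i)
    decompose(graphs[[i]], compute_depth(graphs[[i]], seeds[[i]])))
  tf <- compute_time(al, h, d, per_t)
  rec0 <- growth_record(graphs[[3]], d, h, tf, 2L)
  rec1 <- repair_switches(rec0)
  expect_true(all(rec1$tau <= rec0$tau))
  # parent links still form a tree: walking up always reaches the root
  br <- rec1$hierarchy$branches
  for (b in br$id) {
    seen <- integer(0); cur <- b
    while (!is.na(br$parent[cur])) {
      expect_false(cur %in% seen)
      seen <- c(seen, cur)
      cur <- br$parent[cur]
    }
    expect_equal(cur, rec1$hierarchy$root_branch)
  }
})
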
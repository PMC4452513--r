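test_that("a straight vertical branch has unit tortuosity and zero angles", {
  a <- straight_analysis()$analysis
  tt <- a$traits
  expect_equal(nrow(tt), 1L)
  expect_equal(tt$tortuosity, 1, tolerance = 0.05)
  expect_equal(tt$angle_to_parent, 0)
  expect_lt(tt$angle_to_gravity, 2)
  expect_equal(tt$n_children, 0L)
  expect_lte(tt$length, tt$depth_of_tip)
  # swept radius recovered from volume and length
  expect_equal(tt$average_radius, 1.5, tolerance = 0.1)
  expect_equal(tt$volume, n_voxels(a$record$shape))
})

test_that("an inclined straight branch reports its angle to gravity", {
  for (theta in c(20, 45, 60)) {
    dirvec <- c(sin(theta * pi / 180), 0, -cos(theta * pi / 180))
    specs <- list(branch_spec("s", rbind(c(0, 0, 0), 60 * dirvec),
                              radius = 1.2, appear = 0L, schedule = 55))
    gen <- generate_series(specs, T = 0, edge_length = 0.5)
    a <- analyze_series(gen$series, fixture_config(seed = 31))
    expect_equal(a$traits$angle_to_gravity[1], theta, tolerance = 5)
  }
})

test_that("children are counted and switch events follow relative length", {
  a <- cached("small_T2_analysis",
              analyze_series(cached("small_T2",
                                    generate_series(small_root_system(),
                                                    T = 2,
                                                    edge_length = 0.5))$series,
                             fixture_config(seed = 22)))
  tt <- a$traits
  h <- a$record$hierarchy
  root <- h$root_branch
  tt2 <- tt[tt$t == 2, ]
  expect_gte(tt2$n_children[tt2$branch_id == root], 1L)
  # laterals are shorter than the primary throughout: no switch events
  expect_false(any(tt$switch_event))
})

test_that("per-branch volume and length grow monotonically in time", {
  a <- fig3_analysis()
  tt <- a$traits
  for (b in unique(tt$branch_id)) {
    sel <- tt[tt$branch_id == b, ]
    sel <- sel[order(sel$t), ]
    expect_true(all(diff(sel$volume) >= 0))
    expect_true(all(diff(sel$length) >= -1e-9))
  }
  # growth increments of volume are non-negative (nested series)
  expect_true(all(a$increments$volume_growth >= 0))
})

test_that("aggregates sum the per-branch traits", {
  a <- straight_analysis()$analysis
  ag <- aggregate_traits(a$record, 0, a$traits)
  expect_equal(ag$total_volume, a$traits$volume[1])
  expect_equal(ag$total_length, a$traits$length[1])

  a3 <- fig3_analysis()
  ag2 <- aggregate_traits(a3$record, 2, a3$traits)
  expect_equal(ag2$total_length, sum(a3$traits$length[a3$traits$t == 2]))
  # volume partition at T is exact
  expect_equal(ag2$total_volume, n_voxels(a3$record$shape))
})

test_that("seed traits report volume, orientation, and degeneracy", {
  ball <- voxel_shape(voxel_ball(c(0, 0, 0), 4, 0.5), 0.5)
  sa <- structure(list(voxels = ball$voxels, indices = seq_len(n_voxels(ball)),
                       detection_mode = "manual"), class = "seed_area")
  st <- seed_traits(sa, ball)
  expect_true(st$degenerate)
  expect_equal(st$seed_orientation, 0)
  expect_equal(st$volume_fraction, 1.0)

  # a prolate ellipsoid aligned with z points its major axis up
  g <- as.matrix(expand.grid(-3:3, -3:3, -9:9))
  ell <- g[(g[, 1]^2 / 9 + g[, 2]^2 / 9 + g[, 3]^2 / 81) <= 1, ]
  esh <- voxel_shape(ell, 0.5)
  esa <- structure(list(voxels = esh$voxels,
                        indices = seq_len(n_voxels(esh)),
                        detection_mode = "manual"), class = "seed_area")
  est <- seed_traits(esa, esh)
  expect_false(est$degenerate)
  expect_lt(est$seed_orientation, 3)
})

test_that("branches are classified by fork position relative to the seed", {
  a <- fig3_analysis()
  cls <- a$classes
  expect_true(attr(cls, "provisional"))
  root <- a$record$hierarchy$root_branch
  expect_equal(cls$class[cls$branch_id == root], "primary")
  expect_true(all(cls$class %in% c("primary", "seminal", "crown", "lateral")))

  # forcing the seed area around a fork reclassifies the child as seminal,
  # and a seed far below everything makes forks lie above it (crown)
  rec <- a$record
  h <- rec$hierarchy
  child <- h$branches$id[!is.na(h$branches$fork)][1]
  fk <- h$branches$fork[child]
  near <- which(rowSums(sweep(rec$shape$voxels, 2L,
                              rec$shape$voxels[fk, ])^2) <= 9)
  sa <- structure(list(voxels = rec$shape$voxels[near, , drop = FALSE],
                       indices = near, detection_mode = "manual"),
                  class = "seed_area")
  cls2 <- classify_branches(rec, sa)
  expect_equal(cls2$class[cls2$branch_id == child], "seminal")

  deep <- which.min(rec$shape$voxels[, 3L])
  sa3 <- structure(list(voxels = rec$shape$voxels[deep, , drop = FALSE],
                        indices = deep, detection_mode = "manual"),
                   class = "seed_area")
  cls3 <- classify_branches(rec, sa3)
  expect_true(all(cls3$class[cls3$branch_id != root] == "crown"))
})
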
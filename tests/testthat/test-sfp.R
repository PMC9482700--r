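test_that("frame traces are exactly the matrix rows", {
  tr <- frame_trace(orientation_set(diag(3)))
  expect_equal(tr$x[1, ], c(1, 0, 0))
  expect_equal(tr$y[1, ], c(0, 1, 0))
  expect_equal(tr$z[1, ], c(0, 0, 1))

  ms <- random_orientations(10, seed = 4)
  tr <- frame_trace(orientation_set(ms))
  for (i in 1:10) {
    expect_equal(tr$x[i, ], ms[[i]][1, ], tolerance = 1e-12)
    expect_equal(tr$z[i, ], ms[[i]][3, ], tolerance = 1e-12)
  }
})

test_that("a pure 1-DoF rotation leaves its own axis fixed and sweeps 2*theta arcs", {
  for (theta in c(10, 30, 60, 90)) {
    rom <- generate_rom(rom_spec("one_dof", theta, axes = "X",
                                 step = theta / 10))
    tr <- frame_trace(rom)
    expect_equal(sfproj:::arc_diameter(tr$x), 0, tolerance = 1e-9)
    expect_equal(sfproj:::arc_diameter(tr$y), 2 * theta, tolerance = 1e-9)
    expect_equal(sfproj:::arc_diameter(tr$z), 2 * theta, tolerance = 1e-9)
  }
})

test_that("boundary fitting handles degenerate and dense clouds", {
  # all points identical: a single patch's perimeter (a point falling
  # on a grid vertex or edge occupies the incident patches instead)
  pt <- c(0.3, 0.5, 0.8) / sqrt(sum(c(0.3, 0.5, 0.8)^2))
  p <- fit_boundary(matrix(pt, 1), subdivisions = 2)
  expect_s3_class(p, "sphere_polygon")
  expect_true(contains(p, pt))
  expect_equal(length(attr(p, "occupied")), 1L)
  expect_equal(nrow(p$vertices), 3L)

  # uniform octant cloud: solid angle within 5% of pi/2 at fine grid
  set.seed(9)
  pts <- matrix(abs(rnorm(3 * 20000)), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2))
  poly <- fit_boundary(pts, subdivisions = 4)
  expect_lt(abs(polygon_area(poly) - pi / 2) / (pi / 2), 0.05)

  # whole-sphere cloud has no perimeter
  set.seed(10)
  full <- matrix(rnorm(3 * 5000), ncol = 3)
  full <- full / sqrt(rowSums(full^2))
  expect_error(fit_boundary(full, subdivisions = 1), "no boundary")
})

test_that("2-DoF ranges appear as rectangle sides through the null pose", {
  rom <- generate_rom(rom_spec("two_dof", c(30, 15), axes = c("X", "Y"),
                               step = 2.5))
  ang <- attr(rom, "angles")
  expect_equal(max(ang[, 1]) - min(ang[, 1]), 60)
  expect_equal(max(ang[, 2]) - min(ang[, 2]), 30)

  fit <- sfp(rom)
  pw <- grid_patch_width(fit$grid)
  # the Z polygon spans the X range along one great circle through the
  # null pose and the Y range along the other
  sx <- polygon_section(fit$polygons$z, c(0, 0, 1), c(0, 1, 0))
  sy <- polygon_section(fit$polygons$z, c(0, 0, 1), c(1, 0, 0))
  expect_lt(abs(sx$extent - 60), pw)
  expect_lt(abs(sy$extent - 30), pw)
})

test_that("an SFP always carries three polygons that contain their clouds", {
  rom <- generate_rom(rom_spec("two_dof", c(30, 15), axes = c("X", "Y"),
                               step = 5))
  for (subdiv in 2:3) {
    fit <- sfp(rom, subdivisions = subdiv)
    expect_named(fit$polygons, c("x", "y", "z"))
    expect_length(fit$polygons, 3L)
    pr <- predict(fit)
    expect_true(all(pr$all_inside))
  }

  # 1-DoF: rotation axis polygon degenerates to a few patches, the
  # others are elongated strips
  rom1 <- generate_rom(rom_spec("one_dof", 30, axes = "X", step = 1))
  fit1 <- sfp(rom1)
  expect_length(fit1$polygons, 3L)
  expect_lt(polygon_area(fit1$polygons$x), 0.1)
  expect_gt(polygon_area(fit1$polygons$y), polygon_area(fit1$polygons$x))
  expect_true(all(predict(fit1)$all_inside))

  expect_error(orientation_set(list()), "at least one")
})

test_that("traces and fitted polygons rotate rigidly with a global rotation", {
  rom <- generate_rom(rom_spec("two_dof", c(30, 15), axes = c("X", "Y"),
                               step = 5))
  g <- axis_angle_matrix(c(1, 2, -1), 37)
  rot <- rotate_set(rom, g)
  tr0 <- frame_trace(rom)
  tr1 <- frame_trace(rot)
  for (ax in c("x", "y", "z")) {
    expect_equal(tr1[[ax]], tr0[[ax]] %*% t(g), tolerance = 1e-9)
  }
})

test_that("polygon area grows monotonically with nested samples", {
  rom <- generate_rom(rom_spec("two_dof", c(30, 15), axes = c("X", "Y"),
                               step = 2.5))
  grid <- sphere_grid(3)
  one_patch <- max(grid$solid_angles)
  cloud <- frame_trace(rom)$z
  full <- fit_boundary(cloud, grid = grid)
  for (by in c(2, 4)) {
    idx <- seq(1, length(rom), by = by)
    sub <- fit_boundary(frame_trace(rom[idx])$z, grid = grid)
    expect_lte(polygon_area(sub), polygon_area(full) + one_patch)
  }
  # the raw patch occupancy itself is pointwise monotone at any
  # subsampling (pinch/hole resolution of very sparse subsets can add
  # bridging patches on top of this)
  occ_full <- sfproj:::locate_patch_all(grid, cloud)
  for (by in 2:5) {
    occ_sub <- sfproj:::locate_patch_all(
      grid, frame_trace(rom[seq(1, length(rom), by = by)])$z)
    expect_true(all(occ_sub %in% occ_full))
  }
})

test_that("pose membership agrees with the patch-occupancy oracle off edges", {
  rom <- generate_rom(rom_spec("two_dof", c(30, 15), axes = c("X", "Y"),
                               step = 2.5))
  fit <- sfp(rom)
  poly <- fit$polygons$z
  occ <- attr(poly, "occupied")
  set.seed(14)
  q <- matrix(rnorm(1500), ncol = 3)
  q <- q / sqrt(rowSums(q^2))
  oracle <- locate_patch(fit$grid, q) %in% occ
  ours <- contains_points(poly, q)
  expect_identical(ours, oracle)
})

test_that("membership in the polygons is necessary but not sufficient", {
  rom <- generate_rom(rom_spec("one_dof", 30, axes = "X", step = 1))
  fit <- sfp(rom)

  # source poses pass, far-out-of-range poses fail on some axis
  expect_true(check_pose(fit, rom[[5]])$all_inside)
  outside <- from_euler(90 + 30, "X")
  expect_false(check_pose(fit, outside)$all_inside)

  # the false-positive construction: an annular 2-DoF dataset leaves a
  # hole under the Z cloud; the outer boundary covers the hole, so the
  # null pose - whose axis endpoints are all visited, but by different
  # poses - passes the membership test while being 15 degrees from any
  # sampled pose.  The path check flags it as unreachable.
  ang <- as.matrix(expand.grid(seq(-30, 30, 2.5), seq(-30, 30, 2.5)))
  h <- sqrt(rowSums(ang^2))
  ang <- ang[h >= 15 & h <= 30, ]
  ann <- orientation_set(lapply(seq_len(nrow(ang)), function(i)
    unclass(from_euler(ang[i, ], "XY"))), label = "annular")
  fit_ann <- suppressWarnings(sfp(ann))
  cp <- check_pose(fit_ann, orientation(diag(3)))
  expect_true(cp$all_inside)
  res <- check_pose_path(ann, ann[[1]], orientation(diag(3)),
                         step_max = 10)
  expect_false(res$viable)
})

test_that("path viability tracks connectivity of the sampled poses", {
  rom <- generate_rom(rom_spec("one_dof", 30, axes = "X", step = 1))

  # trivial: target equals start
  res0 <- check_pose_path(rom, rom[[1]], rom[[1]], step_max = 5)
  expect_true(res0$viable)
  expect_length(res0$path, 1L)

  # dense 1-DoF range: all in-range targets reachable with monotone
  # steps, out-of-range targets are not
  res <- check_pose_path(rom, from_euler(0, "X"), from_euler(25, "X"),
                         step_max = 5)
  expect_true(res$viable)
  expect_true(all(res$distances <= 5 + 1e-9))
  expect_false(check_pose_path(rom, from_euler(0, "X"),
                               from_euler(45, "X"), step_max = 5)$viable)

  # two clusters 60 degrees apart cannot be bridged at 5-degree steps
  m1 <- lapply(seq(-5, 5, 1), function(a) unclass(from_euler(a, "X")))
  m2 <- lapply(seq(55, 65, 1), function(a) unclass(from_euler(a, "X")))
  dis <- orientation_set(c(m1, m2))
  expect_false(check_pose_path(dis, from_euler(0, "X"),
                               from_euler(60, "X"), step_max = 5)$viable)
  # ... but within a cluster the path works
  expect_true(check_pose_path(dis, from_euler(60, "X"),
                              from_euler(56, "X"), step_max = 5)$viable)

  expect_error(check_pose_path(dis, from_euler(30, "X"),
                               from_euler(0, "X"), step_max = 5),
               "not anchored")
})

test_that("coverage passes saturate at three and re-entries count", {
  g <- sphere_grid(2)
  cov <- coverage_grid(grid = g)
  cen <- g$centroids[1, ]
  nb <- g$centroids[g$edge_adjacency[[1]][1], ]

  # empty stream: unchanged
  cov0 <- coverage_update(cov, matrix(numeric(0), 0, 3))
  expect_identical(cov0$counts, cov$counts)

  # one dwell = one pass, regardless of samples spent inside
  cov1 <- coverage_update(cov, rbind(cen, cen, cen))
  expect_equal(cov1$counts[1], 1L)
  expect_equal(coverage_intensity(cov1)[1], 1 / 3)

  # leave and re-enter: new pass; three passes saturate
  cov2 <- coverage_update(cov, rbind(cen, nb, cen, nb, cen))
  expect_equal(cov2$counts[1], 3L)
  expect_equal(coverage_intensity(cov2)[1], 1)
  expect_lt(coverage_intensity(coverage_update(cov,
    rbind(cen, nb, cen)))[1], 1)

  # a dwell split across calls still counts once
  cov3 <- coverage_update(cov, rbind(cen, cen))
  cov3 <- coverage_update(cov3, rbind(cen, cen))
  expect_equal(cov3$counts[1], 1L)
})

test_that("summary and plot methods run on a fitted SFP", {
  rom <- generate_rom(rom_spec("two_dof", c(30, 15), axes = c("X", "Y"),
                               step = 5))
  fit <- sfp(rom)
  s <- summary(fit)
  expect_s3_class(s, "summary.sfp")
  expect_equal(nrow(s$table), 3L)
  expect_output(print(fit), "Spherical frame projection")

  png_path <- tempfile(fileext = ".png")
  render_sfp(fit, png_path)
  expect_true(file.exists(png_path))
  expect_gt(file.size(png_path), 5000)
})
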
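test_that("RoM grids have the expected size and Euler-box extents", {
  rom <- generate_rom(rom_spec("one_dof", 30, axes = "X", step = 1))
  expect_length(rom, 61L)    # 2 * 30 + 1 grid points

  rom2 <- generate_rom(rom_spec("two_dof", c(30, 15), axes = c("X", "Y"),
                                step = 5))
  ang <- attr(rom2, "angles")
  expect_equal(range(ang[, 1]), c(-30, 30))
  expect_equal(range(ang[, 2]), c(-15, 15))
  expect_length(rom2, 13L * 7L)

  expect_error(rom_spec("one_dof", 30, axes = "X", step = 0),
               "step")
  expect_error(rom_spec("two_dof", c(30, 15), axes = c("X", "X")),
               "consecutive")
})

test_that("random sampling is seed-deterministic", {
  s <- rom_spec("three_dof_box", c(30, 20, 15), n = 100, seed = 5)
  a <- generate_rom(s)
  b <- generate_rom(s)
  expect_identical(a$rotations, b$rotations)
  d <- generate_rom(rom_spec("three_dof_box", c(30, 20, 15), n = 100,
                             seed = 6))
  expect_false(identical(a$rotations, d$rotations))
})

# tangent of the Z-rotation sweep at an X-axis endpoint p: direction of
# d/db [p under growing Z-rotation], i.e. z x p
sweep_tangent_z <- function(p) c(-p[2], p[1], 0)

test_that("coupled limits open up away from the null pose", {
  tab <- data.frame(angle = c(-40, 0, 40), half_range = c(40, 5, 40))
  sp <- rom_spec("coupled", c(40, 40), axes = c("Y", "Z"), step = 2.5,
                 coupling = list(driver = "Y", limited = "Z",
                                 table = tab))
  rom <- generate_rom(sp)
  ang <- attr(rom, "angles")
  z_at_null <- max(abs(ang[ang[, "Y"] == 0, "Z"]))
  z_at_max <- max(abs(ang[ang[, "Y"] == 40, "Z"]))
  expect_lt(z_at_null, z_at_max)
  expect_equal(z_at_null, 5)
  expect_equal(z_at_max, 40)

  # the SFP signature: the Y polygon is wider (along the rotation
  # about Z) far from the null pose than at it
  fit <- sfp(rom)
  # width of the allowed Z-rotation at the null pose vs after 40 deg
  # about Y, measured on the X polygon along the Z-rotation direction
  at_null <- polygon_section(fit$polygons$x, c(1, 0, 0), c(0, 1, 0))
  far_ctr <- unclass(from_euler(c(40, 0), "YZ"))[1, ]
  at_far <- polygon_section(fit$polygons$x, far_ctr,
                            sweep_tangent_z(far_ctr))
  expect_lt(at_null$extent, at_far$extent)

  expect_error(rom_spec("coupled", c(40, 40), axes = c("Y", "Z")),
               "coupling")
})

test_that("session simulation inverts exactly at zero noise", {
  spec <- rom_spec("three_dof_box", c(30, 20, 15), axes = c("Z", "Y", "X"),
                   n = 60, seed = 2)
  sess <- simulate_session(spec, noise_sd = 0)
  f <- tempfile(fileext = ".tsv")
  write_session_tsv(sess, f)
  poses <- read_mocap(f, sess$geom$marker_tree)
  expect_length(poses$markers_T_base, 60L)
  err <- vapply(seq_len(60), function(i) {
    o <- joint_orientation(poses$markers_T_base[[i]], sess$pACS_T_pPlate,
                           sess$geom$pPlate_T_base, sess$dACS_T_dPlate,
                           sess$geom$dPlate_T_markers)
    max(abs(unclass(o) - unclass(sess$truth[[i]])))
  }, numeric(1))
  expect_lt(max(err), 1e-9)
})

test_that("recovery error grows monotonically with marker noise", {
  spec <- rom_spec("three_dof_box", c(30, 20, 15), axes = c("Z", "Y", "X"),
                   n = 100, seed = 4)
  med_err <- vapply(c(0, 0.1, 0.5, 1), function(sd) {
    sess <- simulate_session(spec, noise_sd = sd, seed = 99)
    f <- tempfile(fileext = ".tsv")
    on.exit(unlink(f), add = TRUE)
    write_session_tsv(sess, f)
    poses <- read_mocap(f, sess$geom$marker_tree)
    stats::median(vapply(seq_along(poses$markers_T_base), function(i) {
      o <- joint_orientation(poses$markers_T_base[[i]],
                             sess$pACS_T_pPlate, sess$geom$pPlate_T_base,
                             sess$dACS_T_dPlate,
                             sess$geom$dPlate_T_markers)
      rotation_distance(o, sess$truth[[i]])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_err) > 0))
  expect_lt(med_err[2], 1)      # 0.1 mm noise: sub-degree median error
})

test_that("soft-limit spring torque follows the piecewise power law", {
  spec <- rom_spec("one_dof", 35, axes = "X", step = 5)
  sess <- simulate_session(spec, noise_sd = 0)
  ang <- attr(sess$truth, "angles")[, 1]
  # zero inside the soft region, including exactly at onset
  expect_true(all(sess$torque[abs(ang) <= 25, "x"] == 0))
  # 10 degrees beyond onset: stiffness * 10^exponent
  expect_equal(unname(sess$torque[ang == 35, "x"]), 0.5 * 10^3)
  expect_equal(unname(sess$torque[ang == -35, "x"]), -0.5 * 10^3)
})

test_that("torque classification matches the feedback thresholds", {
  tau <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 30, 0), c(0, 0, 50),
               c(40, 30, 0))
  cls <- classify_torque(tau, threshold = 5, upper = 50)
  expect_equal(as.character(cls$category),
               c("below", "feedback", "feedback", "above_limit",
                 "above_limit"))
  expect_equal(cls$pitch_fraction[1], 0)
  expect_equal(cls$pitch_fraction[2], 0)    # exactly at threshold
  expect_equal(cls$pitch_fraction[4], 1)
  expect_equal(cls$pitch_fraction[3], (30 - 5) / 45)
  expect_error(classify_torque(tau, threshold = 50, upper = 5), "below")
})

test_that("marker trees and geometry are validated", {
  expect_error(rig_geometry(marker_tree = rbind(c(0, 0, 0), c(1, 0, 0),
                                                c(0, 1, 0), c(1, 1, 0))),
               "coplanar")
  expect_error(rig_geometry(threshold = 60, upper = 50), "threshold")
})
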
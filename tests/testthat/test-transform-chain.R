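test_that("rigid inverse is exact and involutive", {
  expect_equal(unclass(invert_transform(rigid_transform())), diag(4))

  # zero translation: the plain transpose IS the inverse
  r <- t(unclass(from_euler(c(20, -35, 10))))
  tp <- rigid_transform(r, c(0, 0, 0))
  expect_equal(unclass(invert_transform(tp)), t(unclass(tp)),
               tolerance = 1e-12)

  for (seed in 1:20) {
    tr <- random_transform(seed)
    expect_equal(unclass(compose_transforms(tr, invert_transform(tr))),
                 diag(4), tolerance = 1e-12)
    expect_equal(unclass(invert_transform(invert_transform(tr))),
                 unclass(tr), tolerance = 1e-12)
  }

  bad <- diag(4); bad[4, 1] <- 0.1
  expect_error(rigid_transform(bad), "bottom row")
})

test_that("joint orientation extracts the chain's rotational component", {
  id <- rigid_transform()
  expect_equal(unclass(joint_orientation(id, id, id, id, id)), diag(3))

  # translating any constant transform must not change the orientation
  tb <- random_transform(1); pp <- random_transform(2)
  pb <- random_transform(3); dd <- random_transform(4)
  dm <- random_transform(5)
  o1 <- joint_orientation(tb, pp, pb, dd, dm)
  shift <- function(tr, dt) {
    m <- unclass(tr); m[1:3, 4] <- m[1:3, 4] + dt; rigid_transform(m)
  }
  o2 <- joint_orientation(tb, shift(pp, c(100, -50, 3)), pb,
                          shift(dd, c(-7, 2, 90)), dm)
  expect_equal(unclass(o1), unclass(o2), tolerance = 1e-12)

  bad <- diag(4); bad[1:3, 1:3] <- diag(c(1, 1, 1.01))
  expect_error(joint_orientation(bad, id, id, id, id), "markers_T_base")
})

test_that("full-chain recovery reproduces simulated ground truth", {
  spec <- rom_spec("three_dof_box", c(30, 20, 15), axes = c("Z", "Y", "X"),
                   n = 200, seed = 8)
  sess <- simulate_session(spec, noise_sd = 0)
  markers_T_dACS <- invert_transform(
    compose_transforms(sess$dACS_T_dPlate, sess$geom$dPlate_T_markers))
  pACS_T_base <- compose_transforms(sess$pACS_T_pPlate,
                                    sess$geom$pPlate_T_base)
  err <- vapply(seq_len(length(sess$truth)), function(i) {
    joint <- rigid_transform(unclass(sess$truth[[i]]))
    markers_T_base <- compose_transforms(markers_T_dACS, joint,
                                         pACS_T_base)
    o <- joint_orientation(markers_T_base, sess$pACS_T_pPlate,
                           sess$geom$pPlate_T_base, sess$dACS_T_dPlate,
                           sess$geom$dPlate_T_markers)
    max(abs(unclass(o) - unclass(sess$truth[[i]])))
  }, numeric(1))
  expect_lt(max(err), 1e-9)
})

test_that("cross-product orthogonalisation converges and is gentle", {
  # idempotent on an exact frame
  out <- orthogonalise(diag(3))
  expect_equal(unclass(out), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(attr(out, "iterations"), 0L)

  # 2-degree perturbed frames: residual to 1e-12 and the axes move by
  # the same order as the perturbation (even the drift-optimal polar
  # decomposition moves some axes past 2 degrees on these frames)
  for (seed in 1:100) {
    a <- perturb_frame(diag(3), deg = 2, seed = seed)
    out <- orthogonalise(a)
    expect_lte(max_pairwise_dot(unclass(out)), 1e-12)
    drift <- max(vapply(1:3, function(i)
      arc_length(unclass(out)[i, ], a[i, ] / sqrt(sum(a[i, ]^2))),
      numeric(1)))
    expect_lt(drift, 3)
    expect_gt(det(unclass(out)), 0)
  }

  # monotone residual: stepping the recursion never increases the
  # worst pairwise dot product
  for (seed in c(4, 99, 123)) {
    a <- perturb_frame(diag(3), deg = 2, seed = seed)
    a <- a / sqrt(rowSums(a^2))
    res <- max_pairwise_dot(a)
    for (k in 0:60) {
      a <- sfproj:::ortho_step(a, k %% 3L + 1L)
      nres <- max_pairwise_dot(a)
      expect_lte(nres, res + 1e-15)
      res <- nres
    }
  }

  expect_error(orthogonalise(rbind(c(1, 0, 0), c(0.9, 0.44, 0), c(0, 0, 1))),
               "too far from orthogonal")
  lh <- diag(c(1, 1, -1))
  expect_error(orthogonalise(lh, handedness = "reject"), "left-handed")
  fixed <- orthogonalise(lh, handedness = "correct")
  expect_gt(det(unclass(fixed)), 0)
})

make_plate_landmarks <- function(pose = rigid_transform(), nside = 3,
                                 noise_sd = 0, seed = 1) {
  # 20 x 30 x 12 mm plate block; an nside x nside grid of points is
  # placed deliberately on each of the three faces meeting at the
  # outer corner (20, 30, 12), whose outward normals are +x, +y, +z
  set.seed(seed)
  dims <- c(20, 30, 12)
  pts <- list()
  for (i in 1:3) {
    od <- dims[-i]
    gr <- as.matrix(expand.grid(seq(1, od[1] - 1, length.out = nside),
                                seq(1, od[2] - 1, length.out = nside)))
    face <- matrix(0, nside^2, 3)
    face[, i] <- dims[i]
    face[, -i] <- gr
    pts[[i]] <- face
  }
  lm <- do.call(rbind, pts)
  lm <- lm + rnorm(length(lm), sd = noise_sd)
  lm <- transform_points(pose, lm)
  data.frame(group = rep(c("face_x", "face_y", "face_z"), each = nside^2),
             x = lm[, 1], y = lm[, 2], z = lm[, 3])
}

test_that("plate frames are recovered from face landmarks", {
  fit <- fit_plate_frame(make_plate_landmarks())
  m <- unclass(fit$transform)
  # axes are the world axes, origin at the outer corner (20, 30, 12)
  expect_equal(m[1:3, 1:3], diag(3), tolerance = 1e-9)
  expect_equal(m[1:3, 4], c(20, 30, 12), tolerance = 1e-9)
  expect_lte(fit$axis_dot, 1e-9)

  # the fitted frame moves rigidly with the landmarks
  pose <- random_transform(9)
  fit2 <- fit_plate_frame(make_plate_landmarks(pose = pose))
  expect_equal(unclass(fit2$transform),
               unclass(compose_transforms(pose, fit$transform)),
               tolerance = 1e-9)

  # collinear points cannot define a plane
  bad <- data.frame(group = "face_x",
                    x = c(1, 2, 3), y = c(0, 0, 0), z = c(5, 5, 5))
  expect_error(
    fit_plate_frame(rbind(bad, make_plate_landmarks()[10:27, ])),
    "collinear")
})

test_that("noisy plate landmarks still give sub-degree axes", {
  worst <- 0
  for (seed in 1:100) {
    fit <- fit_plate_frame(make_plate_landmarks(noise_sd = 0.05,
                                                seed = seed))
    r <- unclass(fit$transform)[1:3, 1:3]
    err <- max(vapply(1:3, function(i) arc_length(r[, i], diag(3)[, i]),
                      numeric(1)))
    worst <- max(worst, err)
  }
  expect_lt(worst, 0.5)
})

make_bone_points <- function(pose = rigid_transform(), k = 8) {
  # cylinder along z: proximal edge ring at z = 0, distal at z = 40
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  prox <- cbind(3 * cos(th), 3 * sin(th), 0)
  dist <- cbind(3 * cos(th + 0.2), 3 * sin(th + 0.2), 40)
  list(prox = transform_points(pose, prox),
       dist = transform_points(pose, dist))
}

test_that("bone frames align the long axis with the shaft", {
  # edge rings are circles, so the principal edge direction is in the
  # ring plane; use two straight transverse edges instead
  prox <- cbind(seq(-4, 4, length.out = 7), 0, 0)
  dist <- cbind(seq(-3, 3, length.out = 5), 1, 40)
  fit <- fit_bone_frame(prox, dist)
  m <- unclass(fit$transform)
  long <- m[1:3, 1]
  expect_equal(abs(sum(long * c(0, 1 / sqrt(1601), 40 / sqrt(1601)))), 1,
               tolerance = 1e-6)
  expect_equal(m[1:3, 4], c(0, 0, 0), tolerance = 1e-9)
  expect_lte(fit$axis_dot, 1e-9)

  # two-point edges are interpolated exactly
  fit2 <- fit_bone_frame(rbind(c(0, 0, 0), c(2, 0, 0)),
                         rbind(c(0, 0, 30), c(2, 0, 30)))
  expect_equal(fit2$residuals[["proximal"]], 0, tolerance = 1e-12)
  expect_equal(fit2$residuals[["distal"]], 0, tolerance = 1e-12)

  # frames move rigidly with the points
  pose <- random_transform(17)
  f0 <- fit_bone_frame(prox, dist)
  f1 <- fit_bone_frame(transform_points(pose, prox),
                       transform_points(pose, dist))
  expect_equal(unclass(f1$transform),
               unclass(compose_transforms(pose, f0$transform)),
               tolerance = 1e-9)

  expect_error(fit_bone_frame(prox, prox), "coincide")
})
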
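# Shared fixtures: seeded random orientations and perturbed frames.

random_orientations <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    q <- rnorm(4)
    unclass(from_quaternion(q / sqrt(sum(q^2))))
  })
}

# rotate each row of a frame by `deg` about an independent random axis
perturb_frame <- function(frame = diag(3), deg = 2, seed = 1) {
  set.seed(seed)
  rot_about <- function(v, axis, theta) {
    k <- axis / sqrt(sum(axis^2))
    kxv <- c(k[2] * v[3] - k[3] * v[2],
             k[3] * v[1] - k[1] * v[3],
             k[1] * v[2] - k[2] * v[1])
    v * cos(theta) + kxv * sin(theta) + k * sum(k * v) * (1 - cos(theta))
  }
  t(sapply(1:3, function(i)
    rot_about(frame[i, ], rnorm(3), deg * pi / 180)))
}

axis_angle_matrix <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  w <- cos(th / 2)
  v <- axis * sin(th / 2)
  unclass(from_quaternion(c(w, v)))
}

random_transform <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  rigid_transform(t(unclass(from_quaternion(q / sqrt(sum(q^2))))),
                  rnorm(3, sd = 50))
}

max_pairwise_dot <- function(a) {
  max(abs(c(sum(a[1, ] * a[2, ]), sum(a[1, ] * a[3, ]),
            sum(a[2, ] * a[3, ]))))
}
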
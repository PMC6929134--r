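test_that("semi-axes recover isotropy and affine axis ratios", {
  set.seed(21)
  u <- runit(2000)
  ax <- shape_semi_axes(u, c(0, 0, 1))
  expect_equal(unname(ax["b"] / ax["a"]), 1, tolerance = 0.05)
  expect_equal(unname(ax["a"] / ax["c"]), 1, tolerance = 0.05)

  # prolate cloud with axis ratio 1.25 aligned with the field: eps = 0.25
  # exactly, using an icosahedrally symmetric base cloud whose second
  # moments are isotropic by symmetry
  sp <- build_icosphere(1, subdivisions = 3)$positions
  sp[, 3] <- sp[, 3] * 1.25
  ax2 <- shape_semi_axes(sp, c(0, 0, 1))
  eps2 <- unname(elongation(ax2["a"], ax2["b"], ax2["c"]))
  expect_equal(eps2, 0.25, tolerance = 1e-9)

  # frame invariance: rotating configuration and field together leaves
  # the estimate unchanged to machine precision
  th <- 0.83
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  ax3 <- shape_semi_axes(sp %*% t(R), as.numeric(R %*% c(0, 0, 1)))
  expect_equal(unname(elongation(ax3["a"], ax3["b"], ax3["c"])), eps2,
               tolerance = 1e-9)

  expect_error(shape_semi_axes(matrix(rnorm(9), 3, 3)), "at least 10")
  flat <- cbind(matrix(rnorm(60), 30, 2), 0)
  expect_error(shape_semi_axes(flat), "coplanar")
})

test_that("elongation parameter is the normalized axis ratio", {
  expect_identical(elongation(1, 1, 1), 0)
  expect_equal(elongation(1, 1.25, 1), 0.25)
  expect_identical(elongation(2, 2, 2), 0)  # scale invariance
  expect_error(elongation(0, 1, 0), "degenerate")
})

test_that("cavity volume matches closed forms", {
  # regular icosahedron: V = (5/12) (3 + sqrt(5)) a^3
  ico <- build_icosphere(1, subdivisions = 0)
  a <- mean(ico$rest_length)
  expect_equal(cavity_volume(ico), (5 / 12) * (3 + sqrt(5)) * a^3,
               tolerance = 1e-9)
  # fine mesh converges to the sphere volume
  sph <- build_icosphere(2, subdivisions = 4)
  expect_equal(cavity_volume(sph), (4 / 3) * pi * 8, tolerance = 0.02)
  # orientation repair: scrambling triangle windings changes nothing
  scr <- ico
  set.seed(5)
  flip <- sample(nrow(scr$triangles), 8)
  scr$triangles[flip, ] <- scr$triangles[flip, c(1, 3, 2)]
  expect_equal(cavity_volume(scr), cavity_volume(ico), tolerance = 1e-12)
})

test_that("basic-state cavity approximates the sphere of diameter D - 2h", {
  for (q in c(6, 10)) {
    p <- model_params(q = q, mesh_coarsen = 1.2)
    m <- build_membrane(p)
    v0 <- cavity_volume(m$inner)
    expect_equal(v0, (4 / 3) * pi * ((q - 2) / 2)^3, tolerance = 0.15)
  }
})

test_that("volume defect is negative for area-preserving elongation", {
  expect_identical(volume_defect(10, 10), 0)
  expect_equal(volume_defect(2, 4), -0.5)
  # closed-form oracle: prolate spheroid with the same surface area as a
  # unit sphere has less volume
  spheroid_area <- function(a, c) {
    e <- sqrt(1 - a^2 / c^2)  # prolate, c > a
    2 * pi * a^2 * (1 + c / (a * e) * asin(e))
  }
  c_ax <- 1.3
  f <- function(a) spheroid_area(a, c_ax) - 4 * pi
  a_ax <- uniroot(f, c(0.5, 1))$root
  v_spheroid <- (4 / 3) * pi * a_ax^2 * c_ax
  expect_lt(volume_defect(v_spheroid, 4 * pi / 3), 0)
  # and linear in V at fixed V0
  expect_equal(volume_defect(3, 2) - volume_defect(1, 2), 1)
})

test_that("chain statistics partition the dipole set", {
  mu <- sqrt(5 * 0.3^3)
  # isolated dipoles far apart: all chains of length 1
  far <- list(positions = 10 * diag(3), orientations = runit(3),
              mu = mu, dp = 0.3)
  cs <- chain_stats(far)
  expect_identical(cs$n_chains, 3L)
  expect_true(all(cs$lengths == 1))

  # five collinear head-to-tail contact dipoles: one chain of length 5
  z <- seq(0, by = 0.31, length.out = 5)
  chain <- list(positions = cbind(0, 0, z),
                orientations = matrix(rep(c(0, 0, 1), 5), 5, 3, byrow = TRUE),
                mu = mu, dp = 0.3)
  cs2 <- chain_stats(chain)
  expect_identical(cs2$n_chains, 1L)
  expect_identical(cs2$max_length, 5L)

  # partition property on a random configuration
  set.seed(33)
  rnd <- list(positions = matrix(runif(90, 0, 2), 30, 3),
              orientations = runit(30), mu = mu, dp = 0.3)
  cs3 <- chain_stats(rnd)
  expect_identical(sum(cs3$lengths), 30L)
})

test_that("polar occupancy counts the caps about the field axis", {
  mu <- 1
  # 10 equatorial + 2 polar particles on a unit sphere, far apart in pairs
  th <- seq(0, 2 * pi, length.out = 11)[-11]
  pos <- rbind(cbind(cos(th), sin(th), 0), c(0, 0, 1), c(0, 0, -1))
  d <- list(positions = pos * 5, orientations = runit(12), mu = mu, dp = 0.3)
  cs <- chain_stats(d, field_direction = c(0, 0, 1), center = c(0, 0, 0))
  expect_equal(cs$polar_occupancy, 2 / 12)
})

test_that("observable records assemble all measures of a state", {
  p <- model_params(q = 5, mesh_coarsen = 1.2, phi = 0.06, xi = 3, seed = 2)
  m <- build_membrane(p)
  d <- seed_mnps(m, p)
  st <- system_state(m, d, p, xi = 3)
  rec <- observable_record(st)
  expect_gte(rec$epsilon, -1)
  expect_gt(rec$cavity_volume, 0)
  expect_equal(rec$xi, 3)
  expect_identical(sum(chain_stats(d)$lengths), d$n)
  expect_gt(rec$shell_area, 0)
})
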
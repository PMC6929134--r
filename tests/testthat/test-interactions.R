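# --- helpers -------------------------------------------------------------

# central-difference gradient of a scalar energy functional of positions
numerical_forces <- function(energy_fn, pos, h = 1e-6) {
  g <- pos * 0
  for (i in seq_len(nrow(pos))) for (c in 1:3) {
    pp <- pos; pp[i, c] <- pp[i, c] + h
    ep <- energy_fn(pp)
    pp[i, c] <- pp[i, c] - 2 * h
    em <- energy_fn(pp)
    g[i, c] <- -(ep - em) / (2 * h)
  }
  g
}

noisy_shell <- function(subdiv = 1, sd = 0.03, seed = 42) {
  sh <- build_icosphere(1, subdivisions = subdiv)
  set.seed(seed)
  list(shell = sh,
       pos = sh$positions + matrix(rnorm(length(sh$positions), sd = sd),
                                   ncol = 3))
}

# --- elastic shell kernels ----------------------------------------------

test_that("stretch forces are Hookean and vanish at rest", {
  sh <- build_icosphere(1, subdivisions = 1)
  at_rest <- stretch_forces(sh, k = 500)
  expect_equal(max(abs(at_rest$forces)), 0, tolerance = 1e-10)
  expect_equal(at_rest$energy, 0)

  # single stretched edge: |F| = k * delta on each end, antiparallel
  pos <- rbind(c(0, 0, 0), c(1.1, 0, 0))
  res <- mpsdyn:::.cpp_springs(pos, cbind(1L, 2L), 1, 500)
  expect_equal(res$forces[1, ], c(500 * 0.1, 0, 0))
  expect_equal(res$forces[2, ], -res$forces[1, ])
  expect_error(mpsdyn:::.cpp_springs(rbind(c(0, 0, 0), c(0, 0, 0)),
                                     cbind(1L, 2L), 1, 500),
               "degenerate")
})

test_that("area restoring forces point inward under dilation", {
  sh <- build_icosphere(1, subdivisions = 1)
  expect_equal(max(abs(area_forces(sh, k = 500)$forces)), 0,
               tolerance = 1e-10)
  # dilate: every triangle grows, restoring force points inward
  res <- area_forces(sh, sh$positions * 1.05, k = 500)
  inward <- rowSums(res$forces * sh$positions)
  expect_true(all(inward < 0))
})

test_that("bending energy is zero at the built shape and restores it", {
  sh <- build_icosphere(1, subdivisions = 1)
  expect_equal(bending_forces(sh)$energy, 0)
  ns <- noisy_shell()
  expect_gt(bending_forces(ns$shell, ns$pos)$energy, 0)
})

test_that("every elastic kernel matches its numerical energy gradient", {
  ns <- noisy_shell()
  sh <- ns$shell; pos <- ns$pos
  checks <- list(
    stretch = list(f = function(p) stretch_forces(sh, p, 500)$forces,
                   e = function(p) stretch_forces(sh, p, 500)$energy),
    area = list(f = function(p) area_forces(sh, p, 500)$forces,
                e = function(p) area_forces(sh, p, 500)$energy),
    bend = list(f = function(p) bending_forces(sh, p, 12)$forces,
                e = function(p) bending_forces(sh, p, 12)$energy))
  for (nm in names(checks)) {
    fan <- checks[[nm]]$f(pos)
    fnum <- numerical_forces(checks[[nm]]$e, pos)
    scale <- max(abs(fan))
    expect_lt(max(abs(fan - fnum)) / scale, 1e-5, label = nm)
    # Newton's third law: the total internal force vanishes
    expect_equal(colSums(fan), c(0, 0, 0), tolerance = 1e-9 * scale)
  }
})

test_that("intershell bonds are harmonic with zero net force", {
  p <- model_params(q = 6, mesh_coarsen = 1.2, seed = 3)
  m <- build_membrane(p)
  res <- bond_forces(m)
  expect_equal(max(abs(res$forces)), 0, tolerance = 1e-6)
  # stretch by moving the outer shell radially outward by 10%
  pos <- rbind(m$inner$positions, m$outer$positions * 1.1)
  res2 <- bond_forces(m, pos)
  len <- sqrt(rowSums((m$outer$positions[m$bonds[, 2], ] * 1.1 -
                       m$inner$positions[m$bonds[, 1], ])^2))
  fmag <- sqrt(rowSums(res2$forces^2))
  fmag <- fmag[fmag > 1e-8]
  expect_equal(sort(fmag)[1], p$k_bond * min(abs(len - 1)), tolerance = 1e-6)
  expect_equal(colSums(res2$forces), c(0, 0, 0), tolerance = 1e-8)
})

# --- WCA -----------------------------------------------------------------

test_that("WCA is purely repulsive and cut exactly at 2^(1/6) sigma", {
  sig <- 0.475; eps <- 1
  at_cut <- wca_forces(rbind(c(0, 0, 0), c(2^(1/6) * sig, 0, 0)),
                       c(0.65, 0.3), eps = eps)
  expect_identical(max(abs(at_cut$forces)), 0)
  expect_identical(at_cut$energy, 0)
  beyond <- wca_forces(rbind(c(0, 0, 0), c(1, 0, 0)), c(0.65, 0.3))
  expect_identical(beyond$energy, 0)
  # |F(sigma)| = 24 eps / sigma
  at_sig <- wca_forces(rbind(c(0, 0, 0), c(sig, 0, 0)), c(0.65, 0.3))
  expect_equal(abs(at_sig$forces[1, 1]), 24 * eps / sig, tolerance = 1e-12)
  expect_lt(at_sig$forces[1, 1], 0)  # pushed apart
})

test_that("WCA force equals the numerical gradient of its energy", {
  sig <- 0.3
  efun <- function(p) wca_forces(p, c(0.3, 0.3))$energy
  pos <- rbind(c(0, 0, 0), c(1.05 * sig / sqrt(3) * c(1, 1, 1)))
  fan <- wca_forces(pos, c(0.3, 0.3))$forces
  fnum <- numerical_forces(efun, pos, h = 1e-8)
  expect_lt(max(abs(fan - fnum)) / max(abs(fan)), 1e-5)
})

# --- dipolar -------------------------------------------------------------

test_that("dipolar pair force matches the collinear closed form", {
  pref <- 5 * 0.3^3
  dip <- function(pos, e) list(positions = pos, orientations = e,
                               mu = sqrt(pref), dp = 0.3)
  # head-to-tail: attraction of magnitude 6 pref / r^4
  r <- 0.4
  d <- dip(rbind(c(0, 0, 0), c(0, 0, r)), rbind(c(0, 0, 1), c(0, 0, 1)))
  res <- dipolar_forces_torques(d)
  expect_equal(res$forces[2, 3], -6 * pref / r^4, tolerance = 1e-12)
  expect_equal(res$energy, -2 * pref / r^3, tolerance = 1e-12)
  # side-by-side: repulsion
  d2 <- dip(rbind(c(0, 0, 0), c(r, 0, 0)), rbind(c(0, 0, 1), c(0, 0, 1)))
  res2 <- dipolar_forces_torques(d2)
  expect_gt(res2$forces[2, 1], 0)
  expect_equal(res2$energy, pref / r^3, tolerance = 1e-12)
  # Newton's third law
  expect_equal(res$forces[1, ] + res$forces[2, ], c(0, 0, 0),
               tolerance = 1e-12)
})

test_that("dipolar force and torque match numerical derivatives", {
  set.seed(8)
  n <- 5
  pos <- matrix(rnorm(3 * n, sd = 1), n, 3)
  e <- matrix(rnorm(3 * n), n, 3); e <- e / sqrt(rowSums(e^2))
  pref <- 0.135
  efun <- function(p) mpsdyn:::.cpp_dipolar(p, e, pref)$energy
  res <- mpsdyn:::.cpp_dipolar(pos, e, pref)
  fnum <- numerical_forces(efun, pos)
  expect_lt(max(abs(res$forces - fnum)) / max(abs(res$forces)), 1e-5)
  # torque = -e x dU/de (only the component normal to e is physical)
  h <- 1e-6
  for (i in c(1, 3)) {
    grad_e <- numeric(3)
    for (c in 1:3) {
      ep <- e; ep[i, c] <- ep[i, c] + h
      em <- e; em[i, c] <- em[i, c] - h
      grad_e[c] <- (mpsdyn:::.cpp_dipolar(pos, ep, pref)$energy -
                    mpsdyn:::.cpp_dipolar(pos, em, pref)$energy) / (2 * h)
    }
    tq_num <- -cross3(e[i, ], grad_e)
    expect_equal(res$torques[i, ], tq_num, tolerance = 1e-5)
  }
})

test_that("the repulsion window of field-aligned pairs is 90 +- 35 degrees", {
  # radial force between co-aligned dipoles changes sign at the magic angle
  pref <- 0.135; r <- 1
  radial_force <- function(theta_deg) {
    th <- theta_deg * pi / 180
    rhat <- c(sin(th), 0, cos(th))
    pos <- rbind(c(0, 0, 0), rhat * r)
    e <- rbind(c(0, 0, 1), c(0, 0, 1))
    res <- mpsdyn:::.cpp_dipolar(pos, e, pref)
    sum(res$forces[2, ] * rhat)
  }
  # bisection for the sign change of the radial component
  lo <- 10; hi <- 90
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (radial_force(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(lo, acos(1 / sqrt(3)) * 180 / pi, tolerance = 1e-6)
  # half-width about the perpendicular plane: 90 - 54.7 ~ 35 degrees
  expect_equal(round(90 - lo), 35)
  expect_gt(radial_force(90), 0)   # side-by-side repels
  expect_lt(radial_force(5), 0)    # near head-to-tail attracts
})

test_that("dipolar pair conserves angular momentum about any origin", {
  set.seed(10)
  pos <- rbind(c(0.2, -0.1, 0.3), c(0.9, 0.4, -0.2))
  e <- matrix(rnorm(6), 2, 3); e <- e / sqrt(rowSums(e^2))
  res <- mpsdyn:::.cpp_dipolar(pos, e, 0.5)
  origin <- c(-1, 2, 0.5)
  L_dot <- cross3(pos[1, ] - origin, res$forces[1, ]) +
    cross3(pos[2, ] - origin, res$forces[2, ]) +
    res$torques[1, ] + res$torques[2, ]
  expect_equal(L_dot, c(0, 0, 0), tolerance = 1e-12)
})

test_that("coupling-constant round trip through the pair parameters", {
  for (lam in c(0.5, 5, 12)) {
    p <- model_params(q = 6, lambda = lam)
    pep <- pair_energy_params(p)
    expect_equal(pep$dipole_prefactor / (p$kBT * p$dp^3), lam,
                 tolerance = 1e-12)
    expect_equal(lambda_from_reduced_moment(pep$mu, p$dp, p$kBT), lam,
                 tolerance = 1e-12)
    expect_true(isSymmetric(pep$sigma_matrix))
    expect_true(all(pep$sigma_matrix > 0))
  }
})

# --- Zeeman --------------------------------------------------------------

test_that("Zeeman torque follows mu x H for a uniform field", {
  d <- list(orientations = rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)))
  res <- zeeman_torques(d, xi = 7, field_direction = c(0, 0, 1))
  expect_equal(res$torques[1, ], c(0, 0, 0))            # parallel: zero
  expect_equal(sqrt(sum(res$torques[2, ]^2)), 7)        # perpendicular: xi kBT
  res0 <- zeeman_torques(d, xi = 0)
  expect_identical(max(abs(res0$torques)), 0)
})

# --- total force assembly ------------------------------------------------

test_that("assembled system is near equilibrium at build and momentum-free", {
  p <- model_params(q = 6, mesh_coarsen = 1.2, seed = 4)
  m <- build_membrane(p)
  d <- seed_mnps(m, p)
  st <- system_state(m, d, p)
  tf <- total_forces(st)
  # elastic terms vanish by stress-free construction
  expect_equal(tf$energy[["stretch"]], 0, tolerance = 1e-9)
  expect_equal(tf$energy[["area"]], 0, tolerance = 1e-9)
  expect_equal(tf$energy[["bend"]], 0, tolerance = 1e-9)
  expect_equal(tf$energy[["bond"]], 0, tolerance = 1e-9)
  # uniform field exerts torque only: total force vanishes
  expect_equal(colSums(tf$forces), c(0, 0, 0),
               tolerance = 1e-9 * max(1, max(abs(tf$forces))))
})

test_that("total force is the gradient of the total energy", {
  p <- model_params(q = 5, mesh_coarsen = 1.2, xi = 3, seed = 6, phi = 0.06)
  m <- build_membrane(p)
  d <- seed_mnps(m, p)
  st <- system_state(m, d, p, xi = 3)
  topo <- mpsdyn:::.sim_topology(st)
  tf <- total_forces(st)
  set.seed(31)
  idx <- sample(nrow(st$positions), 10)
  h <- 1e-6
  for (i in idx) for (c in 1:3) {
    pp <- st$positions; pp[i, c] <- pp[i, c] + h
    ep <- sum(mpsdyn:::.cpp_forces(topo, pp, st$orientations)$energy)
    pp[i, c] <- pp[i, c] - 2 * h
    em <- sum(mpsdyn:::.cpp_forces(topo, pp, st$orientations)$energy)
    fnum <- -(ep - em) / (2 * h)
    expect_equal(tf$forces[i, c], fnum, tolerance = 2e-5 * max(1, abs(fnum)))
  }
})

test_that("energy decreases under small gradient-descent steps", {
  ns <- noisy_shell(subdiv = 1, sd = 0.05)
  sh <- ns$shell
  pos <- ns$pos
  etot <- function(p) stretch_forces(sh, p, 500)$energy +
    area_forces(sh, p, 500)$energy + bending_forces(sh, p, 12)$energy
  e_prev <- etot(pos)
  for (it in 1:5) {
    f <- stretch_forces(sh, pos, 500)$forces +
      area_forces(sh, pos, 500)$forces + bending_forces(sh, pos, 12)$forces
    pos <- pos + 1e-5 * f
    e_now <- etot(pos)
    expect_lt(e_now, e_prev)
    e_prev <- e_now
  }
})
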
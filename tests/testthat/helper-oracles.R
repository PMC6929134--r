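# small vector helpers shared by the test files
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# uniform unit vectors
runit <- function(n) {
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u / sqrt(rowSums(u^2))
}

# free-particle / free-dipole system evolved through the compiled
# integrator without any interactions: the cleanest thermostat probe
free_topology <- function(n, xi = 0, wca = 0) {
  list(n_beads = 0L, n_mnp = as.integer(n),
       edges = matrix(integer(0), 0, 2), edge_rest = numeric(0),
       k_stretch = 0,
       triangles = matrix(integer(0), 0, 3), tri_ref = numeric(0),
       k_area = 0,
       dihedrals = matrix(integer(0), 0, 4), phi0 = numeric(0), k_bend = 0,
       bonds = matrix(integer(0), 0, 2), bond_rest = 1, k_bond = 0,
       diam = rep(0.3, n), wca_eps = wca, dip_pref = 0,
       xi_kBT = xi, field_dir = c(0, 0, 1))
}

run_free <- function(n, n_steps, xi = 0, dt = 0.002, inertia = 0.009,
                     zeta_r = 0.03, seed = 1, thermostat = TRUE,
                     sample_interval = 0L) {
  set.seed(seed)
  pos <- matrix(runif(3 * n, -20, 20), n, 3)
  vel <- matrix(rnorm(3 * n), n, 3)
  e <- runit(n)
  w <- matrix(rnorm(3 * n, sd = sqrt(1 / inertia)), n, 3)
  dyn <- list(dt = dt, kBT = 1, mass = 1, inertia = inertia, zeta_t = 1,
              zeta_r = zeta_r, thermostat = thermostat,
              energy_interval = 0L,
              sample_interval = as.integer(sample_interval), max_disp = 1e9)
  mpsdyn:::.cpp_run_langevin(free_topology(n, xi = xi), pos, vel, e, w, dyn,
                             as.integer(n_steps), seed, 0)
}

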
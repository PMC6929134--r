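#' Assemble the full dynamical state of a model polymersome
#'
#' Stacks the membrane beads (inner shell first, then outer) and the
#' nanoparticles into one position array, draws Maxwell-Boltzmann initial
#' velocities and angular velocities at `kBT`, and records the moment
#' orientations and the applied field.
#'
#' @param membrane An `mps_membrane`.
#' @param dipoles An `mps_dipoles` seeded in that membrane.
#' @param params An [model_params()] object (defaults to the membrane's).
#' @param xi Initial field parameter (defaults to 0: basic-state start).
#' @param field_direction Unit vector of the applied field.
#' @param velocity_seed Seed for the initial velocity draw.
#' @return An object of class `mps_state`.
#' @export
system_state <- function(membrane, dipoles, params = membrane$params,
                         xi = 0, field_direction = c(0, 0, 1),
                         velocity_seed = params$seed) {
  p <- validate_params(params)
  n_b <- 2L * membrane$n_beads_per_shell
  n_m <- dipoles$n
  pos <- rbind(membrane$inner$positions, membrane$outer$positions,
               dipoles$positions)
  set.seed(as.integer(velocity_seed))
  sdv <- rep(sqrt(p$kBT / c(p$mass, p$mass_mnp)), c(n_b, n_m))
  vel <- matrix(stats::rnorm((n_b + n_m) * 3), n_b + n_m, 3) * sdv
  angvel <- matrix(stats::rnorm(max(n_m, 1) * 3,
                                sd = sqrt(p$kBT / p$inertia)),
                   max(n_m, 1), 3)[seq_len(n_m), , drop = FALSE]
  orient <- dipoles$orientations

  st <- list(positions = pos, velocities = vel,
             orientations = orient, ang_velocities = angvel,
             n_beads = n_b, n_mnp = n_m,
             membrane = membrane, dipoles = dipoles, params = p,
             xi = xi, field_direction = field_direction / sqrt(sum(field_direction^2)),
             time = 0, rng_counter = 0L, wca_caps = 0)
  class(st) <- "mps_state"
  validate_state(st)
  st
}

validate_state <- function(st) {
  if (any(!is.finite(st$positions)) || any(!is.finite(st$velocities)) ||
      any(!is.finite(st$orientations)) || any(!is.finite(st$ang_velocities)))
    stop("non-finite values in system state", call. = FALSE)
  if (st$n_mnp > 0) {
    nrm <- sqrt(rowSums(st$orientations^2))
    if (any(abs(nrm - 1) > 1e-9))
      stop("moment orientations are not unit vectors", call. = FALSE)
  }
  invisible(st)
}

#' @export
print.mps_state <- function(x, ...) {
  cat(sprintf(
    "Polymersome state: %d shell beads + %d nanoparticles, t = %.4g, xi = %g\n",
    x$n_beads, x$n_mnp, x$time, x$xi))
  invisible(x)
}

# flat topology description handed to the compiled kernels
.sim_topology <- function(state) {
  m <- state$membrane
  p <- state$params
  n <- m$n_beads_per_shell
  edges <- rbind(m$inner$edges, m$outer$edges + n)
  edge_rest <- c(m$inner$rest_length, m$outer$rest_length)
  tris <- rbind(m$inner$triangles, m$outer$triangles + n)
  tri_ref <- c(m$inner$ref_area, m$outer$ref_area)
  dihedrals <- rbind(m$inner$dihedrals, m$outer$dihedrals + n)
  phi0 <- c(m$inner$phi0, m$outer$phi0)
  bonds <- cbind(m$bonds[, 1], m$bonds[, 2] + n)
  diam <- c(rep(p$din, n), rep(p$dout, n), rep(p$dp, state$n_mnp))
  list(n_beads = state$n_beads, n_mnp = state$n_mnp,
       edges = edges, edge_rest = edge_rest, k_stretch = p$k_stretch,
       triangles = tris, tri_ref = tri_ref, k_area = p$k_area,
       dihedrals = dihedrals, phi0 = phi0, k_bend = p$k_bend,
       bonds = bonds, bond_rest = m$bond_rest, k_bond = p$k_bond,
       diam = diam, wca_eps = p$wca_eps,
       dip_pref = p$lambda * p$kBT * p$dp^3,
       xi_kBT = state$xi * p$kBT,
       field_dir = state$field_direction)
}

# positions of one shell within the state layout
shell_positions <- function(state, which = c("outer", "inner")) {
  which <- match.arg(which)
  n <- state$membrane$n_beads_per_shell
  idx <- if (which == "inner") seq_len(n) else n + seq_len(n)
  state$positions[idx, , drop = FALSE]
}

# positions of the nanoparticles within the state layout
mnp_positions <- function(state) {
  state$positions[state$n_beads + seq_len(state$n_mnp), , drop = FALSE]
}
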
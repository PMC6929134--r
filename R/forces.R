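#' Pairwise interaction parameters
#'
#' Bundles the Weeks-Chandler-Andersen (WCA) energy scale, the symmetric
#' matrix of species contact distances `sigma_ij = (d_i + d_j)/2`, and the
#' dipolar prefactor.  In reduced units the dipole pair energy is
#' `pref * [e_i.e_j - 3 (e_i.r^)(e_j.r^)] / r^3` with
#' `pref = lambda * kBT * dp^3`, so that two contact dipoles side by side
#' store `+lambda kBT` and head to tail `-2 lambda kBT`.
#'
#' @param params An [model_params()] object.
#' @return A list with `wca_epsilon`, `sigma_matrix` (3 x 3, species order
#'   inner bead / outer bead / nanoparticle), `dipole_prefactor`, `mu`.
#' @export
pair_energy_params <- function(params) {
  p <- validate_params(params)
  d <- c(inner = p$din, outer = p$dout, mnp = p$dp)
  sig <- outer(d, d, function(a, b) (a + b) / 2)
  list(wca_epsilon = p$wca_eps,
       sigma_matrix = sig,
       dipole_prefactor = p$lambda * p$kBT * p$dp^3,
       mu = reduced_moment(p$lambda, p$dp, p$kBT))
}

#' Elastic forces of one triangulated shell
#'
#' `stretch_forces` sums the harmonic edge-spring forces
#' `-k (l - l0) u^` over the mesh edges; `area_forces` the gradients of the
#' per-triangle energy `(k_area/2) (A - A0)^2 / A0`.
#'
#' @param shell An `mps_shell`.
#' @param positions n x 3 matrix of current bead positions.
#' @param k Spring (or area) constant; defaults match [model_params()].
#' @return List with `forces` (n x 3) and scalar `energy`.
#' @export
stretch_forces <- function(shell, positions = shell$positions, k = 500) {
  .cpp_springs(positions, shell$edges, shell$rest_length, k)
}

#' @rdname stretch_forces
#' @export
area_forces <- function(shell, positions = shell$positions, k = 500) {
  .cpp_area(positions, shell$triangles, shell$ref_area, k)
}

#' @rdname stretch_forces
#' @export
bending_forces <- function(shell, positions = shell$positions, k = 12) {
  .cpp_bending(positions, shell$dihedrals, shell$phi0, k)
}

#' Intershell bond forces
#'
#' Harmonic springs of rest length `h` between the bonded node pairs of the
#' two shells.  `positions` stacks the inner-shell beads first, then the
#' outer-shell beads (the layout used throughout the dynamics).
#'
#' @param membrane An `mps_membrane`.
#' @param positions (2n) x 3 matrix, inner beads then outer beads.
#' @param k Bond spring constant.
#' @return List with `forces` ((2n) x 3) and scalar `energy`.
#' @export
bond_forces <- function(membrane,
                        positions = rbind(membrane$inner$positions,
                                          membrane$outer$positions),
                        k = membrane$params$k_bond) {
  n <- membrane$n_beads_per_shell
  pairs <- cbind(membrane$bonds[, 1], membrane$bonds[, 2] + n)
  .cpp_springs(positions, pairs,
               rep(membrane$bond_rest, nrow(pairs)), k)
}

#' Weeks-Chandler-Andersen repulsion
#'
#' Purely repulsive truncated-shifted Lennard-Jones forces,
#' `U = 4 eps [(sigma/r)^12 - (sigma/r)^6] + eps` for `r < 2^(1/6) sigma`
#' and zero beyond, with `sigma` the mean of the two particle diameters.
#' With `positions_b` given, all cross pairs between the two sets are
#' evaluated; otherwise all pairs within set a.
#'
#' @param positions_a,positions_b Particle position matrices (n x 3).
#' @param diameters_a,diameters_b Per-particle diameters.
#' @param eps Energy scale.
#' @return List with `forces_a`, `forces_b` (cross mode) or `forces`
#'   (self mode), and scalar `energy`.
#' @export
wca_forces <- function(positions_a, diameters_a,
                       positions_b = NULL, diameters_b = NULL, eps = 1) {
  na <- nrow(positions_a)
  diameters_a <- rep_len(diameters_a, na)
  if (is.null(positions_b)) {
    pairs <- which(upper.tri(matrix(0, na, na)), arr.ind = TRUE)
    res <- .cpp_wca(positions_a, diameters_a,
                    cbind(pairs[, 1], pairs[, 2]), eps)
    return(list(forces = res$forces, energy = res$energy,
                wca_caps = res$wca_caps))
  }
  nb <- nrow(positions_b)
  diameters_b <- rep_len(diameters_b, nb)
  pos <- rbind(positions_a, positions_b)
  diam <- c(diameters_a, diameters_b)
  pairs <- as.matrix(expand.grid(seq_len(na), na + seq_len(nb)))
  res <- .cpp_wca(pos, diam, pairs, eps)
  list(forces_a = res$forces[seq_len(na), , drop = FALSE],
       forces_b = res$forces[na + seq_len(nb), , drop = FALSE],
       energy = res$energy, wca_caps = res$wca_caps)
}

#' Dipole-dipole forces and torques
#'
#' All-pairs point-dipole interaction in open space (no cutoff, no periodic
#' images).  The force on particle i is minus the gradient of the pair
#' energy; the torque is `mu e_i x B_i` with `B_i` the dipolar field of all
#' other moments.
#'
#' @param dipoles An `mps_dipoles`, or a list with `positions`,
#'   `orientations`.
#' @param prefactor Dipolar energy prefactor `lambda * kBT * dp^3`; defaults
#'   to `mu^2` of the dipole set (reduced units).
#' @return List with `forces`, `torques` (N x 3) and scalar `energy`.
#' @export
dipolar_forces_torques <- function(dipoles, prefactor = dipoles$mu^2) {
  if (nrow(dipoles$positions) < 2)
    stop("need at least 2 dipoles", call. = FALSE)
  .cpp_dipolar(dipoles$positions, dipoles$orientations, prefactor)
}

#' Zeeman torques of a uniform external field
#'
#' Torque `xi * kBT * (e_i x h^)` per nanoparticle; a uniform field exerts
#' no net force.
#'
#' @param dipoles An `mps_dipoles` (or list with `orientations`).
#' @param xi Langevin field parameter.
#' @param field_direction 3-vector (normalized internally).
#' @param kBT Thermal energy.
#' @return List with `torques` (N x 3) and scalar `energy`.
#' @export
zeeman_torques <- function(dipoles, xi, field_direction = c(0, 0, 1),
                           kBT = 1) {
  .cpp_zeeman(dipoles$orientations, xi * kBT, field_direction)
}

#' Total forces, torques and potential energy of a system state
#'
#' Evaluates every interaction of the model on the current configuration:
#' shell stretching, triangle-area restoring, intershell bonds, WCA
#' repulsion (nanoparticle-nanoparticle and nanoparticle-shell), dipolar
#' pair forces/torques and Zeeman torques.
#'
#' @param state An `mps_state` from [system_state()].
#' @return List with `forces` (all particles x 3), `torques`
#'   (nanoparticles x 3), named `energy` vector per term.
#' @export
total_forces <- function(state) {
  .cpp_forces(.sim_topology(state), state$positions, state$orientations)
}
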
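#' Model parameters for a magnetosensitive polymersome
#'
#' Collects every parameter of the coarse-grained model in reduced units.
#' The intershell spring rest length `h` is the length unit and the thermal
#' energy `kBT` the energy unit, so both default to 1.  The capsule size is
#' given by the nondimensional diameter `q = D/h`; the nanoparticle diameter
#' `dp` and accessible gap `hgap` are fractions of `h`.
#'
#' The shell bead diameters satisfy `hgap = h - (din + dout)/2`; by default
#' `din = dout = h - hgap = 0.65`, which makes the shell beads larger than the
#' nanoparticles so the triangulated walls are steric barriers.  The membrane
#' connectivity `cb` is the fraction of shell nodes tied to the opposite shell
#' by a linear spring of rest length `h`.
#'
#' @param q Dimensionless outer diameter `D/h`; must be >= 4.
#' @param lambda Dipolar coupling constant: contact dipole-dipole energy of
#'   two nanoparticles over `kBT`.
#' @param xi Langevin field parameter: Zeeman energy of one nanoparticle in
#'   the applied field over `kBT`.
#' @param phi Nanoparticle volume fraction of the intershell space, in (0, 0.6).
#' @param cb Connectivity: fraction of shell nodes bonded across the gap,
#'   in (0, 1].
#' @param dp Nanoparticle diameter (units of `h`).
#' @param hgap Gap accessible to the nanoparticles (units of `h`).
#' @param din,dout Inner/outer shell bead diameters (units of `h`).  Their
#'   mean must equal `h - hgap`.
#' @param h Intershell spring rest length; the length unit (1).
#' @param kBT Thermal energy; the energy unit (1).
#' @param zeta_t Translational friction coefficient (reduced).
#' @param zeta_r Rotational friction coefficient; default `zeta_t * dp^2 / 3`.
#' @param mass Shell bead mass (reduced).  Equilibrium statistics do not
#'   depend on the masses.
#' @param mass_mnp Nanoparticle mass; default `4 * mass`.  The heavier
#'   nanoparticles keep the stiff dipolar-contact vibrations stable at the
#'   default timestep without affecting any equilibrium observable.
#' @param inertia Nanoparticle moment of inertia; default solid-sphere value
#'   `mass_mnp * dp^2 / 10`.
#' @param k_stretch In-shell edge spring constant (`kBT/h^2`).  Deliberately
#'   soft: an amphiphilic membrane is a 2D fluid with no static shear
#'   modulus, and the mesh edge springs only regularise the triangulation.
#'   The default is the softest value whose thermal edge fluctuations stay
#'   below the mean mesh edge.  Raising it toward the near-inextensible
#'   regime (hundreds) suppresses the field-induced elongation.
#' @param k_area Triangle-area restoring constant (`kBT/h^2`).  Stiff: it
#'   enforces local (hence total) area conservation, the membrane's
#'   physical constraint, and keeps triangles from degenerating.
#' @param k_bend Dihedral bending constant (`kBT/rad^2`) of the
#'   shape-memory angle springs placed on every mesh edge, with the built
#'   geometry as reference.  The default corresponds to a bending modulus
#'   `kappa ~ sqrt(3)/2 * k_bend ~ 10 kBT`, typical of polymer membranes:
#'   large enough to keep the shells out of the thermally crumpled phase,
#'   small against the elastic and dipolar energy scales.  Set 0 to
#'   disable.
#' @param k_bond Intershell spring constant (`kBT/h^2`).  Softer than the
#'   in-shell springs so the layer thickness can fluctuate.
#' @param wca_eps Weeks-Chandler-Andersen energy scale (`kBT`).
#' @param dt Integration timestep (reduced time).
#' @param seed Seed for the geometric build (nanoparticle placement).
#' @param n_replicas Default replica count for field experiments.
#' @param mesh_coarsen Mesh coarsening factor >= 1.  The target mesh edge is
#'   `mesh_coarsen * dout`; values > 1 give fewer beads per shell for
#'   desk-scale runs.  Capped so the triangular pores stay impenetrable to
#'   the nanoparticles.
#' @param edge_target Explicit mesh edge target (reduced), overriding
#'   `mesh_coarsen * dout`.  Used by coarse-grained configurations where
#'   the shell beads are smaller than the nanoparticles and the wall is a
#'   WCA net rather than touching beads; always validated against the
#'   pore-impenetrability bound `sqrt(3) (dout + dp)/2`.
#'
#' @return An object of class `mps_params` (a validated named list).
#' @examples
#' p <- model_params(q = 6, lambda = 5, xi = 10)
#' p$hgap
#' @export
model_params <- function(q = 6, lambda = 5, xi = 0, phi = 0.11, cb = 0.2,
                         dp = 0.3, hgap = 0.35, din = NULL, dout = NULL,
                         h = 1, kBT = 1,
                         zeta_t = 1, zeta_r = NULL,
                         mass = 1, mass_mnp = NULL, inertia = NULL,
                         k_stretch = 10, k_area = 500, k_bend = 12,
                         k_bond = 50,
                         wca_eps = 1,
                         dt = 0.002, seed = 1L, n_replicas = 10L,
                         mesh_coarsen = 1, edge_target = NULL) {
  if (is.null(din) && is.null(dout)) {
    din <- dout <- h - hgap
  } else if (is.null(din)) {
    din <- 2 * (h - hgap) - dout
  } else if (is.null(dout)) {
    dout <- 2 * (h - hgap) - din
  }
  if (is.null(zeta_r)) zeta_r <- zeta_t * dp^2 / 3
  if (is.null(mass_mnp)) mass_mnp <- 4 * mass
  if (is.null(inertia)) inertia <- mass_mnp * dp^2 / 10

  p <- list(q = q, lambda = lambda, xi = xi, phi = phi, cb = cb,
            dp = dp, hgap = hgap, din = din, dout = dout, h = h, kBT = kBT,
            zeta_t = zeta_t, zeta_r = zeta_r, mass = mass,
            mass_mnp = mass_mnp, inertia = inertia,
            k_stretch = k_stretch, k_area = k_area, k_bend = k_bend,
            k_bond = k_bond,
            wca_eps = wca_eps, dt = dt, seed = as.integer(seed),
            n_replicas = as.integer(n_replicas), mesh_coarsen = mesh_coarsen,
            edge_target = edge_target)
  class(p) <- "mps_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(is.list(p))
  num_pos <- c("q", "phi", "cb", "dp", "hgap", "din", "dout", "h", "kBT",
               "zeta_t", "zeta_r", "mass", "mass_mnp", "inertia",
               "k_stretch", "k_area",
               "k_bond", "wca_eps", "dt", "mesh_coarsen")
  if (!is.numeric(p$k_bend) || length(p$k_bend) != 1L || !is.finite(p$k_bend) ||
      p$k_bend < 0)
    stop("parameter 'k_bend' must be a single non-negative number",
         call. = FALSE)
  for (f in num_pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", f, "' must be a single positive number", call. = FALSE)
  }
  if (abs(p$hgap - (p$h - (p$din + p$dout) / 2)) > 1e-9 * p$h)
    stop("inconsistent geometry: hgap must equal h - (din + dout)/2",
         call. = FALSE)
  if (p$dp >= p$hgap)
    stop("nanoparticle diameter dp must be smaller than the gap hgap ",
         "(the layer holds a monolayer)", call. = FALSE)
  if (p$q < 4)
    stop("q must be >= 4: smaller capsules have no inner cavity", call. = FALSE)
  if (p$cb > 1) stop("connectivity cb must be in (0, 1]", call. = FALSE)
  if (p$phi >= 0.6)
    stop("volume fraction phi must be below 0.6", call. = FALSE)
  if (p$lambda < 0 || p$xi < 0)
    stop("lambda and xi must be non-negative", call. = FALSE)
  # pore impenetrability cap: the circumradius of a mesh triangle must
  # stay inside the bead-nanoparticle contact distance
  sigma_out <- (p$dout + p$dp) / 2
  max_edge <- sqrt(3) * sigma_out * 0.999
  tgt <- if (!is.null(p$edge_target)) p$edge_target
         else p$mesh_coarsen * p$dout
  if (tgt > max_edge)
    stop("mesh edge target too large: shell pores would pass nanoparticles ",
         "(max edge ", signif(max_edge, 3), ")", call. = FALSE)
  invisible(p)
}

#' @export
print.mps_params <- function(x, ...) {
  cat("Magnetosensitive polymersome parameters (reduced units, h = 1)\n")
  cat(sprintf("  size q = %g   lambda = %g   xi = %g   phi = %g   cb = %g\n",
              x$q, x$lambda, x$xi, x$phi, x$cb))
  cat(sprintf("  dp = %g   hgap = %g   din = %g   dout = %g\n",
              x$dp, x$hgap, x$din, x$dout))
  cat(sprintf("  k_stretch = %g   k_area = %g   k_bend = %g   k_bond = %g\n",
              x$k_stretch, x$k_area, x$k_bend, x$k_bond))
  cat(sprintf("  dt = %g   zeta_t = %g   zeta_r = %g   seed = %d\n",
              x$dt, x$zeta_t, x$zeta_r, x$seed))
  invisible(x)
}

# Boltzmann constant, erg/K (Gaussian units)
kB_erg <- 1.380649e-16

#' Magnetic moment of a single nanoparticle from its material magnetization
#'
#' `mu = (pi/6) M dp^3`: the saturated moment of a homogeneously magnetized
#' sphere.  Gaussian units (emu, cm) are used throughout the material
#' conversions since ferrite magnetizations are quoted in emu/cm^3.
#'
#' @param dp_nm Particle diameter in nanometres.
#' @param M_emu_cc Material magnetization in emu/cm^3 (ferrites: ~500).
#' @return Magnetic moment in emu.
#' @examples
#' moment_from_material(15, 500) # ~8.8e-16 emu
#' @export
moment_from_material <- function(dp_nm, M_emu_cc) {
  stopifnot(dp_nm > 0, M_emu_cc >= 0)
  dp_cm <- dp_nm * 1e-7
  (pi / 6) * M_emu_cc * dp_cm^3
}

#' Dipolar coupling constant of a nanoparticle pair
#'
#' The ratio of the dipole-dipole interaction energy of two identical
#' particles at contact (separation `dp`) to the thermal energy:
#' `lambda = mu^2 / (dp^3 kB T)` in Gaussian units.
#'
#' Ferrite moments are usually quoted to one figure (a 15 nm particle at
#' `M = 500 emu/cm^3` is cited as `8e-16 emu` although the formula gives
#' `8.8e-16`); `mu_emu` lets the caller propagate such a quoted moment
#' instead of the formula value.
#'
#' @inheritParams moment_from_material
#' @param T_K Temperature in kelvin.
#' @param mu_emu Optional explicit moment (emu); overrides the material value.
#' @return Dimensionless coupling constant.
#' @examples
#' lambda_from_material(15, 500, 300)                  # ~5.6 (exact moment)
#' lambda_from_material(15, 500, 300, mu_emu = 8e-16)  # ~4.6 (quoted moment)
#' @export
lambda_from_material <- function(dp_nm, M_emu_cc, T_K, mu_emu = NULL) {
  stopifnot(T_K > 0)
  mu <- if (is.null(mu_emu)) moment_from_material(dp_nm, M_emu_cc) else mu_emu
  dp_cm <- dp_nm * 1e-7
  mu^2 / (dp_cm^3 * kB_erg * T_K)
}

#' Langevin field parameter from a dimensional field strength
#'
#' `xi = mu H0 / (kB T)` in Gaussian units: the Zeeman energy of one
#' nanoparticle moment in the applied field over the thermal energy.
#'
#' @param mu_emu Particle magnetic moment in emu.
#' @param H0_Oe Field strength in oersted.
#' @param T_K Temperature in kelvin.
#' @return Dimensionless field parameter.
#' @examples
#' xi_from_field(8e-16, 2000, 300) # ~39
#' @export
xi_from_field <- function(mu_emu, H0_Oe, T_K) {
  stopifnot(mu_emu >= 0, T_K > 0)
  mu_emu * H0_Oe / (kB_erg * T_K)
}

#' @rdname xi_from_field
#' @param xi Dimensionless field parameter.
#' @return `field_from_xi`: field strength in oersted.
#' @export
field_from_xi <- function(xi, mu_emu, T_K) {
  stopifnot(mu_emu > 0, T_K > 0)
  xi * kB_erg * T_K / mu_emu
}

#' Convert dimensional capsule inputs to reduced model parameters
#'
#' Maps laboratory quantities (nanometres, emu/cm^3, kelvin, oersted) onto
#' the reduced parameter set: lengths are scaled by the intershell distance
#' `h`, energies by `kB T`.  `reduced_to_dimensional` is the exact inverse.
#'
#' @param dp_nm Nanoparticle diameter, nm.
#' @param h_nm Intershell distance, nm (the length unit).
#' @param D_nm Outer capsule diameter, nm.
#' @param M_emu_cc Material magnetization, emu/cm^3.
#' @param T_K Temperature, K.
#' @param H0_Oe Applied field, Oe.
#' @return A named list with reduced `q`, `dp`, `lambda`, `xi`, the moment
#'   `mu_emu`, and the input scales.
#' @examples
#' r <- dimensional_to_reduced(15, 50, 300, 500, 300, 500)
#' d <- reduced_to_dimensional(r)
#' d$D_nm
#' @export
dimensional_to_reduced <- function(dp_nm, h_nm, D_nm, M_emu_cc, T_K, H0_Oe) {
  stopifnot(dp_nm > 0, h_nm > 0, D_nm > 0, T_K > 0, H0_Oe >= 0)
  mu <- moment_from_material(dp_nm, M_emu_cc)
  list(q = D_nm / h_nm,
       dp = dp_nm / h_nm,
       lambda = lambda_from_material(dp_nm, M_emu_cc, T_K),
       xi = xi_from_field(mu, H0_Oe, T_K),
       mu_emu = mu,
       h_nm = h_nm, T_K = T_K, M_emu_cc = M_emu_cc)
}

#' @rdname dimensional_to_reduced
#' @param reduced A list as returned by `dimensional_to_reduced`.
#' @export
reduced_to_dimensional <- function(reduced) {
  r <- reduced
  dp_nm <- r$dp * r$h_nm
  list(dp_nm = dp_nm,
       h_nm = r$h_nm,
       D_nm = r$q * r$h_nm,
       M_emu_cc = r$mu_emu / ((pi / 6) * (dp_nm * 1e-7)^3),
       T_K = r$T_K,
       H0_Oe = field_from_xi(r$xi, r$mu_emu, r$T_K))
}

#' Reduced dipole moment fixed by the coupling constant
#'
#' In reduced units the dipolar pair energy is written with prefactor
#' `lambda * kBT * dp^3`, so the moment magnitude is
#' `mu = sqrt(lambda * kBT * dp^3)`.  Rebuilding `lambda` from this moment
#' returns the input exactly (round-trip identity used in the tests).
#'
#' @param lambda Dipolar coupling constant.
#' @param dp Nanoparticle diameter (reduced).
#' @param kBT Thermal energy (reduced).
#' @return Reduced moment magnitude.
#' @export
reduced_moment <- function(lambda, dp, kBT = 1) {
  stopifnot(lambda >= 0, dp > 0, kBT > 0)
  sqrt(lambda * kBT * dp^3)
}

#' @rdname reduced_moment
#' @param mu Reduced moment magnitude.
#' @export
lambda_from_reduced_moment <- function(mu, dp, kBT = 1) {
  mu^2 / (dp^3 * kBT)
}
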
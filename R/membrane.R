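#' Build the double-shell membrane of a model polymersome
#'
#' Constructs two nested triangulated shells with an equal number of beads
#' and links a fraction `cb` of the subtending node pairs with linear
#' springs of rest length `h`.  The outer shell mid-surface sits at radius
#' `D/2 = q*h/2` (the capsule diameter refers to the bead mid-surface, so
#' the basic-state cavity is close to a sphere of diameter `D - 2h`); the
#' inner mid-surface lies exactly `h` below it, so
#' every intershell spring starts at its stress-free length.  Both shells
#' use the same subdivision level (equal bead counts) which aligns the
#' nodes radially: each bonded pair consists of mutual nearest nodes.
#'
#' The mesh edge target is the shell bead diameter (times `mesh_coarsen`),
#' so neighbouring beads touch and the wall is a closed steric barrier to
#' the nanoparticles.
#'
#' @param params An [model_params()] object.
#' @return An object of class `mps_membrane` with fields `inner`, `outer`
#'   (both `mps_shell`), `bonds` (b x 2 matrix: inner index, outer index),
#'   `bond_rest` (= `h`), `n_beads_per_shell`, `params`.
#' @examples
#' m <- build_membrane(model_params(q = 6, mesh_coarsen = 1.2))
#' m$n_beads_per_shell
#' @export
build_membrane <- function(params) {
  p <- validate_params(params)
  r_out <- p$q * p$h / 2
  r_in <- r_out - p$h
  if (r_in - p$din / 2 <= 0)
    stop("inconsistent geometry: inner shell radius is not positive",
         call. = FALSE)
  target <- if (!is.null(p$edge_target)) p$edge_target
            else p$mesh_coarsen * p$dout
  k <- choose_subdivisions(r_out, target, mode = "at_most")
  outer <- build_icosphere(r_out, subdivisions = k, bead_diameter = p$dout)
  inner <- build_icosphere(r_in, subdivisions = k, bead_diameter = p$din)
  n <- nrow(outer$positions)

  n_bonds <- min(n, ceiling(p$cb * n))
  set.seed(p$seed)
  picked <- sort(sample.int(n, n_bonds))
  # partner = nearest node on the other shell (radially aligned by
  # construction, so this is the same index; computed, not assumed)
  partner <- vapply(picked, function(i) {
    d2 <- rowSums((outer$positions - matrix(inner$positions[i, ], n, 3,
                                            byrow = TRUE))^2)
    which.min(d2)
  }, integer(1))
  bonds <- cbind(inner = picked, outer = partner)

  out <- list(inner = inner, outer = outer, bonds = bonds,
              bond_rest = p$h, n_beads_per_shell = n, params = p)
  class(out) <- "mps_membrane"
  validate_membrane(out)
  out
}

validate_membrane <- function(m) {
  if (nrow(m$inner$positions) != nrow(m$outer$positions))
    stop("shells must carry equal bead counts", call. = FALSE)
  n <- m$n_beads_per_shell
  cb <- m$params$cb
  if (abs(nrow(m$bonds) - cb * n) > 1 + 1e-9)
    stop("intershell bond count inconsistent with connectivity cb",
         call. = FALSE)
  len <- sqrt(rowSums((m$outer$positions[m$bonds[, 2], , drop = FALSE] -
                       m$inner$positions[m$bonds[, 1], , drop = FALSE])^2))
  if (any(abs(len - m$bond_rest) > 0.05 * m$bond_rest))
    stop("intershell bonds are not stress free at build", call. = FALSE)
  invisible(m)
}

#' @export
print.mps_membrane <- function(x, ...) {
  p <- x$params
  cat(sprintf("Polymersome membrane: q = %g (outer radius %.4g)\n",
              p$q, x$outer$radius))
  cat(sprintf("  %d beads per shell, %d intershell bonds (cb = %g)\n",
              x$n_beads_per_shell, nrow(x$bonds), p$cb))
  cat(sprintf("  outer mean edge %.3g, inner mean edge %.3g\n",
              mean(x$outer$rest_length), mean(x$inner$rest_length)))
  invisible(x)
}

# radial band available to nanoparticle centres
mnp_center_band <- function(m) {
  p <- m$params
  c(lo = m$inner$radius + (p$din + p$dp) / 2,
    hi = m$outer$radius - (p$dout + p$dp) / 2)
}

#' Volume of the intershell space accessible to the nanoparticles
#'
#' The spherical-shell volume between the inner bead surface and the outer
#' bead surface (radial width `hgap`), the region within which the
#' nanoparticles move and with respect to which the volume fraction `phi`
#' is defined.
#'
#' @param membrane An `mps_membrane`.
#' @return Volume in reduced units.
#' @export
gap_volume <- function(membrane) {
  p <- membrane$params
  r_lo <- membrane$inner$radius + p$din / 2
  r_hi <- membrane$outer$radius - p$dout / 2
  (4 * pi / 3) * (r_hi^3 - r_lo^3)
}
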
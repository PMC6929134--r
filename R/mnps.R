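#' Seed magnetic nanoparticles in the membrane gap
#'
#' Places `N = round(phi * V_gap / ((pi/6) dp^3))` dipolar nanoparticles
#' uniformly in the intershell gap: directions uniform on the sphere,
#' radii uniform over the band available to particle centres, followed by
#' deterministic soft-core push-apart sweeps until no pair overlaps by more
#' than 10% of `dp`.  Moment orientations are drawn isotropically; the
#' reduced moment magnitude follows from the coupling constant `lambda`
#' (see [reduced_moment()]).
#'
#' Replicas of a field experiment share nanoparticle positions (seeded by
#' `params$seed`) and differ only in the moment orientations, which are
#' drawn from `orientation_seed`.
#'
#' @param membrane An `mps_membrane`.
#' @param params An [model_params()] object (defaults to the membrane's).
#' @param orientation_seed Seed for the isotropic moment orientations;
#'   defaults to `params$seed`.
#' @return An object of class `mps_dipoles` with fields `positions`
#'   (N x 3), `orientations` (N x 3 unit rows), `mu` (reduced moment),
#'   `dp`, `n`, `phi_realized`.
#' @examples
#' m <- build_membrane(model_params(q = 6, mesh_coarsen = 1.2))
#' d <- seed_mnps(m)
#' d$n
#' @export
seed_mnps <- function(membrane, params = membrane$params,
                      orientation_seed = params$seed) {
  p <- validate_params(params)
  vgap <- gap_volume(membrane)
  v1 <- (pi / 6) * p$dp^3
  n <- round(p$phi * vgap / v1)
  band <- mnp_center_band(membrane)
  if (n == 0) {
    out <- list(positions = matrix(numeric(0), 0, 3),
                orientations = matrix(numeric(0), 0, 3),
                mu = reduced_moment(p$lambda, p$dp, p$kBT),
                dp = p$dp, n = 0L, phi_realized = 0)
    class(out) <- "mps_dipoles"
    return(out)
  }
  # monolayer feasibility: disc packing fraction on the mid-surface
  r_mid <- mean(band)
  pack <- n * (pi / 4) * p$dp^2 / (4 * pi * r_mid^2)
  if (pack > 0.8) {
    phi_max <- 0.8 / pack * p$phi
    stop(sprintf(paste0("phi = %.3g infeasible for a monolayer (area packing ",
                        "%.2f); maximum feasible phi ~ %.3g"),
                 p$phi, pack, phi_max), call. = FALSE)
  }

  set.seed(p$seed)
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  r <- stats::runif(n, band["lo"], band["hi"])
  pos <- u * r
  pos <- relax_overlaps(pos, p$dp, band)

  set.seed(as.integer(orientation_seed))
  e <- matrix(stats::rnorm(3 * n), n, 3)
  e <- e / sqrt(rowSums(e^2))

  out <- list(positions = pos, orientations = e,
              mu = reduced_moment(p$lambda, p$dp, p$kBT),
              dp = p$dp, n = as.integer(n),
              phi_realized = n * v1 / vgap)
  class(out) <- "mps_dipoles"
  out
}

# deterministic pairwise push-apart with radial clamping to the centre band
relax_overlaps <- function(pos, dp, band, tol = 0.9, max_sweeps = 500L) {
  n <- nrow(pos)
  if (n < 2) return(pos)
  for (s in seq_len(max_sweeps)) {
    d <- as.matrix(stats::dist(pos))
    diag(d) <- Inf
    if (min(d) >= tol * dp * (1 + 1e-9) && s > 1) break
    ov <- which(d < dp, arr.ind = TRUE)
    ov <- ov[ov[, 1] < ov[, 2], , drop = FALSE]
    if (!nrow(ov)) break
    for (k in seq_len(nrow(ov))) {
      i <- ov[k, 1]; j <- ov[k, 2]
      dv <- pos[j, ] - pos[i, ]
      dd <- sqrt(sum(dv^2))
      if (dd < 1e-12) dv <- c(1, 0, 0) * dp else dv <- dv / dd
      push <- 0.55 * (dp - min(dd, dp))
      pos[i, ] <- pos[i, ] - dv * push
      pos[j, ] <- pos[j, ] + dv * push
    }
    # clamp back into the radial band
    r <- sqrt(rowSums(pos^2))
    r2 <- pmin(pmax(r, band["lo"]), band["hi"])
    pos <- pos * (r2 / r)
  }
  pos
}

#' @export
print.mps_dipoles <- function(x, ...) {
  cat(sprintf(
    "Dipole set: %d nanoparticles, dp = %g, reduced moment %.4g (phi = %.4g)\n",
    x$n, x$dp, x$mu, x$phi_realized))
  invisible(x)
}
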
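#' Ellipsoidal semi-axes from the gyration tensor
#'
#' Computes the second-moment (gyration) tensor of the bead positions about
#' their centroid and returns semi-axis estimates proportional to the
#' square roots of its eigenvalues.  `b` is the component along the
#' eigenvector most aligned with the field; `a` and `c` the transverse
#' pair.  Only ratios enter the elongation parameter, so the overall
#' shell-thickness scaling of the eigenvalues cancels.
#'
#' @param positions n x 3 matrix (n >= 10, non-coplanar).
#' @param field_direction 3-vector; the deformation axis reference.
#' @return Named numeric vector `c(a, b, c)` with `b` field aligned.
#' @examples
#' u <- matrix(rnorm(3000), 1000, 3)
#' u <- u / sqrt(rowSums(u^2))
#' shape_semi_axes(u, c(0, 0, 1))  # ~ (1,1,1)/sqrt(3)
#' @export
shape_semi_axes <- function(positions, field_direction = c(0, 0, 1)) {
  if (nrow(positions) < 10)
    stop("need at least 10 positions for a shape estimate", call. = FALSE)
  x <- sweep(positions, 2, colMeans(positions))
  g <- crossprod(x) / nrow(x)
  ev <- eigen(g, symmetric = TRUE)
  if (min(ev$values) < 1e-12 * max(ev$values))
    stop("degenerate (coplanar) point set", call. = FALSE)
  h <- field_direction / sqrt(sum(field_direction^2))
  align <- abs(as.numeric(crossprod(ev$vectors, h)))
  ib <- which.max(align)
  semi <- sqrt(ev$values)
  trans <- sort(semi[-ib], decreasing = TRUE)
  c(a = trans[1], b = semi[ib], c = trans[2])
}

#' Elongation parameter
#'
#' `epsilon = 2 b / (a + c) - 1`: zero for a sphere, positive for a shape
#' stretched along the field-aligned axis `b`.
#'
#' @param a,b,c Semi-axes, `b` field aligned.
#' @return Dimensionless elongation.
#' @examples
#' elongation(1, 1.25, 1) # 0.25
#' @export
elongation <- function(a, b, c) {
  if (a + c <= 0) stop("degenerate semi-axes: a + c must be > 0",
                       call. = FALSE)
  2 * b / (a + c) - 1
}

#' Cavity volume of the inner shell polyhedron
#'
#' Signed-tetrahedra sum over the inner-shell triangulation (divergence
#' theorem): `V = sum det(x0, x1, x2) / 6` over outward-oriented triangles.
#' Inconsistently oriented input meshes are repaired by propagating a
#' consistent orientation across shared edges; the global sign is fixed to
#' give positive volume for a closed non-self-intersecting surface.
#'
#' @param shell An `mps_shell` (provides the triangulation).
#' @param positions Current vertex positions (defaults to the built ones).
#' @return Enclosed volume (reduced length^3).
#' @examples
#' sh <- build_icosphere(1, subdivisions = 3)
#' cavity_volume(sh)  # ~ 4*pi/3
#' @export
cavity_volume <- function(shell, positions = shell$positions) {
  tri <- repair_orientation(shell$triangles)
  v <- signed_volume(positions, tri)
  abs(v)
}

signed_volume <- function(pos, tri) {
  a <- pos[tri[, 1], , drop = FALSE]
  b <- pos[tri[, 2], , drop = FALSE]
  c <- pos[tri[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

# make triangle windings consistent: flood fill across shared edges,
# flipping triangles whose shared edge runs in the same direction
repair_orientation <- function(tri) {
  m <- nrow(tri)
  dir_edges <- function(t) rbind(t[c(1, 2)], t[c(2, 3)], t[c(3, 1)])
  # map undirected edge -> triangle ids
  key <- paste(pmin(tri[, 1], tri[, 2]), pmax(tri[, 1], tri[, 2]))
  keys <- c(paste(pmin(tri[, 1], tri[, 2]), pmax(tri[, 1], tri[, 2])),
            paste(pmin(tri[, 2], tri[, 3]), pmax(tri[, 2], tri[, 3])),
            paste(pmin(tri[, 3], tri[, 1]), pmax(tri[, 3], tri[, 1])))
  owner <- rep(seq_len(m), 3)
  by_edge <- split(owner, keys)
  if (any(lengths(by_edge) != 2))
    stop("mesh is not a closed manifold; cannot repair orientation",
         call. = FALSE)
  visited <- logical(m)
  queue <- 1L
  visited[1L] <- TRUE
  while (length(queue)) {
    t <- queue[1L]
    queue <- queue[-1L]
    de <- dir_edges(tri[t, ])
    for (r in 1:3) {
      e <- de[r, ]
      k <- paste(min(e), max(e))
      nb <- setdiff(by_edge[[k]], t)
      for (u in nb) {
        if (visited[u]) next
        deu <- dir_edges(tri[u, ])
        same <- any(deu[, 1] == e[1] & deu[, 2] == e[2])
        if (same) tri[u, ] <- tri[u, c(1, 3, 2)]  # consistent = opposite dir
        visited[u] <- TRUE
        queue <- c(queue, u)
      }
    }
  }
  tri
}

#' Relative cavity-volume change
#'
#' `(V - V0) / V0`, the volume defect of the magnetized state relative to
#' the field-free basic state.  Negative whenever an area-preserving
#' sphere-to-spheroid deformation shrinks the cavity.
#'
#' @param V Cavity volume in the field.
#' @param V0 Basic-state cavity volume.
#' @return Dimensionless defect.
#' @export
volume_defect <- function(V, V0) {
  stopifnot(V0 > 0)
  (V - V0) / V0
}

#' Nanoparticle chain statistics
#'
#' Two nanoparticles are linked when their centre distance is below
#' `link_dist_factor * dp` and their dipolar pair energy is below
#' `link_energy_kBT * kBT`; chains are the connected components of the
#' resulting graph.  The polar-zone occupancy is the fraction of
#' nanoparticles inside the two polar caps of half-angle `polar_cap_deg`
#' about the field axis through the capsule centre.
#'
#' @param dipoles An `mps_dipoles` (or list with `positions`,
#'   `orientations`, `mu`, `dp`).
#' @param field_direction Field axis for the polar caps.
#' @param center Capsule centre (default: centroid of the positions).
#' @param link_dist_factor,link_energy_kBT Chain linkage thresholds.
#' @param polar_cap_deg Polar cap half-angle in degrees.
#' @param kBT Thermal energy.
#' @return List with `n_chains`, `mean_length`, `max_length`, `lengths`,
#'   `polar_occupancy`, and `link_alignment`: the mean `|r^ . h^|` over
#'   linked pairs (1 for chains strictly along the field, 0.5 for randomly
#'   oriented links, `NA` when nothing is linked) -- the sharpest chain-order
#'   parameter when zero-field aggregates percolate.
#' @export
chain_stats <- function(dipoles, field_direction = c(0, 0, 1),
                        center = NULL, link_dist_factor = 1.3,
                        link_energy_kBT = -1, polar_cap_deg = 30,
                        kBT = 1) {
  pos <- dipoles$positions
  n <- nrow(pos)
  if (n < 1) stop("need at least one nanoparticle", call. = FALSE)
  h <- field_direction / sqrt(sum(field_direction^2))
  if (is.null(center)) center <- colMeans(pos)
  rel <- sweep(pos, 2, center)
  rn <- sqrt(rowSums(rel^2))
  cosang <- abs(as.numeric(rel %*% h)) / pmax(rn, 1e-12)
  polar <- mean(cosang > cos(polar_cap_deg * pi / 180))

  if (n == 1) {
    return(list(n_chains = 1L, mean_length = 1, max_length = 1L,
                lengths = 1L, polar_occupancy = polar,
                link_alignment = NA_real_))
  }
  pref <- dipoles$mu^2
  e <- dipoles$orientations
  d <- as.matrix(stats::dist(pos))
  cand <- which(upper.tri(d) & d < link_dist_factor * dipoles$dp,
                arr.ind = TRUE)
  linked <- matrix(integer(0), 0, 2)
  if (nrow(cand)) {
    keep <- vapply(seq_len(nrow(cand)), function(k) {
      i <- cand[k, 1]; j <- cand[k, 2]
      r <- pos[i, ] - pos[j, ]
      rr <- sqrt(sum(r^2))
      rh <- r / rr
      u <- pref * (sum(e[i, ] * e[j, ]) -
                   3 * sum(e[i, ] * rh) * sum(e[j, ] * rh)) / rr^3
      u < link_energy_kBT * kBT
    }, logical(1))
    linked <- cand[keep, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(linked)) g <- igraph::add_edges(g, as.integer(t(linked)))
  comp <- igraph::components(g)
  lens <- as.integer(comp$csize)
  align <- NA_real_
  if (nrow(linked)) {
    bv <- pos[linked[, 1], , drop = FALSE] - pos[linked[, 2], , drop = FALSE]
    align <- mean(abs(bv %*% h) / sqrt(rowSums(bv^2)))
  }
  list(n_chains = as.integer(comp$no), mean_length = mean(lens),
       max_length = max(lens), lengths = lens,
       polar_occupancy = polar, link_alignment = align)
}

#' Per-snapshot observable record
#'
#' Measures shape, cavity volume, magnetization projection and chain
#' structure of one configuration of a system state.
#'
#' @param state An `mps_state` (provides topology and parameters).
#' @param positions Optional positions to measure (defaults to the
#'   state's); layout inner beads / outer beads / nanoparticles.
#' @param orientations Optional moment orientations.
#' @return A list of class `mps_record` with fields `semi_axes`,
#'   `epsilon`, `cavity_volume`, `moment_projection`, `n_chains`,
#'   `mean_chain_length`, `max_chain_length`, `polar_occupancy`,
#'   `shell_area`, `xi`.
#' @export
observable_record <- function(state, positions = state$positions,
                              orientations = state$orientations) {
  n <- state$membrane$n_beads_per_shell
  inner <- positions[seq_len(n), , drop = FALSE]
  outer <- positions[n + seq_len(n), , drop = FALSE]
  h <- state$field_direction
  ax <- shape_semi_axes(outer, h)
  eps <- elongation(ax["a"], ax["b"], ax["c"])
  V <- cavity_volume(state$membrane$inner, inner)
  area <- shell_area(state$membrane$outer, outer) +
    shell_area(state$membrane$inner, inner)
  if (state$n_mnp > 0) {
    mpos <- positions[2 * n + seq_len(state$n_mnp), , drop = FALSE]
    dip <- list(positions = mpos, orientations = orientations,
                mu = state$dipoles$mu, dp = state$dipoles$dp)
    cs <- chain_stats(dip, h, center = colMeans(outer))
    mproj <- mean(orientations %*% h)
  } else {
    cs <- list(n_chains = 0L, mean_length = 0, max_length = 0L,
               polar_occupancy = NA_real_, link_alignment = NA_real_)
    mproj <- NA_real_
  }
  rec <- list(semi_axes = ax, epsilon = unname(eps), cavity_volume = V,
              moment_projection = mproj,
              n_chains = cs$n_chains, mean_chain_length = cs$mean_length,
              max_chain_length = cs$max_length,
              polar_occupancy = cs$polar_occupancy,
              link_alignment = cs$link_alignment,
              shell_area = area, xi = state$xi)
  class(rec) <- "mps_record"
  rec
}

# mean of numeric fields over a list of records
average_records <- function(records) {
  stopifnot(length(records) > 0)
  out <- records[[1]]
  flds <- c("epsilon", "cavity_volume", "moment_projection", "n_chains",
            "mean_chain_length", "max_chain_length", "polar_occupancy",
            "link_alignment", "shell_area")
  for (f in flds)
    out[[f]] <- mean(vapply(records, function(r) as.numeric(r[[f]]),
                            numeric(1)))
  out$semi_axes <- Reduce(`+`, lapply(records, `[[`, "semi_axes")) /
    length(records)
  out
}

#' @export
print.mps_record <- function(x, ...) {
  cat(sprintf(
    "Observables (xi = %g): eps = %+.4f, V = %.4g, <e.h> = %.3f\n",
    x$xi, x$epsilon, x$cavity_volume,
    ifelse(is.na(x$moment_projection), NaN, x$moment_projection)))
  cat(sprintf("  chains: %.1f (mean length %.2f, max %d), polar occupancy %.3f\n",
              x$n_chains, x$mean_chain_length, x$max_chain_length,
              x$polar_occupancy))
  invisible(x)
}
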
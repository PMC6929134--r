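#' Triangulated spherical shell
#'
#' A closed genus-0 triangular mesh whose vertices are the centres of the
#' polymer beads of one membrane shell.  Construction is by recursive
#' subdivision of a regular icosahedron with projection onto the sphere,
#' which yields a near-uniform mesh (valence 6 everywhere except the twelve
#' valence-5 icosahedral vertices).  Edge rest lengths and triangle
#' reference areas are recorded from the built geometry, so a freshly built
#' shell is stress free.
#'
#' @param radius Sphere radius (reduced length).
#' @param subdivisions Number of icosahedral subdivision steps (0 gives the
#'   bare icosahedron, each step quadruples the face count).  If `NULL`,
#'   chosen from `target_edge`.
#' @param target_edge Desired mean edge length; used when `subdivisions` is
#'   `NULL`.  Mode `"nearest"` picks the level whose mean edge is closest on
#'   a log scale; `"at_most"` picks the coarsest level with mean edge at or
#'   below the target (used for impenetrable walls).
#' @param mode Level-selection rule, see `target_edge`.
#' @param bead_diameter Diameter of the beads sitting at the mesh nodes.
#' @return An object of class `mps_shell` with fields `positions` (n x 3),
#'   `triangles` (m x 3, 1-based, outward oriented), `edges` (e x 2),
#'   `rest_length` (per edge), `ref_area` (per triangle), `radius`,
#'   `bead_diameter`.
#' @examples
#' sh <- build_icosphere(1, subdivisions = 1)
#' nrow(sh$positions)  # 42
#' @export
build_icosphere <- function(radius, subdivisions = NULL, target_edge = NULL,
                            mode = c("nearest", "at_most"),
                            bead_diameter = NULL) {
  mode <- match.arg(mode)
  stopifnot(radius > 0)
  if (is.null(subdivisions)) {
    if (is.null(target_edge))
      stop("give either subdivisions or target_edge", call. = FALSE)
    if (target_edge <= 0 || target_edge >= radius)
      stop("need radius > target_edge > 0; a sphere of this radius cannot ",
           "host >= 12 vertices at that spacing", call. = FALSE)
    subdivisions <- choose_subdivisions(radius, target_edge, mode)
  }
  stopifnot(subdivisions >= 0, subdivisions == round(subdivisions))
  mesh <- icosahedron_mesh()
  k <- 0
  while (k < subdivisions) {
    mesh <- subdivide_mesh(mesh)
    k <- k + 1
  }
  pos <- mesh$positions / sqrt(rowSums(mesh$positions^2)) * radius
  tri <- orient_outward(pos, mesh$triangles)
  ed <- edges_from_triangles(tri)
  rest <- sqrt(rowSums((pos[ed[, 1], ] - pos[ed[, 2], ])^2))
  ref <- triangle_areas(pos, tri)
  dih <- shell_dihedrals(tri, pos)
  out <- list(positions = pos, triangles = tri, edges = ed,
              rest_length = rest, ref_area = ref,
              dihedrals = dih$quads, phi0 = dih$phi0,
              radius = radius,
              bead_diameter = if (is.null(bead_diameter)) mean(rest)
                              else bead_diameter,
              subdivisions = as.integer(subdivisions))
  class(out) <- "mps_shell"
  validate_shell(out)
  out
}

# mean edge of a unit-radius icosphere at level k (icosahedron edge / 2^k,
# slightly shrunk by projection; the leading estimate is enough for level
# selection)
icosphere_edge_estimate <- function(radius, k) {
  radius * (4 / sqrt(10 + 2 * sqrt(5))) / 2^k
}

choose_subdivisions <- function(radius, target_edge, mode = "nearest",
                                max_level = 8L) {
  est <- icosphere_edge_estimate(radius, 0:max_level)
  if (mode == "at_most") {
    ok <- which(est <= target_edge)
    if (!length(ok))
      stop("target edge unreachable within ", max_level, " subdivision levels",
           call. = FALSE)
    return(min(ok) - 1L)
  }
  which.min(abs(log(est / target_edge))) - 1L
}

icosahedron_mesh <- function() {
  g <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  g, 0), c(1,  g, 0), c(-1, -g, 0), c(1, -g, 0),
    c(0, -1,  g), c(0, 1,  g), c(0, -1, -g), c(0, 1, -g),
    c(g, 0, -1), c(g, 0, 1), c(-g, 0, -1), c(-g, 0, 1))
  v <- v / sqrt(1 + g^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(positions = v, triangles = f)
}

subdivide_mesh <- function(mesh) {
  v <- mesh$positions
  f <- mesh$triangles
  nv <- nrow(v)
  # midpoint index cache keyed by ordered vertex pair
  key <- function(a, b) ifelse(a < b, a * (nv + 1) + b, b * (nv + 1) + a)
  env <- new.env(hash = TRUE, size = 4L * nrow(f))
  newv <- list()
  midpoint <- function(a, b) {
    k <- as.character(key(a, b))
    id <- env[[k]]
    if (!is.null(id)) return(id)
    p <- (v[a, ] + v[b, ]) / 2
    p <- p / sqrt(sum(p^2))
    newv[[length(newv) + 1L]] <<- p
    id <- nv + length(newv)
    env[[k]] <- id
    id
  }
  nf <- matrix(0L, nrow(f) * 4L, 3L)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    nf[4L * i - 3L, ] <- c(a, ab, ca)
    nf[4L * i - 2L, ] <- c(b, bc, ab)
    nf[4L * i - 1L, ] <- c(c, ca, bc)
    nf[4L * i, ] <- c(ab, bc, ca)
  }
  list(positions = rbind(v, do.call(rbind, newv)), triangles = nf)
}

edges_from_triangles <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  storage.mode(e) <- "integer"
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# one bending dihedral per mesh edge: quad (k, i, j, l) where triangles
# (k,i,j) and (i,j,l) share the edge i-j; reference angles from the built
# geometry (shape-memory bending)
shell_dihedrals <- function(tri, positions) {
  ea <- c(tri[, 1], tri[, 2], tri[, 3])
  eb <- c(tri[, 2], tri[, 3], tri[, 1])
  opp <- c(tri[, 3], tri[, 1], tri[, 2])
  lo <- pmin(ea, eb)
  hi <- pmax(ea, eb)
  o <- order(lo, hi)
  k1 <- o[seq(1, length(o), 2)]
  k2 <- o[seq(2, length(o), 2)]
  if (!all(lo[k1] == lo[k2] & hi[k1] == hi[k2]))
    stop("mesh edge not shared by exactly two triangles", call. = FALSE)
  quads <- cbind(opp[k1], lo[k1], hi[k1], opp[k2])
  storage.mode(quads) <- "integer"
  list(quads = quads, phi0 = .cpp_dihedral_angles(positions, quads))
}

triangle_areas <- function(pos, tri) {
  u <- pos[tri[, 2], , drop = FALSE] - pos[tri[, 1], , drop = FALSE]
  w <- pos[tri[, 3], , drop = FALSE] - pos[tri[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# flip triangles whose normal points toward the centroid
orient_outward <- function(pos, tri) {
  ctr <- colMeans(pos)
  for (i in seq_len(nrow(tri))) {
    a <- pos[tri[i, 1], ] - ctr
    u <- pos[tri[i, 2], ] - pos[tri[i, 1], ]
    w <- pos[tri[i, 3], ] - pos[tri[i, 1], ]
    n <- c(u[2] * w[3] - u[3] * w[2],
           u[3] * w[1] - u[1] * w[3],
           u[1] * w[2] - u[2] * w[1])
    if (sum(n * a) < 0) tri[i, ] <- tri[i, c(1, 3, 2)]
  }
  tri
}

validate_shell <- function(sh) {
  V <- nrow(sh$positions); E <- nrow(sh$edges); F <- nrow(sh$triangles)
  if (V - E + F != 2L)
    stop("mesh is not a closed genus-0 surface (V - E + F = ",
         V - E + F, ")", call. = FALSE)
  # every undirected edge must be shared by exactly two triangles
  e <- rbind(sh$triangles[, c(1, 2)], sh$triangles[, c(2, 3)],
             sh$triangles[, c(3, 1)])
  k <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (any(table(k) != 2L))
    stop("mesh has boundary or non-manifold edges", call. = FALSE)
  if (any(sh$rest_length <= 0) || any(sh$ref_area <= 0))
    stop("degenerate edges or triangles in shell", call. = FALSE)
  invisible(sh)
}

#' @export
print.mps_shell <- function(x, ...) {
  cat(sprintf(
    "Triangulated shell: radius %.4g, %d beads, %d edges, %d triangles\n",
    x$radius, nrow(x$positions), nrow(x$edges), nrow(x$triangles)))
  cat(sprintf("  mean edge %.4g, bead diameter %.4g, total area %.4g\n",
              mean(x$rest_length), x$bead_diameter, sum(x$ref_area)))
  invisible(x)
}

#' Total surface area of a triangulated shell configuration
#'
#' @param shell An `mps_shell`.
#' @param positions Optional n x 3 matrix of current bead positions
#'   (defaults to the built positions).
#' @return Sum of triangle areas.
#' @export
shell_area <- function(shell, positions = shell$positions) {
  sum(triangle_areas(positions, shell$triangles))
}
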
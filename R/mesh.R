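#' Build a graded triangular mesh of a disk
#'
#' Generates an unstructured-style triangulation of the disk of the given
#' radius (centered at the origin) whose local element diameter grades
#' linearly in radius between `h_center` at the origin and `h_boundary` at
#' the rim.  Vertices are laid out on concentric rings whose spacing and
#' in-ring arc length both follow the sizing field; rings receive a seeded
#' random angular offset so successive rings are not aligned.  The
#' construction is deterministic given `seed`.
#'
#' @param radius domain radius in cm.
#' @param h_boundary target element diameter at the boundary (cm).
#' @param h_center target element diameter at the center (cm).
#' @param seed integer seed controlling the ring offsets.
#' @return an object of class `qp_mesh` with fields `vertices` (N x 2,
#'   cm), `triangles` (M x 3 vertex indices, counter-clockwise),
#'   `boundary_edges` (E x 2), `boundary_normals` (E x 2, outward unit
#'   vectors), and `radius`.
#' @export
build_disk_mesh <- function(radius, h_boundary, h_center, seed = 1L) {
  if (!(radius > 0)) stop("radius must be positive", call. = FALSE)
  if (!(h_boundary > 0 && h_boundary <= h_center))
    stop("sizing error: need 0 < h_boundary <= h_center", call. = FALSE)
  if (h_center > radius)
    stop("sizing error: h_center exceeds the domain radius (infeasible sizing)",
         call. = FALSE)

  hfun <- function(r) h_center + (h_boundary - h_center) * r / radius

  ## ring radii follow dr = h(r); last ring lands exactly on the rim
  radii <- 0
  r <- 0
  repeat {
    step <- hfun(r)
    if (r + step >= radius - 0.45 * h_boundary) break
    r <- r + step
    radii <- c(radii, r)
  }
  radii <- c(radii, radius)

  verts <- matrix(0, nrow = 0, ncol = 2)
  ring_idx <- vector("list", length(radii))
  local_seed(seed, {
    for (k in seq_along(radii)) {
      rk <- radii[k]
      if (rk == 0) {
        ring_idx[[k]] <- nrow(verts) + 1L
        verts <- rbind(verts, c(0, 0))
        next
      }
      n_k <- max(6L, as.integer(round(2 * pi * rk / hfun(rk))))
      off <- if (k < length(radii)) runif(1, 0, 2 * pi / n_k) else 0
      th <- 2 * pi * (seq_len(n_k) - 1L) / n_k + off
      ring_idx[[k]] <- nrow(verts) + seq_len(n_k)
      verts <- rbind(verts, cbind(rk * cos(th), rk * sin(th)))
    }
  })

  tris <- vector("list", length(radii) - 1L)
  for (k in seq_len(length(radii) - 1L)) {
    inner <- ring_idx[[k]]
    outer <- ring_idx[[k + 1L]]
    if (length(inner) == 1L) {
      nb <- length(outer)
      tris[[k]] <- cbind(inner, outer, outer[c(2:nb, 1L)])
    } else {
      tris[[k]] <- triangulate_annulus(verts, inner, outer)
    }
  }
  triangles <- do.call(rbind, tris)

  ## enforce counter-clockwise orientation
  a <- verts[triangles[, 1], , drop = FALSE]
  b <- verts[triangles[, 2], , drop = FALSE]
  cc <- verts[triangles[, 3], , drop = FALSE]
  sa <- (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
        (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])
  flip <- sa < 0
  if (any(flip)) triangles[flip, 2:3] <- triangles[flip, 3:2]

  bring <- ring_idx[[length(radii)]]
  nb <- length(bring)
  boundary_edges <- cbind(bring, bring[c(2:nb, 1L)])
  e1 <- verts[boundary_edges[, 1], , drop = FALSE]
  e2 <- verts[boundary_edges[, 2], , drop = FALSE]
  ev <- e2 - e1
  nrm <- cbind(ev[, 2], -ev[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  mid <- (e1 + e2) / 2
  sgn <- sign(rowSums(nrm * mid))
  nrm <- nrm * sgn

  mesh <- structure(
    list(vertices = verts, triangles = triangles,
         boundary_edges = boundary_edges, boundary_normals = nrm,
         radius = radius, h_boundary = h_boundary, h_center = h_center,
         seed = as.integer(seed)),
    class = "qp_mesh")
  validate_mesh(mesh)
  mesh
}

## Triangulate the annulus between two concentric vertex rings with the
## classic two-pointer sweep: at each step the shorter advancing edge is
## chosen, yielding length(inner) + length(outer) triangles.
triangulate_annulus <- function(verts, inner, outer) {
  na <- length(inner); nb <- length(outer)
  tha <- atan2(verts[inner, 2], verts[inner, 1])
  thb <- atan2(verts[outer, 2], verts[outer, 1])
  oa <- order(tha); inner <- inner[oa]; tha <- tha[oa]
  ob <- order(thb); outer <- outer[ob]; thb <- thb[ob]

  ## unwrap the outer ring angles to start just after tha[1]
  rel <- (thb - tha[1]) %% (2 * pi)
  j0 <- which.min(rel)
  ordb <- ((j0 - 1L + 0:(nb - 1L)) %% nb) + 1L
  outer <- outer[ordb]
  bu <- tha[1] + rel[ordb]
  au <- tha[1] + (tha - tha[1]) %% (2 * pi)
  au <- c(au, au[1] + 2 * pi)
  bu <- c(bu, bu[1] + 2 * pi)

  tri <- matrix(0L, nrow = na + nb, ncol = 3)
  ai <- 1L; bi <- 1L; t <- 0L
  idx <- function(v, i, n) v[((i - 1L) %% n) + 1L]
  while (ai <= na || bi <= nb) {
    t <- t + 1L
    adv_a <- if (bi > nb) TRUE else if (ai > na) FALSE else au[ai + 1L] <= bu[bi + 1L]
    A <- idx(inner, ai, na); B <- idx(outer, bi, nb)
    if (adv_a) {
      tri[t, ] <- c(A, B, idx(inner, ai + 1L, na)); ai <- ai + 1L
    } else {
      tri[t, ] <- c(A, B, idx(outer, bi + 1L, nb)); bi <- bi + 1L
    }
  }
  tri
}

#' Check mesh invariants
#'
#' Verifies positive triangle orientation, boundary vertices on the circle
#' within mesh-size tolerance, outward unit boundary normals, and that
#' each boundary edge belongs to exactly one triangle.  Called by
#' [build_disk_mesh()]; exported for direct use on externally constructed
#' meshes.
#'
#' @param mesh a `qp_mesh`.
#' @return invisibly `TRUE`, or an error describing the violated invariant.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  ar <- triangle_areas(mesh)
  if (any(ar <= 0))
    stop("mesh invariant violated: non-positive triangle area (element ",
         which(ar <= 0)[1], ")", call. = FALSE)
  bn <- unique(as.vector(mesh$boundary_edges))
  rb <- sqrt(rowSums(v[bn, , drop = FALSE]^2))
  if (any(abs(rb - mesh$radius) > 0.1 * mesh$h_boundary))
    stop("mesh invariant violated: boundary vertex off the circle", call. = FALSE)
  nn <- sqrt(rowSums(mesh$boundary_normals^2))
  if (any(abs(nn - 1) > 1e-10))
    stop("mesh invariant violated: non-unit boundary normal", call. = FALSE)
  mid <- (v[mesh$boundary_edges[, 1], , drop = FALSE] +
          v[mesh$boundary_edges[, 2], , drop = FALSE]) / 2
  if (any(rowSums(mesh$boundary_normals * mid) <= 0))
    stop("mesh invariant violated: inward boundary normal", call. = FALSE)
  ## each boundary edge must belong to exactly one triangle
  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  tkeys <- c(ekey(tr[, 1], tr[, 2]), ekey(tr[, 2], tr[, 3]), ekey(tr[, 3], tr[, 1]))
  cnt <- table(tkeys)[ekey(mesh$boundary_edges[, 1], mesh$boundary_edges[, 2])]
  if (any(is.na(cnt)) || any(cnt != 1L))
    stop("mesh invariant violated: boundary edge not in exactly one triangle",
         call. = FALSE)
  invisible(TRUE)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  0.5 * ((b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
         (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1]))
}

mesh_min_edge <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  el <- function(i, j) sqrt(rowSums((v[tr[, i], , drop = FALSE] -
                                     v[tr[, j], , drop = FALSE])^2))
  min(el(1, 2), el(2, 3), el(3, 1))
}

#' @export
print.qp_mesh <- function(x, ...) {
  cat(sprintf("qp_mesh: disk radius %.3g cm, %d vertices, %d triangles, %d boundary edges\n",
              x$radius, nrow(x$vertices), nrow(x$triangles), nrow(x$boundary_edges)))
  cat(sprintf("  sizing: h = %.3g cm (boundary) .. %.3g cm (center)\n",
              x$h_boundary, x$h_center))
  invisible(x)
}

#' Expected vertex count for a sizing field
#'
#' Closed-form density estimate of the number of vertices an ideal mesher
#' places in the disk under the linear radial sizing field: the integral of
#' the vertex density 1/h(r)^2 over the domain.  Used as an independent
#' oracle for mesh resolution.
#'
#' @inheritParams build_disk_mesh
#' @return expected vertex count (double).
#' @export
expected_vertex_count <- function(radius, h_boundary, h_center) {
  f <- function(r) 2 * pi * r / (h_center + (h_boundary - h_center) * r / radius)^2
  stats::integrate(f, 0, radius)$value
}

#' Write a mesh (with optional nodal fields) as legacy ASCII VTK
#'
#' @param mesh a `qp_mesh`.
#' @param file output path.
#' @param point_data named list of length-N nodal vectors to attach.
#' @return invisibly the file path.
#' @export
write_mesh_vtk <- function(mesh, file, point_data = list()) {
  v <- mesh$vertices; tr <- mesh$triangles - 1L
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "qpactoed mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.10g %.10g 0", v[, 1], v[, 2]), con)
  writeLines(sprintf("CELLS %d %d", nrow(tr), 4 * nrow(tr)), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(tr)), con)
  writeLines(rep("5", nrow(tr)), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", point_data[[nm]]), con)
    }
  }
  invisible(file)
}
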
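#' Assemble first-order continuous Galerkin finite-element structures
#'
#' Precomputes everything needed for P1 assembly on a triangular mesh:
#' the consistent mass matrix, the unit-coefficient stiffness matrix, the
#' boundary mass matrix for the Robin surface term, per-element basis
#' gradients, averaged outward unit normals at boundary nodes, and the
#' scatter operators that make repeated coefficient-dependent assembly
#' and element-to-node accumulation O(nnz) with no sorting.
#'
#' @param mesh a `qp_mesh` from [build_disk_mesh()].
#' @return an object of class `qp_fem`.
#' @export
assemble_fem <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  N <- nrow(v); M <- nrow(tr)
  area <- triangle_areas(mesh)
  if (any(area <= 1e-14 * mesh$radius^2))
    stop("degenerate (zero-area) triangle in assembly: element ",
         which(area <= 1e-14 * mesh$radius^2)[1], call. = FALSE)

  x <- matrix(v[tr, 1], M, 3); y <- matrix(v[tr, 2], M, 3)
  ## P1 gradient coefficients: grad(phi_i) = (bg[,i], cg[,i]) / (2*area)
  bg <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  cg <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])

  ## element triplets for the 9 local (i, j) blocks, plus per-block
  ## weights for exact P1 reaction coefficients and element-mean
  ## diffusion coefficients
  ii <- jj <- integer(9 * M)
  mconst <- geo <- matrix(0, M, 9)
  Wc <- list(matrix(0, M, 9), matrix(0, M, 9), matrix(0, M, 9))
  p <- 0L
  for (a in 1:3) for (b in 1:3) {
    p <- p + 1L
    idx <- (p - 1L) * M + seq_len(M)
    ii[idx] <- tr[, a]; jj[idx] <- tr[, b]
    mconst[, p] <- area / if (a == b) 6 else 12
    geo[, p] <- (bg[, a] * bg[, b] + cg[, a] * cg[, b]) / (4 * area)
    if (a == b) {
      for (k in 1:3) Wc[[k]][, p] <- area * (if (k == a) 3 else 1) / 30
    } else {
      for (k in 1:3) Wc[[k]][, p] <- area * (if (k == a || k == b) 2 else 1) / 60
    }
  }

  be <- mesh$boundary_edges
  elen <- sqrt(rowSums((v[be[, 1], , drop = FALSE] - v[be[, 2], , drop = FALSE])^2))
  bi <- c(be[, 1], be[, 2], be[, 1], be[, 2])
  bj <- c(be[, 1], be[, 2], be[, 2], be[, 1])
  bx <- c(elen / 3, elen / 3, elen / 6, elen / 6)

  ## deduplicated sparsity pattern and triplet -> slot scatter operator
  ti <- c(ii, bi); tj <- c(jj, bj)
  pattern <- Matrix::sparseMatrix(i = ti, j = tj, x = 0, dims = c(N, N))
  pkey <- (rep.int(seq_len(N), diff(pattern@p)) - 1) * N + pattern@i + 1
  slot <- match((tj - 1) * N + ti, pkey)
  scatter <- Matrix::sparseMatrix(i = slot, j = seq_along(slot), x = 1,
                                  dims = c(length(pattern@x), length(slot)))

  Mmat <- pattern; Mmat@x <- as.numeric(scatter %*% c(as.vector(mconst), 0 * bx))
  Kmat <- pattern; Kmat@x <- as.numeric(scatter %*% c(as.vector(geo), 0 * bx))
  Bmat <- Matrix::sparseMatrix(i = bi, j = bj, x = bx, dims = c(N, N))

  ## element-to-node accumulation operator (N x 3M)
  node_acc <- Matrix::sparseMatrix(i = as.vector(tr), j = seq_len(3 * M), x = 1,
                                   dims = c(N, 3 * M))

  ## averaged outward unit normal per boundary node (length-weighted)
  bnodes <- sort(unique(as.vector(be)))
  nacc <- matrix(0, N, 2)
  for (k in 1:2) {
    r1 <- rowsum(elen * mesh$boundary_normals[, 1] / 2, be[, k])
    r2 <- rowsum(elen * mesh$boundary_normals[, 2] / 2, be[, k])
    nacc[as.integer(rownames(r1)), 1] <- nacc[as.integer(rownames(r1)), 1] + r1
    nacc[as.integer(rownames(r2)), 2] <- nacc[as.integer(rownames(r2)), 2] + r2
  }
  nn <- sqrt(rowSums(nacc^2))
  node_normals <- nacc[bnodes, , drop = FALSE] / nn[bnodes]

  structure(
    list(mesh = mesh, n_nodes = N, mass_matrix = Mmat, stiffness_matrix = Kmat,
         boundary_mass = Bmat, areas = area, tri = tr, grad_b = bg, grad_c = cg,
         pattern = pattern, scatter = scatter, mass_weights = Wc, geo = geo,
         boundary_x = bx, node_acc = node_acc, tri0 = tr - 1L,
         boundary_nodes = bnodes, boundary_node_normals = node_normals,
         boundary_edge_lengths = elen),
    class = "qp_fem")
}

#' Assemble a coefficient-dependent bilinear form
#'
#' Returns the sparse matrix of the form
#' \eqn{\int_\Omega a\,u\,v + \int_\Omega b\,\nabla u \cdot \nabla v +
#' \rho \oint_{\partial\Omega} u\,v} for piecewise-linear nodal
#' coefficients `a` and `b`.  The reaction coefficient `a` is integrated
#' exactly (P1 x P1 x P1 quadrature); the diffusion coefficient `b`
#' enters through its element mean, exact for P1 `b` against constant
#' element gradients.
#'
#' @param fem a `qp_fem`.
#' @param a nodal reaction coefficient (length N), or a scalar, or `NULL`.
#' @param b nodal diffusion coefficient, scalar, or `NULL`.
#' @param robin scalar multiplier of the boundary mass matrix.
#' @return a symmetric sparse `Matrix`.
#' @export
assemble_operator <- function(fem, a = NULL, b = NULL, robin = 0) {
  N <- fem$n_nodes
  tr <- fem$tri; Mel <- nrow(tr)
  vals <- matrix(0, Mel, 9)
  if (!is.null(a)) {
    if (length(a) == 1L) a <- rep(a, N)
    if (length(a) != N) stop_dim("reaction coefficient", N, length(a))
    vals <- vals + a[tr[, 1]] * fem$mass_weights[[1]] +
      a[tr[, 2]] * fem$mass_weights[[2]] + a[tr[, 3]] * fem$mass_weights[[3]]
  }
  if (!is.null(b)) {
    if (length(b) == 1L) b <- rep(b, N)
    if (length(b) != N) stop_dim("diffusion coefficient", N, length(b))
    bbar <- (b[tr[, 1]] + b[tr[, 2]] + b[tr[, 3]]) / 3
    vals <- vals + bbar * fem$geo
  }
  if (is.null(a) && is.null(b) && robin == 0)
    stop("no coefficients supplied", call. = FALSE)
  A <- fem$pattern
  A@x <- as.numeric(fem$scatter %*% c(as.vector(vals), robin * fem$boundary_x))
  A
}

#' Integrate a nodal field over the domain
#'
#' Computes \eqn{\int_\Omega f\,dx = \mathbf{1}^T M f} for a P1 field.
#'
#' @param field nodal coefficient vector (length N).
#' @param fem a `qp_fem`.
#' @return scalar integral.
#' @export
integrate_field <- function(field, fem) {
  if (length(field) != fem$n_nodes) stop_dim("field", fem$n_nodes, length(field))
  sum(as.numeric(fem$mass_matrix %*% field))
}

## nodal vector t with t_k = d/da_k [ p^T M(a) phi ]; the P1 trilinear
## tensor is fully symmetric, so this is also M(p) phi etc.
mass_trilinear_vec <- function(fem, p, phi) {
  fem_mass_trilinear(fem$tri0, fem$areas, p, phi, fem$n_nodes)
}

## nodal vector w with w_k = d/db_k [ p^T K(bbar(b)) phi ],  bbar = element mean
stiff_trilinear_vec <- function(fem, p, phi) {
  fem_stiff_trilinear(fem$tri0, fem$areas, fem$grad_b, fem$grad_c, p, phi,
                      fem$n_nodes)
}

## (M(a) phi): fully symmetric trilinear tensor
mass_coeff_apply <- function(fem, a, phi) mass_trilinear_vec(fem, a, phi)

## (K(bbar) phi) with element-mean coefficient
stiff_coeff_apply <- function(fem, b, phi) {
  fem_stiff_apply(fem$tri0, fem$areas, fem$grad_b, fem$grad_c, b, phi,
                  fem$n_nodes)
}

#' @export
print.qp_fem <- function(x, ...) {
  cat(sprintf("qp_fem: %d nodes, %d elements, domain area %.6g cm^2\n",
              x$n_nodes, nrow(x$tri), sum(x$areas)))
  invisible(x)
}
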
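#' Acoustic detection geometry
#'
#' Idealized point transducers uniformly placed on a circle around the
#' domain, each sampling the circular-Radon data function at uniformly
#' spaced times.  The arc radii are \eqn{c_0 (t_0 + k\,\Delta t)},
#' `k = 0, ..., n_times - 1`.  The default time offset `t0` places the
#' first arc at the gap between the transducer ring and the domain
#' boundary (1 cm at the default radii), so the sampled arcs sweep the
#' near portion of the domain; it is configurable because only the
#' sample count and spacing are physically constrained.
#'
#' @param n_transducers number of transducers (default 360).
#' @param ring_radius transducer circle radius, cm (default 6).
#' @param n_times time samples per transducer (default 184).
#' @param dt sampling interval, s (default 2e-7).
#' @param c0 sound speed, cm/s (default 1.5e5, i.e. 1500 m/s).
#' @param t0 time offset of the first sample, s (default: ring gap).
#' @param domain_radius domain radius, cm (default 5).
#' @return an object of class `qp_acoustic_geometry`; `K` is the total
#'   data dimension.
#' @export
acoustic_geometry <- function(n_transducers = 360L, ring_radius = 6,
                              n_times = 184L, dt = 2e-7, c0 = 1.5e5,
                              t0 = NULL, domain_radius = 5) {
  if (ring_radius <= domain_radius)
    stop("transducers must lie outside the closed domain", call. = FALSE)
  t0 <- t0 %||% ((ring_radius - domain_radius) / c0)
  ang <- 2 * pi * (seq_len(n_transducers) - 1L) / n_transducers
  structure(
    list(transducers = cbind(ring_radius * cos(ang), ring_radius * sin(ang)),
         n_transducers = as.integer(n_transducers), ring_radius = ring_radius,
         n_times = as.integer(n_times), dt = dt, c0 = c0, t0 = t0,
         radii = c0 * (t0 + dt * (seq_len(n_times) - 1L)),
         domain_radius = domain_radius,
         K = as.integer(n_transducers) * as.integer(n_times)),
    class = "qp_acoustic_geometry")
}

#' Assemble the circular Radon transform operator
#'
#' Builds the sparse K x N matrix whose row (j, k) approximates the line
#' integral of the P1 basis along the circle of radius \eqn{c_0 t_k}
#' about transducer j, restricted to the domain, by fixed-step midpoint
#' arc quadrature with barycentric interpolation.  The operator is the
#' measurement model \eqn{d = H_a h}; its adjoint is the exact matrix
#' transpose.
#'
#' @param mesh a `qp_mesh`.
#' @param geom a `qp_acoustic_geometry`.
#' @param step arc quadrature step (cm); default one quarter of the
#'   minimum element edge.  Steps coarser than the minimum element size
#'   are rejected as undersampling.
#' @return an object of class `qp_crt` wrapping the sparse matrix `H`.
#' @export
build_crt <- function(mesh, geom, step = NULL) {
  min_h <- mesh_min_edge(mesh)
  step <- step %||% (min_h / 4)
  if (step > min_h)
    stop(sprintf("arc quadrature step %.4g exceeds minimum element size %.4g (undersampling)",
                 step, min_h), call. = FALSE)
  trip <- crt_assemble_cpp(mesh$vertices, mesh$triangles - 1L,
                           geom$transducers, geom$radii, mesh$radius, step)
  H <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(geom$K, nrow(mesh$vertices)))
  structure(list(H = H, geom = geom, step = step, n_nodes = nrow(mesh$vertices)),
            class = "qp_crt")
}

#' Apply the CRT operator (or its adjoint) to a field
#'
#' @param op a `qp_crt`.
#' @param h nodal field (length N), or a data vector (length K) when
#'   `adjoint = TRUE`.
#' @param adjoint apply the exact transpose instead.
#' @return data vector of length K (or nodal vector of length N).
#' @export
apply_crt <- function(op, h, adjoint = FALSE) {
  if (adjoint) {
    if (length(h) != op$geom$K) stop_dim("data vector", op$geom$K, length(h))
    return(as.numeric(Matrix::crossprod(op$H, h)))
  }
  if (length(h) != op$n_nodes) stop_dim("field", op$n_nodes, length(h))
  as.numeric(op$H %*% h)
}

#' Closed-form sinogram of a centered disk indicator
#'
#' Circle-circle intersection arc length: for a unit-height indicator of
#' the disk of radius `a` centered at the origin and a transducer at
#' distance `L` from the origin, the data function at arc radius
#' \eqn{\rho} is \eqn{2\rho\,\arccos[(L^2 + \rho^2 - a^2)/(2L\rho)]} for
#' \eqn{|L - a| < \rho < L + a} and zero otherwise.  Independent oracle
#' for the assembled operator.
#'
#' @param rho arc radii (cm).
#' @param L transducer distance from the origin (cm).
#' @param a disk radius (cm).
#' @return data values at `rho`.
#' @export
disk_sinogram <- function(rho, L, a) {
  arg <- (L^2 + rho^2 - a^2) / (2 * L * rho)
  out <- numeric(length(rho))
  inside <- arg < 1 & arg > -1
  out[inside] <- 2 * rho[inside] * acos(arg[inside])
  out
}

#' @export
print.qp_crt <- function(x, ...) {
  cat(sprintf("qp_crt: %d x %d sparse operator (%d nonzeros), %d transducers x %d times, step %.3g cm\n",
              nrow(x$H), ncol(x$H), length(x$H@x),
              x$geom$n_transducers, x$geom$n_times, x$step))
  invisible(x)
}
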
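#' Cone-beam light source
#'
#' @param position length-2 source position (cm), outside the domain.
#' @param direction length-2 pointing direction (normalized internally).
#' @param power source power P (AU cm).
#' @param aperture full aperture angle beta (radians); the beam is cut
#'   off at `|theta| >= beta/2`.
#' @param mu_a_prime absorption of the surrounding medium (cm^-1).
#' @return an object of class `qp_source`.
#' @export
cone_beam_source <- function(position, direction, power = 1,
                             aperture = 25 * pi / 180, mu_a_prime = 1e-3) {
  stopifnot(length(position) == 2, length(direction) == 2,
            power >= 0, aperture > 0, aperture < pi)
  direction <- direction / sqrt(sum(direction^2))
  structure(list(position = as.numeric(position), direction = direction,
                 power = power, aperture = aperture, mu_a_prime = mu_a_prime),
            class = "qp_source")
}

#' Flux density of a cone-beam source at boundary points
#'
#' Evaluates the attenuated monopole beam
#' \deqn{q(x; s) = P\,g(\theta)\,\frac{e^{-\mu_a' \|s-x\|}}{4\pi\|s-x\|^2}\,u,}
#' with \eqn{u = (s-x)/\|s-x\|}, \eqn{g(\theta) = \cos\theta\,
#' \mathbf{1}(|\theta| < \beta/2)}, and \eqn{\theta} the angle between the
#' source pointing direction and the ray from the source to `x`.
#'
#' @param x n x 2 matrix of evaluation points (or a length-2 vector).
#' @param source a `qp_source`.
#' @return n x 2 matrix of flux vectors (AU cm^-1).
#' @export
cone_beam_flux <- function(x, source) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  dx <- cbind(source$position[1] - x[, 1], source$position[2] - x[, 2])
  r <- sqrt(rowSums(dx^2))
  if (any(r == 0)) stop("evaluation point coincides with the source", call. = FALSE)
  u <- dx / r
  ## ray from s to x is -u
  cth <- -(u[, 1] * source$direction[1] + u[, 2] * source$direction[2])
  cth <- pmin(pmax(cth, -1), 1)
  g <- ifelse(acos(cth) < source$aperture / 2, cth, 0)
  mag <- source$power * g * exp(-source$mu_a_prime * r) / (4 * pi * r^2)
  u * mag
}

#' Multi-illumination design schemes
#'
#' Constructs the source sets of the illumination design schemes:
#' `"contiguous"` places `S` sources uniformly on a 90-degree arc of the
#' source ring and rotates them by pi/2 between illuminations;
#' `"interlaced"` places `S` sources uniformly around the full ring and
#' rotates them by pi/20; `"single_uniform"` is the idealized
#' single-illumination scheme with unit uniform boundary flux (the
#' cone-beam model is bypassed).  All sources point towards the center
#' of the imaging system.
#'
#' @param scheme one of `"contiguous"`, `"interlaced"`, `"single_uniform"`.
#' @param ring_radius source ring radius (cm).
#' @param S sources per illumination.
#' @param I number of illuminations.
#' @param aperture full aperture angle (radians).
#' @param mu_a_prime exterior absorption (cm^-1).
#' @param power initial shared source power (rescaled by
#'   [normalize_power()]).
#' @return an object of class `qp_design`: a list of `I` illuminations,
#'   each a list of `qp_source` objects (empty for `"single_uniform"`).
#' @export
make_design <- function(scheme = c("contiguous", "interlaced", "single_uniform"),
                        ring_radius = 10, S = 10L, I = 4L,
                        aperture = 25 * pi / 180, mu_a_prime = 1e-3,
                        power = 1) {
  scheme <- match.arg(scheme)
  if (scheme == "single_uniform") {
    return(structure(list(scheme = "single_uniform", illuminations = list(list()),
                          I = 1L, S = 0L, ring_radius = ring_radius,
                          power = power, uniform_flux = 1),
                     class = "qp_design"))
  }
  base <- if (scheme == "contiguous") {
    seq(-pi / 4, pi / 4, length.out = S)
  } else {
    2 * pi * (seq_len(S) - 1L) / S
  }
  alpha <- if (scheme == "contiguous") pi / 2 else pi / 20
  illum <- lapply(seq_len(I), function(i) {
    ang <- base + (i - 1L) * alpha
    lapply(ang, function(a) {
      pos <- ring_radius * c(cos(a), sin(a))
      cone_beam_source(pos, -pos, power = power, aperture = aperture,
                       mu_a_prime = mu_a_prime)
    })
  })
  structure(list(scheme = scheme, illuminations = illum, I = as.integer(I),
                 S = as.integer(S), ring_radius = ring_radius,
                 alpha = alpha, power = power),
            class = "qp_design")
}

#' Nodal boundary flux of one illumination
#'
#' Sums the inward-projected cone-beam fluxes over the sources of
#' illumination `illum_index`,
#' \eqn{q(x) = \sum_i \max(\langle q(x; s_i), \eta(x)\rangle, 0)},
#' evaluated at boundary nodes with their averaged outward normals.
#' Interior nodes are zero.
#'
#' @param design a `qp_design`.
#' @param illum_index illumination number (1-based).
#' @param fem a `qp_fem`.
#' @return nodal field (length N) supported on the boundary.
#' @export
boundary_flux <- function(design, illum_index, fem) {
  stopifnot(illum_index >= 1, illum_index <= design$I)
  N <- fem$n_nodes
  q <- numeric(N)
  bn <- fem$boundary_nodes
  if (design$scheme == "single_uniform") {
    q[bn] <- design$uniform_flux * design$power
    return(q)
  }
  x <- fem$mesh$vertices[bn, , drop = FALSE]
  eta <- fem$boundary_node_normals
  for (src in design$illuminations[[illum_index]]) {
    fl <- cone_beam_flux(x, src)
    q[bn] <- q[bn] + pmax(rowSums(fl * eta), 0)
  }
  q
}

#' Normalize the design power to the ANSI fluence limit
#'
#' Scales the shared source power so that the maximum nodal fluence over
#' the domain, across all illuminations of the design, equals 1 AU at
#' the reference (prior-mean) optical parameters.  Linearity of the
#' diffusion problem in the boundary source makes this a single solve
#' and rescale per illumination.  The idealized uniform scheme is
#' returned unchanged (its boundary flux is 1 AU by definition).
#'
#' @param design a `qp_design`.
#' @param fem a `qp_fem`.
#' @param params reference optical parameters (default: prior mean,
#'   `m1 = m2 = 0`).
#' @return the design with rescaled `power` and the achieved maximum
#'   fluence recorded.
#' @export
normalize_power <- function(design, fem, params = NULL) {
  if (design$scheme == "single_uniform") {
    design$max_fluence <- NA_real_
    return(design)
  }
  if (is.null(params)) params <- optical_parameters(fem)
  sys <- diffusion_system(params, fem)
  peak <- 0
  for (i in seq_len(design$I)) {
    fl <- solve_diffusion(params, boundary_flux(design, i, fem), fem, sys = sys)
    peak <- max(peak, max(fl$phi))
  }
  if (peak <= 0) stop("zero fluence: no active sources", call. = FALSE)
  scale <- 1 / peak
  design$power <- design$power * scale
  design$illuminations <- lapply(design$illuminations, function(srcs)
    lapply(srcs, function(s) { s$power <- s$power * scale; s }))
  design$max_fluence <- 1
  design
}

#' @export
print.qp_design <- function(x, ...) {
  cat(sprintf("qp_design: %s scheme, I = %d illuminations x S = %d sources, ring radius %.3g cm, power %.4g\n",
              x$scheme, x$I, x$S, x$ring_radius, x$power))
  invisible(x)
}
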
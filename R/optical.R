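#' Optical parameter fields
#'
#' Bundles the latent log-deviation fields with the reference optical
#' values.  The absorption and reduced scattering coefficients are the
#' log-Gaussian pushforwards \eqn{\mu_a = \bar\mu_a e^{m_1}} and
#' \eqn{\mu_s' = \bar\mu_s' e^{m_2}}, and the diffusion coefficient is
#' \eqn{D = 1/[3(\mu_a + \mu_s')]}; all are strictly positive by
#' construction.  Products are formed nodally (interpolatory), consistent
#' with first-order elements.
#'
#' @param fem a `qp_fem`.
#' @param m1 nodal log-absorption deviation (scalar or length N; default 0).
#' @param m2 nodal log-scattering deviation (scalar or length N; default 0).
#' @param mu_a_bar reference absorption, cm^-1 (default `exp(-2)`).
#' @param mu_s_bar reference reduced scattering, cm^-1 (default 10).
#' @return an object of class `qp_optical_parameters` with derived nodal
#'   fields `mu_a`, `mu_s`, `D`.
#' @export
optical_parameters <- function(fem, m1 = 0, m2 = 0,
                               mu_a_bar = exp(-2), mu_s_bar = 10) {
  N <- fem$n_nodes
  if (length(m1) == 1L) m1 <- rep(m1, N)
  if (length(m2) == 1L) m2 <- rep(m2, N)
  if (length(m1) != N) stop_dim("m1", N, length(m1))
  if (length(m2) != N) stop_dim("m2", N, length(m2))
  mu_a <- mu_a_bar * exp(m1)
  mu_s <- mu_s_bar * exp(m2)
  structure(list(m1 = m1, m2 = m2, mu_a_bar = mu_a_bar, mu_s_bar = mu_s_bar,
                 mu_a = mu_a, mu_s = mu_s, D = 1 / (3 * (mu_a + mu_s))),
            class = "qp_optical_parameters")
}

## Photoacoustic conversion efficiency (Gruneisen parameter), assumed
## known and spatially constant throughout the package.
GRUNEISEN <- 1

## System matrix of the diffusion problem with Robin boundary factor 1/2
## (matched refractive indices), factorized once per parameter set and
## reused across right-hand sides / illuminations.
diffusion_system <- function(params, fem) {
  if (any(params$mu_a <= 0) || any(params$D <= 0))
    stop("negative optical coefficient field", call. = FALSE)
  S <- assemble_operator(fem, a = params$mu_a, b = params$D, robin = 0.5)
  list(S = S, chol = Matrix::Cholesky(Matrix::forceSymmetric(S), LDL = FALSE))
}

solve_system <- function(sys, rhs) {
  as.numeric(Matrix::solve(sys$chol, rhs, system = "A"))
}

#' Solve the diffusion-approximation fluence problem
#'
#' Finite-element solution of
#' \eqn{\mu_a \phi - \nabla\cdot D \nabla\phi = 0} in the disk with the
#' Robin boundary condition
#' \eqn{\langle D\nabla\phi, \eta\rangle + \phi/2 = 2q} on the rim.  The
#' system is symmetric positive definite and solved by sparse Cholesky
#' factorization.
#'
#' @param params a `qp_optical_parameters`.
#' @param q nodal boundary source field (length N, zero at interior
#'   nodes), in AU.
#' @param fem a `qp_fem`.
#' @param sys optional precomputed factorization from repeated solves
#'   with the same parameters.
#' @return an object of class `qp_fluence` with nodal fields `phi` (AU)
#'   and `h` (absorbed energy density, AU cm^-1).
#' @export
solve_diffusion <- function(params, q, fem, sys = NULL) {
  if (length(q) != fem$n_nodes) stop_dim("boundary source", fem$n_nodes, length(q))
  if (is.null(sys)) sys <- diffusion_system(params, fem)
  rhs <- as.numeric(fem$boundary_mass %*% (2 * q))
  phi <- solve_system(sys, rhs)
  structure(list(phi = phi, q = q, h = GRUNEISEN * params$mu_a * phi),
            class = "qp_fluence")
}

#' Absorbed optical energy density
#'
#' Nodal product \eqn{h = \Gamma\,\mu_a\,\phi} with \eqn{\Gamma \equiv 1}.
#'
#' @param params a `qp_optical_parameters`.
#' @param fluence a `qp_fluence` (or a raw nodal fluence vector).
#' @return nodal absorbed energy density.
#' @export
absorbed_energy <- function(params, fluence) {
  phi <- if (inherits(fluence, "qp_fluence")) fluence$phi else fluence
  if (length(phi) != length(params$mu_a))
    stop_dim("fluence", length(params$mu_a), length(phi))
  GRUNEISEN * params$mu_a * phi
}

#' Radial fluence of the homogeneous-disk Robin problem
#'
#' Closed-form modified-Bessel solution \eqn{\phi(r) = c\,I_0(kr)} with
#' \eqn{k = \sqrt{\mu_a/D}} and
#' \eqn{c = 2q_0 / [D k I_1(kR) + I_0(kR)/2]}, the exact solution of the
#' diffusion problem for constant coefficients and constant boundary
#' source \eqn{q_0}.  Serves as the analytic oracle for the FEM solver.
#'
#' @param r radii at which to evaluate (cm).
#' @param radius domain radius (cm).
#' @param mu_a constant absorption (cm^-1).
#' @param mu_s constant reduced scattering (cm^-1).
#' @param q0 constant boundary source (AU).
#' @return fluence values at `r`.
#' @export
bessel_fluence <- function(r, radius, mu_a, mu_s, q0 = 1) {
  D <- 1 / (3 * (mu_a + mu_s))
  k <- sqrt(mu_a / D)
  cc <- 2 * q0 / (D * k * besselI(k * radius, 1) + 0.5 * besselI(k * radius, 0))
  cc * besselI(k * r, 0)
}
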
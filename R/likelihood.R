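#' Bundle a qPACT measurement model
#'
#' Collects everything the likelihood needs: the FEM discretization, a
#' power-normalized illumination design, the assembled CRT operator, the
#' noise level, and the nuisance mode.  With
#' `known_scattering = TRUE` the reduced scattering coefficient is fixed
#' at its reference value and the inversion parameter is `m1` alone;
#' otherwise `m = (m1, m2)`.
#'
#' @param fem a `qp_fem`.
#' @param design a `qp_design` (normalize with [normalize_power()] first).
#' @param crt a `qp_crt` built on the same mesh.
#' @param sigma2 noise variance per data sample (AU^2).
#' @param mu_a_bar,mu_s_bar reference optical values (cm^-1).
#' @param known_scattering logical nuisance mode.
#' @return an object of class `qp_model`; boundary fluxes per
#'   illumination are precomputed.
#' @export
qpact_model <- function(fem, design, crt, sigma2 = 1e-3,
                        mu_a_bar = exp(-2), mu_s_bar = 10,
                        known_scattering = TRUE) {
  stopifnot(sigma2 > 0, crt$n_nodes == fem$n_nodes)
  q <- lapply(seq_len(design$I), function(i) boundary_flux(design, i, fem))
  structure(list(fem = fem, design = design, crt = crt, sigma2 = sigma2,
                 mu_a_bar = mu_a_bar, mu_s_bar = mu_s_bar,
                 known_scattering = known_scattering, q = q,
                 n_param = fem$n_nodes * (if (known_scattering) 1L else 2L)),
            class = "qp_model")
}

#' Linear-Gaussian surrogate model
#'
#' Replaces the PDE-based forward map by a fixed matrix `G`, giving the
#' exactly solvable model \eqn{y = G m + z}.  Used as the closed-form
#' oracle for the information estimate, the bound assembly, and the MAP
#' solver.
#'
#' @param G forward matrix (K x N).
#' @param sigma2 noise variance.
#' @return an object of class `qp_linear_model`.
#' @export
linear_model <- function(G, sigma2 = 1e-3) {
  structure(list(G = as.matrix(G), sigma2 = sigma2, n_param = ncol(G)),
            class = "qp_linear_model")
}

## split / join the stacked parameter vector; block order is [m1; m2]
model_split_m <- function(model, m) {
  if (is.list(m)) return(m)
  N <- model$fem$n_nodes
  if (model$known_scattering) list(m1 = m) else
    list(m1 = m[seq_len(N)], m2 = m[N + seq_len(N)])
}

model_join_g <- function(model, g1, g2) {
  if (model$known_scattering) g1 else c(g1, g2)
}

## forward PDE solves shared by likelihood, score, and Hessian actions
forward_state <- function(model, m) {
  m <- model_split_m(model, m)
  fem <- model$fem
  params <- optical_parameters(fem, m1 = m$m1,
                               m2 = if (model$known_scattering) 0 else m$m2,
                               mu_a_bar = model$mu_a_bar,
                               mu_s_bar = model$mu_s_bar)
  sys <- diffusion_system(params, fem)
  phi <- lapply(model$q, function(qi)
    solve_diffusion(params, qi, fem, sys = sys)$phi)
  h <- lapply(phi, function(ph) params$mu_a * ph)
  d0 <- lapply(h, function(hi) apply_crt(model$crt, hi))
  list(m = m, params = params, sys = sys, phi = phi, h = h, d0 = d0)
}

#' Simulate noisy measurements
#'
#' For each illumination: solve the diffusion problem, form the absorbed
#' energy, apply the CRT, and add i.i.d. Gaussian noise of variance
#' `sigma2`.  Reproducible per seed; per-illumination noise streams are
#' derived from `(seed, illumination)`.
#'
#' @param m parameter (list with `m1`/`m2`, or a stacked vector; for the
#'   linear surrogate a plain vector).
#' @param model a `qp_model` or `qp_linear_model`.
#' @param seed integer seed; `NULL` or `sigma2 = 0` gives noise-free data.
#' @param sigma2 noise variance override (default: the model's).
#' @return an object of class `qp_measurement`: list `d` of K-vectors
#'   (one per illumination), with `sigma2` and `seed` recorded.
#' @export
simulate_data <- function(m, model, seed = 1L, sigma2 = NULL) {
  sigma2 <- sigma2 %||% model$sigma2
  if (inherits(model, "qp_linear_model")) {
    d0 <- list(as.numeric(model$G %*% m))
  } else {
    d0 <- forward_state(model, m)$d0
  }
  d <- lapply(seq_along(d0), function(i) {
    if (is.null(seed) || sigma2 == 0) return(d0[[i]])
    d0[[i]] + sqrt(sigma2) *
      local_seed(derive_seed(seed, i, 21L), rnorm(length(d0[[i]])))
  })
  structure(list(d = d, sigma2 = sigma2, seed = seed),
            class = "qp_measurement")
}

#' Log-likelihood over all illuminations
#'
#' Returns \eqn{-\tfrac{1}{2}\sum_i \|H_a h_i - d_i\|^2 / \sigma^2}
#' (additive normalization constants dropped).
#'
#' @inheritParams simulate_data
#' @param y a `qp_measurement` (or list of data vectors).
#' @param state optional precomputed [forward_state()].
#' @return scalar log-likelihood (non-positive).
#' @export
log_likelihood <- function(m, y, model, state = NULL) {
  d <- if (inherits(y, "qp_measurement")) y$d else y
  if (inherits(model, "qp_linear_model")) {
    r <- as.numeric(model$G %*% m) - d[[1]]
    return(-0.5 * sum(r^2) / model$sigma2)
  }
  state <- state %||% forward_state(model, m)
  ll <- 0
  for (i in seq_along(d)) ll <- ll - 0.5 * sum((state$d0[[i]] - d[[i]])^2)
  ll / model$sigma2
}

#' Score of the likelihood via the variational adjoint method
#'
#' Computes the gradient of the log-likelihood with respect to the nodal
#' coefficients of the latent fields.  Per illumination, with residual
#' \eqn{r_i = H_a h_i - d_i} and its pullback
#' \eqn{w_i = H_a^T r_i / \sigma^2}, one adjoint problem
#' \eqn{S p_i = \mu_a \circ w_i} is solved with the same (self-adjoint)
#' operator and factorization as the forward problem, and the gradient
#' accumulates the exact discrete derivative of the residual functional
#' through both the absorbed-energy product and the
#' parameter-dependent system matrix:
#' \deqn{g_1 \mathrel{+}= \mu_a \circ (-w_i \circ \phi_i + T(p_i,\phi_i))
#'   - 3 D^2 \circ \mu_a \circ W(p_i,\phi_i), \quad
#'   g_2 \mathrel{+}= -3 D^2 \circ \mu_s \circ W(p_i,\phi_i),}
#' where `T` and `W` are the trilinear reaction and diffusion assembly
#' derivatives.  Correctness is pinned by a central finite-difference
#' contract (see [fd_directional_check()]).
#'
#' @inheritParams log_likelihood
#' @return an object of class `qp_score`: stacked gradient `g`, blocks
#'   `g1`/`g2`, and the per-illumination gradients.
#' @export
score <- function(m, y, model, state = NULL) {
  d <- if (inherits(y, "qp_measurement")) y$d else y
  if (inherits(model, "qp_linear_model")) {
    r <- as.numeric(model$G %*% m) - d[[1]]
    g <- -as.numeric(crossprod(model$G, r)) / model$sigma2
    return(structure(list(g = g, g1 = g, g2 = NULL, per_illum = list(g)),
                     class = "qp_score"))
  }
  state <- state %||% forward_state(model, m)
  fem <- model$fem
  pa <- state$params
  dfac <- -3 * pa$D^2
  N <- fem$n_nodes
  g1 <- numeric(N)
  g2 <- if (model$known_scattering) NULL else numeric(N)
  per <- vector("list", length(d))
  for (i in seq_along(d)) {
    r <- state$d0[[i]] - d[[i]]
    w <- apply_crt(model$crt, r, adjoint = TRUE) / model$sigma2
    p <- solve_system(state$sys, pa$mu_a * w)
    Tv <- mass_trilinear_vec(fem, p, state$phi[[i]])
    Wv <- stiff_trilinear_vec(fem, p, state$phi[[i]])
    gi1 <- pa$mu_a * (-w * state$phi[[i]] + Tv) + dfac * pa$mu_a * Wv
    gi2 <- if (model$known_scattering) NULL else dfac * pa$mu_s * Wv
    per[[i]] <- list(g1 = gi1, g2 = gi2)
    g1 <- g1 + gi1
    if (!model$known_scattering) g2 <- g2 + gi2
  }
  structure(list(g = model_join_g(model, g1, g2), g1 = g1, g2 = g2,
                 per_illum = per),
            class = "qp_score")
}

#' Central finite-difference check of a directional derivative
#'
#' Compares \eqn{\langle g, v\rangle} with the central difference of the
#' log-likelihood along `v`.  This is the correctness contract for the
#' adjoint score.
#'
#' @param m stacked parameter vector.
#' @param y measurement.
#' @param model a `qp_model` or `qp_linear_model`.
#' @param v direction (stacked).
#' @param step finite-difference step.
#' @return list with the adjoint directional derivative `ad`, the
#'   finite-difference value `fd`, and their relative discrepancy.
#' @export
fd_directional_check <- function(m, y, model, v, step = 1e-5) {
  g <- score(m, y, model)$g
  ad <- sum(g * v)
  fp <- log_likelihood(m + step * v, y, model)
  fm <- log_likelihood(m - step * v, y, model)
  fd <- (fp - fm) / (2 * step)
  list(ad = ad, fd = fd, rel = abs(ad - fd) / max(abs(ad), .Machine$double.eps))
}
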
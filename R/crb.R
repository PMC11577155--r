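#' Monte Carlo estimate of the data term of the Bayesian information
#'
#' Draws i.i.d. samples from the joint distribution — a prior draw of
#' the latent fields followed by a simulated measurement — evaluates the
#' adjoint score of the likelihood at each sample, and averages the
#' score outer products:
#' \deqn{\hat J_D = \frac{1}{N_s}\sum_{i=1}^{N_s} \nabla_m \log p(y_i|m_i)\,
#'   \nabla_m \log p(y_i|m_i)^T.}
#' Sample `i` uses seeds derived from `(seed, i)`, so the estimate is
#' reproducible and samples are independent of `N_s`.
#'
#' @param model a `qp_model` or `qp_linear_model`.
#' @param prior a `qp_joint_prior` (blocks matching the model's nuisance
#'   mode) or, for the linear surrogate, a `qp_dense_prior`.
#' @param N_s number of Monte Carlo samples.
#' @param seed integer base seed.
#' @return list with the `n x n` matrix `J_D`, the `n x N_s` matrix of
#'   scores (kept for half-sample diagnostics), and bookkeeping.
#' @export
estimate_JD <- function(model, prior, N_s, seed = 1L) {
  stopifnot(N_s >= 1)
  n <- model$n_param
  scores <- matrix(0, n, N_s)
  for (i in seq_len(N_s)) {
    mi <- joint_draw(model, prior, derive_seed(seed, i, 31L))
    yi <- simulate_data(mi, model, seed = derive_seed(seed, i, 32L))
    sc <- tryCatch(score(mi, yi, model),
                   error = function(e) stop("score failed at sample ", i, ": ",
                                            conditionMessage(e), call. = FALSE))
    scores[, i] <- sc$g
  }
  J_D <- tcrossprod(scores) / N_s
  J_D <- (J_D + t(J_D)) / 2
  list(J_D = J_D, scores = scores, N_s = N_s, seed = seed)
}

joint_draw <- function(model, prior, seed) {
  if (inherits(model, "qp_linear_model")) {
    return(sample_dense_prior(prior, seed))
  }
  s <- draw_prior_sample(as_joint(prior), seed)
  if (model$known_scattering) s$m1 else c(s$m1, s$m2)
}

as_joint <- function(prior) {
  if (inherits(prior, "qp_prior")) joint_prior(prior) else prior
}

#' Dense Gaussian prior for the linear surrogate
#' @param C covariance matrix.
#' @return object of class `qp_dense_prior` with cached factorizations.
#' @export
dense_gaussian_prior <- function(C) {
  C <- as.matrix(C)
  R <- chol(C)
  structure(list(C = C, R = R, Cinv = chol2inv(R)), class = "qp_dense_prior")
}

sample_dense_prior <- function(prior, seed) {
  w <- local_seed(seed, rnorm(nrow(prior$C)))
  as.numeric(crossprod(prior$R, w))
}

#' Assemble the Bayesian information and Cramér–Rao bound
#'
#' Forms \eqn{\hat J_m = C^{-1} + \hat J_D} with the block-diagonal
#' prior precision (each block the dense \eqn{A M^{-1} A}), inverts it
#' by Cholesky — \eqn{\hat J_m} is the sum of an SPD and a PSD matrix,
#' so a factorization failure signals an upstream bug and is not
#' regularized away — and extracts the marginal `m1` block
#' (post-marginalization of the nuisance block).  The bound is then
#' transported to the absorption coefficient by the change-of-variable
#' congruence \eqn{\hat V_{\mu_a} = \hat C^T \hat V_{m_1} \hat C}.
#'
#' @param JD result of [estimate_JD()] (or a bare matrix).
#' @param prior `qp_joint_prior` / `qp_prior` (or `qp_dense_prior` for
#'   the linear surrogate).
#' @param fem the `qp_fem` (used for the mass-weighted traces).
#' @param mu_a_bar reference absorption for the change of variable.
#' @param cov_mode `"monte_carlo"` (default, the general route) or
#'   `"closed_form"` (lognormal moment formula from the nodal marginal
#'   variances).
#' @param cov_N_s Monte Carlo samples for the change-of-variable matrix.
#' @param seed seed for the change-of-variable sampling.
#' @return an object of class `qp_bound` with the information/bound
#'   matrices, the marginal and transformed blocks, pointwise bound
#'   maps, and mass-weighted trace metrics `tr_m1`, `tr_mua`.
#' @export
assemble_bound <- function(JD, prior, fem, mu_a_bar = exp(-2),
                           cov_mode = c("monte_carlo", "closed_form"),
                           cov_N_s = 5000L, seed = 1L) {
  cov_mode <- match.arg(cov_mode)
  J_D <- if (is.list(JD)) JD$J_D else JD
  if (max(abs(J_D - t(J_D))) > 1e-8 * max(abs(J_D)))
    stop("J_D must be symmetric", call. = FALSE)

  if (inherits(prior, "qp_dense_prior")) {
    J_m <- prior$Cinv + J_D
    V_m <- chol2inv(chol(J_m))
    return(structure(list(J_D = J_D, J_m = J_m, V_m = V_m, V_m1 = V_m,
                          pointwise_m1 = diag(V_m)),
                     class = "qp_bound"))
  }

  jp <- as_joint(prior)
  N1 <- jp$m1$fem$n_nodes
  C1inv <- dense_precision(jp$m1)
  n <- nrow(J_D)
  if (n == N1) {
    Cinv <- C1inv
  } else {
    C2inv <- dense_precision(jp$m2)
    stopifnot(n == N1 + nrow(C2inv))
    Cinv <- matrix(0, n, n)
    Cinv[seq_len(N1), seq_len(N1)] <- C1inv
    Cinv[(N1 + 1):n, (N1 + 1):n] <- C2inv
  }
  J_m <- Cinv + J_D
  V_m <- chol2inv(chol(J_m))
  V_m1 <- V_m[seq_len(N1), seq_len(N1), drop = FALSE]

  cv <- change_of_variable(V_m1, jp$m1, mode = cov_mode, N_s = cov_N_s,
                           seed = seed, mu_a_bar = mu_a_bar)
  M1 <- jp$m1$fem$mass_matrix
  structure(
    list(J_D = J_D, J_m = J_m, V_m = V_m, V_m1 = V_m1,
         C_hat = cv$C_hat, V_mua = cv$V_mua,
         pointwise_m1 = diag(V_m1), pointwise_mua = diag(cv$V_mua),
         tr_m1 = weighted_trace(M1, V_m1),
         tr_mua = weighted_trace(M1, cv$V_mua),
         cov_mode = cov_mode, seed = seed,
         scores = if (is.list(JD)) JD$scores else NULL,
         N_s = if (is.list(JD)) JD$N_s else NULL),
    class = "qp_bound")
}

## dense prior precision A M^-1 A for one block
dense_precision <- function(prior) {
  X <- as.matrix(Matrix::solve(prior$fem$mass_matrix, prior$A_matrix))
  P <- as.matrix(prior$A_matrix %*% X)
  (P + t(P)) / 2
}

#' Mass-weighted trace \eqn{tr_M(X) = tr(M X)}
#' @param M sparse mass matrix.
#' @param X dense matrix of matching dimension.
#' @return scalar.
#' @export
weighted_trace <- function(M, X) {
  Tm <- as(M, "TsparseMatrix")
  sum(Tm@x * X[cbind(Tm@i + 1L, Tm@j + 1L)])
}

#' Change-of-variable transport of the bound to the absorption coefficient
#'
#' The diagonal Jacobian-expectation matrix has entries
#' \eqn{E[\bar\mu_a e^{m_{1,i}}]}: in closed form
#' \eqn{\bar\mu_a \exp(v_i/2)} with \eqn{v_i} the nodal marginal prior
#' variances (lognormal moment formula), or by Monte Carlo averaging of
#' \eqn{\bar\mu_a e^{m_1}} over prior draws.
#'
#' @param V_m1 marginal bound block for `m1`.
#' @param prior the calibrated `qp_prior` for `m1`.
#' @param mode `"closed_form"` or `"monte_carlo"`.
#' @param N_s Monte Carlo sample count.
#' @param seed sampling seed.
#' @param mu_a_bar reference absorption.
#' @return list with the diagonal entries `C_hat` and the transformed
#'   bound `V_mua`.
#' @export
change_of_variable <- function(V_m1, prior, mode = c("monte_carlo", "closed_form"),
                               N_s = 5000L, seed = 1L, mu_a_bar = exp(-2)) {
  mode <- match.arg(mode)
  if (mode == "closed_form") {
    v <- pointwise_variance(prior)
    ch <- mu_a_bar * exp(v / 2)
  } else {
    ex <- mass_noise_factor(prior$fem)
    acc <- numeric(prior$fem$n_nodes)
    for (i in seq_len(N_s)) {
      m1 <- draw_field(prior, derive_seed(seed, i, 41L), ex)
      acc <- acc + exp(m1)
    }
    ch <- mu_a_bar * acc / N_s
  }
  V_mua <- V_m1 * tcrossprod(ch)   # diag(ch) %*% V %*% diag(ch)
  list(C_hat = ch, V_mua = V_mua)
}

#' Scalar design metrics of an assembled bound
#'
#' Reports the A-optimal style mass-weighted traces
#' \eqn{tr_M(\hat V_{m_1})} and \eqn{tr_M(\hat V_{\mu_a})} (the design
#' metric the schemes are ranked by) together with the pointwise bound
#' maps.
#'
#' @param bound a `qp_bound`.
#' @return list with `tr_m1`, `tr_mua`, and the pointwise maps.
#' @export
design_metric <- function(bound) {
  list(tr_m1 = bound$tr_m1, tr_mua = bound$tr_mua,
       pointwise_m1 = bound$pointwise_m1, pointwise_mua = bound$pointwise_mua)
}

#' Half-sample stability interval of the design metric
#'
#' Recomputes the bound metric from the two disjoint halves of the
#' stored Monte Carlo scores; the spread is the Monte Carlo error bar
#' used when declaring design rankings.
#'
#' @param JD result of [estimate_JD()] (with scores).
#' @param prior,fem,mu_a_bar,cov_mode,cov_N_s,seed as in
#'   [assemble_bound()].
#' @return list with the two half estimates and the interval
#'   `c(lo, hi)` for `tr_mua`.
#' @export
half_sample_metrics <- function(JD, prior, fem, mu_a_bar = exp(-2),
                                cov_mode = "closed_form", cov_N_s = 2000L,
                                seed = 1L) {
  S <- JD$scores
  N_s <- ncol(S)
  halves <- list(seq(1L, N_s, by = 2L), seq(2L, N_s, by = 2L))
  tr <- vapply(halves, function(idx) {
    Jh <- tcrossprod(S[, idx, drop = FALSE]) / length(idx)
    b <- assemble_bound(list(J_D = (Jh + t(Jh)) / 2), prior, fem,
                        mu_a_bar = mu_a_bar, cov_mode = cov_mode,
                        cov_N_s = cov_N_s, seed = seed)
    b$tr_mua
  }, numeric(1))
  list(halves = tr, interval = range(tr))
}

#' @export
print.qp_bound <- function(x, ...) {
  cat("qp_bound: Bayesian Cramér–Rao bound estimate\n")
  if (!is.null(x$tr_m1))
    cat(sprintf("  tr_M(V_m1)  = %.6g\n  tr_M(V_mua) = %.6g\n",
                x$tr_m1, x$tr_mua))
  invisible(x)
}
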
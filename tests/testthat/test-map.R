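test_that("MAP on the linear surrogate equals the closed-form posterior mean", {
  lg <- lg_setup()
  m_true <- qpactoed:::sample_dense_prior(lg$prior, 9)
  y <- simulate_data(m_true, lg$model, seed = 11)
  fit <- map_estimate(y, lg$model, lg$prior,
                      config = map_solver_config(grad_rtol = 1e-10))
  Vexact <- solve(solve(lg$C) + crossprod(lg$G) / lg$sigma2)
  m_exact <- as.numeric(Vexact %*% crossprod(lg$G, y$d[[1]])) / lg$sigma2
  expect_equal(fit$m, m_exact, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("the optimizer gradient matches finite differences of the full objective", {
  model <- coarse_model("contiguous")
  jp <- coarse_joint_prior()
  m <- qpactoed:::joint_draw(model, jp, 21)
  y <- simulate_data(m, model, seed = 22)
  g <- qpactoed:::map_gradient(m, y, model, jp)
  v <- unit_direction(model$n_param, 23)
  step <- 1e-5
  fp <- qpactoed:::map_objective(m + step * v, y, model, jp)$obj
  fm <- qpactoed:::map_objective(m - step * v, y, model, jp)$obj
  expect_equal(sum(g * v), (fp - fm) / (2 * step), tolerance = 1e-5)
})

test_that("Gauss-Newton Hessian actions are symmetric and positive", {
  model <- coarse_model("contiguous")
  jp <- coarse_joint_prior()
  m <- qpactoed:::joint_draw(model, jp, 24)
  state <- qpactoed:::forward_state(model, m)
  u <- unit_direction(model$n_param, 25)
  v <- unit_direction(model$n_param, 26)
  Hu <- qpactoed:::gn_hessian_apply(model, jp, state, u)
  Hv <- qpactoed:::gn_hessian_apply(model, jp, state, v)
  expect_equal(sum(v * Hu), sum(u * Hv), tolerance = 1e-10)
  expect_gt(sum(u * Hu), 0)
})

test_that("objective decreases monotonically and descent holds from the truth", {
  model <- coarse_model("contiguous")
  jp <- coarse_joint_prior()
  m_true <- qpactoed:::joint_draw(model, jp, 27)
  y0 <- simulate_data(m_true, model, seed = NULL)  # noise-free
  fit <- map_estimate(y0, model, jp, m0 = m_true)
  expect_true(all(diff(fit$objective) <= 1e-10))
  expect_lte(fit$objective[length(fit$objective)], fit$objective[1])
  y <- simulate_data(m_true, model, seed = 28)
  fit2 <- map_estimate(y, model, jp)
  expect_true(all(diff(fit2$objective) <= 1e-10))
  expect_true(fit2$converged)
})

test_that("reconstruction is most accurate near the boundary and recovers at high SNR", {
  ## coarse single-illumination setting (study-1 layout)
  fem <- coarse_fem()
  design <- make_design("single_uniform")
  model <- qpact_model(fem, design, coarse_crt(), known_scattering = TRUE)
  jp <- coarse_joint_prior()
  r <- sqrt(rowSums(fem$mesh$vertices^2))
  band <- r >= 4; center <- r <= 2.5
  se <- numeric(fem$n_nodes)
  n_trials <- 8
  for (t in seq_len(n_trials)) {
    m_true <- qpactoed:::joint_draw(model, jp, 400 + t)
    y <- simulate_data(m_true, model, seed = 500 + t)
    fit <- map_estimate(y, model, jp, config = map_solver_config(max_iter = 60L))
    se <- se + (fit$m - m_true)^2
  }
  expect_lt(mean(se[band]), mean(se[center]))
  ## near-noiseless recovery in the boundary band
  mlow <- qpact_model(fem, design, coarse_crt(), sigma2 = 1e-6,
                      known_scattering = TRUE)
  m_true <- qpactoed:::joint_draw(mlow, jp, 1)
  y <- simulate_data(m_true, mlow, seed = 2)
  ## the near-noiseless problem is much stiffer: allow a longer Newton run
  fit <- map_estimate(y, mlow, jp, config = map_solver_config(max_iter = 80L))
  rel <- sqrt(sum((fit$m - m_true)[band]^2) / sum(m_true[band]^2))
  expect_lt(rel, 0.2)
})

test_that("in the no-information limit the MAP collapses to the prior mean", {
  fem <- coarse_fem()
  jp <- coarse_joint_prior()
  model <- qpact_model(fem, make_design("single_uniform"), coarse_crt(),
                       sigma2 = 1e6, known_scattering = TRUE)
  m_true <- qpactoed:::joint_draw(model, jp, 3)
  y <- simulate_data(m_true, model, seed = 4)
  fit <- map_estimate(y, model, jp)
  ## the estimate is essentially zero, so the error is the prior draw itself
  expect_lt(max(abs(fit$m)), 0.05 * max(abs(m_true)))
  err_m <- sum((fit$m - m_true) * as.numeric(fem$mass_matrix %*% (fit$m - m_true)))
  prior_ms <- sum(m_true * as.numeric(fem$mass_matrix %*% m_true))
  expect_equal(err_m, prior_ms, tolerance = 0.1)
})

test_that("expected_mse aggregates trials and stays above the matched bound", {
  model <- coarse_model("contiguous")
  jp <- coarse_joint_prior()
  fem <- coarse_fem()
  mse <- expected_mse(model, jp, n_trials = 10L, seed = 6)
  expect_equal(mse$n_trials, 10L)
  expect_true(all(mse$pointwise_m1 >= 0))
  expect_true(all(mse$pointwise_mua >= 0))
  ## integrated values are consistent with the pointwise fields in scale
  expect_gt(mse$tr_m1, 0)
  jd <- estimate_JD(model, jp, N_s = 60L, seed = 7)
  b <- assemble_bound(jd, jp, fem, cov_mode = "closed_form")
  expect_gte(mse$tr_m1, b$tr_m1 * 0.95)
})
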
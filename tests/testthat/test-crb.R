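test_that("the information estimate converges to the linear-Gaussian closed form", {
  lg <- lg_setup()
  Jexact <- crossprod(lg$G) / lg$sigma2
  jd <- estimate_JD(lg$model, lg$prior, N_s = 10000L, seed = 5)
  expect_lt(norm(jd$J_D - Jexact, "F") / norm(Jexact, "F"), 3 / sqrt(10000))
  ## a single sample gives a rank-1 PSD matrix
  jd1 <- estimate_JD(lg$model, lg$prior, N_s = 1L, seed = 5)
  expect_equal(qr(jd1$J_D)$rank, 1)
  expect_true(all(eigen(jd1$J_D, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
})

test_that("bound assembly inverts the information exactly in the linear-Gaussian case", {
  lg <- lg_setup()
  Jexact <- crossprod(lg$G) / lg$sigma2
  b <- assemble_bound(list(J_D = Jexact), lg$prior, fem = NULL)
  Vexact <- solve(solve(lg$C) + Jexact)
  expect_equal(b$V_m, Vexact, tolerance = 1e-8)
})

test_that("with no data the bound collapses to the prior covariance", {
  fem <- coarse_fem()
  jp <- coarse_joint_prior()
  n <- fem$n_nodes
  b <- assemble_bound(list(J_D = matrix(0, n, n)), jp, fem,
                      cov_mode = "closed_form")
  ## tr_M of the prior covariance is the integrated prior variance,
  ## ~ 0.2 * 25 pi up to the documented non-uniformity of the calibrated
  ## variance field (max/min <= 1.3)
  expect_equal(b$tr_m1, 0.2 * 25 * pi, tolerance = 0.12)
  ## and for mu_a, the integrated lognormal variance
  expect_equal(b$tr_mua, exp(-4) * exp(0.2) * (exp(0.2) - 1) * 25 * pi,
               tolerance = 0.2)
  ## marginal block extraction is plain block indexing
  expect_identical(b$V_m1, b$V_m[seq_len(n), seq_len(n)])
})

test_that("change of variable matches the lognormal closed form", {
  pr <- coarse_prior1()
  n <- pr$fem$n_nodes
  V <- diag(n)
  cf <- change_of_variable(V, pr, mode = "closed_form")
  ## center node: mu_a_bar * exp(var/2) = e^{-2} e^{0.1}
  expect_equal(cf$C_hat[pr$center_node], exp(-2) * exp(0.1), tolerance = 0.005)
  mc <- change_of_variable(V, pr, mode = "monte_carlo", N_s = 3000L, seed = 2)
  ## lognormal mean MC error: sd = mu sqrt(e^v - 1) / sqrt(N_s)
  se <- cf$C_hat * sqrt(exp(0.22) - 1) / sqrt(3000)
  expect_true(all(abs(mc$C_hat - cf$C_hat) <= 4 * se))
  ## near-degenerate prior: C_hat -> mu_a_bar identity
  mesh <- build_disk_mesh(5, 1.2, 1.2, seed = 2)
  prz <- calibrate_prior(assemble_fem(mesh), 1e-4, 5)
  cfz <- change_of_variable(diag(prz$fem$n_nodes), prz, mode = "closed_form")
  expect_equal(cfz$C_hat, rep(exp(-2), prz$fem$n_nodes), tolerance = 1e-3)
})

test_that("the design metric is invariant under node reordering", {
  fem <- coarse_fem()
  n <- fem$n_nodes
  V <- qpactoed:::local_seed(6, crossprod(matrix(rnorm(n * n), n, n))) / n
  perm <- qpactoed:::local_seed(7, sample.int(n))
  t1 <- weighted_trace(fem$mass_matrix, V)
  t2 <- weighted_trace(fem$mass_matrix[perm, perm], V[perm, perm])
  expect_equal(t1, t2, tolerance = 1e-10)
})

test_that("information decreases with noise and data never hurt the bound", {
  model <- coarse_model("contiguous")
  jp <- coarse_joint_prior()
  fem <- coarse_fem()
  trs <- vapply(c(1e-3, 1e-1, 10), function(s2) {
    m2 <- model; m2$sigma2 <- s2
    sum(diag(estimate_JD(m2, jp, N_s = 25L, seed = 4)$J_D))
  }, numeric(1))
  expect_true(all(diff(trs) < 0))
  ## adding the data term can only shrink the mass-weighted trace
  jd <- estimate_JD(model, jp, N_s = 40L, seed = 8)
  b <- assemble_bound(jd, jp, fem, cov_mode = "closed_form")
  b0 <- assemble_bound(list(J_D = 0 * jd$J_D), jp, fem, cov_mode = "closed_form")
  expect_lt(b$tr_m1, b0$tr_m1)
  expect_lt(b$tr_mua, b0$tr_mua)
  ## the bound matrices are SPD with strictly positive metrics
  ev <- eigen(b$V_m, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_gt(b$tr_mua, 0)
  ## non-symmetric input is rejected
  Jbad <- jd$J_D; Jbad[1, 2] <- Jbad[1, 2] + 1
  expect_error(assemble_bound(list(J_D = Jbad), jp, fem), "symmetric")
})
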
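test_that("cone-beam flux evaluates the attenuated monopole beam", {
  src <- cone_beam_source(position = c(10, 0), direction = c(-1, 0),
                          power = 1, mu_a_prime = 1e-3)
  ## on-axis point at distance 5: |q| = e^{-0.005} / (100 pi)
  fl <- cone_beam_flux(c(5, 0), src)
  expect_equal(sqrt(sum(fl^2)), exp(-0.005) / (100 * pi), tolerance = 1e-12)
  ## flux points along the ray (s - x direction)
  expect_gt(fl[1], 0)
  expect_equal(fl[2], 0)
})

test_that("the beam cuts off at the aperture and decays with angle", {
  beta <- 25 * pi / 180
  src <- cone_beam_source(c(10, 0), c(-1, 0), aperture = beta)
  ## points on a circle of radius 5 about the source, at angles theta
  pt <- function(th) c(10, 0) + 5 * c(-cos(th), sin(th))
  mag <- function(th) sqrt(sum(cone_beam_flux(pt(th), src)^2))
  expect_equal(mag(beta / 2 + 1e-3), 0)
  expect_gt(mag(0), mag(beta / 2 - 1e-3))
  expect_gt(mag(beta / 4), mag(beta / 2 - 1e-3))
})

test_that("boundary flux is geometrically shadowed and rotation-equivariant", {
  fem <- coarse_fem()
  d <- make_design("contiguous", I = 4L)
  ## single source at (10, 0): positive only on the facing arc
  d1 <- d; d1$illuminations <- list(list(cone_beam_source(c(10, 0), c(-1, 0)))); d1$I <- 1L
  q <- boundary_flux(d1, 1, fem)
  x <- fem$mesh$vertices
  expect_true(all(q[x[, 1] < 0] == 0))
  expect_gt(max(q), 0)
  interior <- setdiff(seq_len(fem$n_nodes), fem$boundary_nodes)
  expect_true(all(q[interior] == 0))
  ## rotating sources by pi/2 maps the flux pattern onto rotated nodes:
  ## compare total inward flux, a rotation invariant
  q2 <- boundary_flux(d, 2, fem)
  q1 <- boundary_flux(d, 1, fem)
  expect_equal(sum(as.numeric(fem$boundary_mass %*% q1)),
               sum(as.numeric(fem$boundary_mass %*% q2)), tolerance = 0.02)
})

test_that("design schemes realize the prescribed source layouts", {
  dc <- make_design("contiguous", S = 10L, I = 4L)
  ang <- function(srcs) sort(vapply(srcs, function(s) atan2(s$position[2], s$position[1]), numeric(1)))
  a1 <- ang(dc$illuminations[[1]])
  a2 <- ang(dc$illuminations[[2]])
  expect_equal(sort((a1 + pi / 2) %% (2 * pi)), sort(a2 %% (2 * pi)), tolerance = 1e-12)
  ## interlaced: union of all 4 illuminations = 40 distinct uniform angles
  di <- make_design("interlaced", S = 10L, I = 4L)
  all_ang <- sort(unlist(lapply(di$illuminations, function(il)
    vapply(il, function(s) atan2(s$position[2], s$position[1]) %% (2 * pi), numeric(1)))))
  expect_equal(length(unique(round(all_ang, 10))), 40)
  expect_equal(diff(all_ang), rep(2 * pi / 40, 39), tolerance = 1e-10)
  ## all sources point at the center
  for (s in dc$illuminations[[1]]) {
    expect_equal(s$direction, -s$position / sqrt(sum(s$position^2)), tolerance = 1e-12)
  }
  expect_error(make_design("spiral"), "arg")
})

test_that("contiguous scheme covers every boundary node across its four illuminations", {
  fem <- coarse_fem()
  d <- make_design("contiguous")
  qtot <- Reduce(`+`, lapply(1:4, function(i) boundary_flux(d, i, fem)))
  expect_true(all(qtot[fem$boundary_nodes] > 0))
  ## every single illumination carries positive total inward flux
  for (i in 1:4)
    expect_gt(sum(as.numeric(fem$boundary_mass %*% boundary_flux(d, i, fem))), 0)
})

test_that("power normalization pins the peak fluence at the safety limit", {
  fem <- coarse_fem()
  for (scheme in c("contiguous", "interlaced")) {
    d <- normalize_power(make_design(scheme), fem)
    pars <- optical_parameters(fem)
    sys <- qpactoed:::diffusion_system(pars, fem)
    peak <- max(vapply(1:4, function(i)
      max(solve_diffusion(pars, boundary_flux(d, i, fem), fem, sys = sys)$phi),
      numeric(1)))
    expect_equal(peak, 1, tolerance = 1e-6)
    ## scale invariance: doubling the initial power changes nothing
    d2 <- normalize_power(make_design(scheme, power = 2), fem)
    expect_equal(d2$power, d$power, tolerance = 1e-12)
  }
  ## the idealized uniform design is returned unchanged
  du <- make_design("single_uniform")
  expect_identical(normalize_power(du, fem)$power, du$power)
})

test_that("interlaced superimposed fluence exceeds contiguous in domain integral", {
  fem <- coarse_fem()
  pars <- optical_parameters(fem)
  sys <- qpactoed:::diffusion_system(pars, fem)
  total_fluence <- function(scheme) {
    d <- normalize_power(make_design(scheme), fem)
    sum(vapply(1:4, function(i)
      integrate_field(solve_diffusion(pars, boundary_flux(d, i, fem), fem,
                                      sys = sys)$phi, fem), numeric(1)))
  }
  expect_gt(total_fluence("interlaced"), total_fluence("contiguous"))
})
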
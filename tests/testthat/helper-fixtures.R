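## Shared fixtures, built once per test run and cached.
##
## Scales used throughout the suite:
##   coarse: uniform 0.8 cm mesh (~130 nodes), 32 transducers x 32 times --
##     fast enough for adjoint/FD and Monte Carlo property tests;
##   desk:   the package's desk preset (0.4 cm mesh, 60 x 64 data grid);
##   study:  the full imaging discretization (graded 0.08..0.15 cm mesh),
##     used only where a check is about that resolution.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(builder)
  .fix[[name]]
}

coarse_mesh <- function() fixture("coarse_mesh", build_disk_mesh(5, 0.8, 0.8, seed = 3))
coarse_fem <- function() fixture("coarse_fem", assemble_fem(coarse_mesh()))
coarse_prior1 <- function() fixture("coarse_prior1", calibrate_prior(coarse_fem(), 0.2, 5))
coarse_prior2 <- function() fixture("coarse_prior2", calibrate_prior(coarse_fem(), 0.05, 5))

coarse_geom <- function() fixture("coarse_geom",
  acoustic_geometry(n_transducers = 32L, n_times = 32L, dt = 11.7e-7))
coarse_crt <- function() fixture("coarse_crt", build_crt(coarse_mesh(), coarse_geom()))

coarse_model <- function(scheme = "contiguous", known_scattering = TRUE) {
  key <- paste0("model_", scheme, "_", known_scattering)
  fixture(key, {
    design <- normalize_power(make_design(scheme), coarse_fem())
    qpact_model(coarse_fem(), design, coarse_crt(),
                known_scattering = known_scattering)
  })
}

coarse_joint_prior <- function(known_scattering = TRUE) {
  if (known_scattering) joint_prior(coarse_prior1())
  else joint_prior(coarse_prior1(), coarse_prior2())
}

study_mesh <- function() fixture("study_mesh", build_disk_mesh(5, 0.08, 0.15, seed = 1))
study_fem <- function() fixture("study_fem", assemble_fem(study_mesh()))
study_prior1 <- function() fixture("study_prior1", calibrate_prior(study_fem(), 0.2, 5))

## micro study-2 configuration used for the information-inequality and
## monotonicity checks (MAP solves are the expensive stage)
micro_config <- function(study = 2L, ...) {
  study_config(study, "desk", h_boundary = 0.8, h_center = 0.8,
               n_transducers = 32L, n_times = 32L, dt = 11.7e-7, ...)
}

## linear-Gaussian surrogate with a decaying forward spectrum (the
## closed-form oracle problem)
lg_setup <- function() {
  fixture("lg_setup", {
    n <- 8L; K <- 12L
    G <- qpactoed:::local_seed(42, matrix(rnorm(K * n), K, n)) %*% diag(0.6^(0:(n - 1)))
    A <- qpactoed:::local_seed(43, matrix(rnorm(n * n), n, n))
    C <- crossprod(A) / n + diag(n) * 0.5
    list(model = linear_model(G, sigma2 = 0.05), prior = dense_gaussian_prior(C),
         G = G, C = C, sigma2 = 0.05)
  })
}

## deterministic unit direction
unit_direction <- function(n, seed) {
  v <- qpactoed:::local_seed(seed, rnorm(n))
  v / sqrt(sum(v^2))
}

mass_l2 <- function(e, fem) sqrt(sum(e * as.numeric(fem$mass_matrix %*% e)))
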
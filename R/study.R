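#' Declarative configuration of the numerical studies
#'
#' Three study presets: study 1 validates the bound against the MAP
#' reconstruction error with a single uniform illumination and known
#' scattering; study 2 ranks the contiguous vs. interlaced cone-beam
#' schemes with known scattering; study 3 repeats the ranking with the
#' reduced scattering coefficient as an unknown nuisance field (prior
#' variance 0.05, correlation length 5 cm).  The `"full"` scale uses
#' the full imaging geometry (graded mesh with element diameter 0.08 cm
#' at the rim to 0.15 cm at the center, 360 transducers, 184 time
#' samples, 5000 bound samples, 10000 MAP trials) — a workstation-scale
#' computation.  The `"desk"` scale is a reduced preset (uniform 0.4 cm
#' mesh, 60 transducers, 64 time samples spanning the same arc radii,
#' 200 bound samples, 100 MAP trials) that exercises every stage in
#' minutes.
#'
#' @param study 1, 2 or 3.
#' @param scale `"desk"` or `"full"`.
#' @param ... field overrides.
#' @return a `qp_study_config` list.
#' @export
study_config <- function(study = 1L, scale = c("desk", "full"), ...) {
  scale <- match.arg(scale)
  full <- scale == "full"
  cfg <- list(
    study = as.integer(study), scale = scale,
    radius = 5, h_boundary = if (full) 0.08 else 0.4,
    h_center = if (full) 0.15 else 0.4, mesh_seed = 1L,
    n_transducers = if (full) 360L else 60L,
    transducer_radius = 6,
    n_times = if (full) 184L else 64L,
    dt = if (full) 2e-7 else 5.84e-7,
    c0 = 1.5e5, sigma2 = 1e-3,
    mu_a_bar = exp(-2), mu_s_bar = 10,
    prior_variance_m1 = 0.2, prior_variance_m2 = 0.05,
    corr_length = 5,
    source_ring_radius = 10, S = 10L, I = 4L,
    aperture = 25 * pi / 180, mu_a_prime = 1e-3,
    N_s = if (full) 5000L else 200L,
    cov_N_s = if (full) 5000L else 1000L,
    n_trials = if (full) 10000L else 100L,
    schemes = if (study == 1) "single_uniform" else c("contiguous", "interlaced"),
    known_scattering = study != 3)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "qp_study_config")
}

#' Read a study configuration from a YAML file
#' @param file path to a YAML file of [study_config()] fields.
#' @return a `qp_study_config`.
#' @export
study_config_from_yaml <- function(file) {
  vals <- yaml::read_yaml(file)
  do.call(study_config, vals)
}

#' Materialize the objects of a study configuration
#'
#' Builds the mesh, FEM structures, calibrated priors, acoustic
#' geometry, CRT operator, and one power-normalized model per design
#' scheme.
#'
#' @param config a `qp_study_config`.
#' @param quiet suppress progress messages.
#' @return list with `mesh`, `fem`, `prior` (a `qp_joint_prior`),
#'   `geom`, `crt`, and named `models`.
#' @export
build_study <- function(config, quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("meshing (h = %.3g..%.3g cm)", config$h_boundary, config$h_center)
  mesh <- build_disk_mesh(config$radius, config$h_boundary, config$h_center,
                          seed = config$mesh_seed)
  fem <- assemble_fem(mesh)
  say("calibrating priors (N = %d)", fem$n_nodes)
  pr1 <- calibrate_prior(fem, config$prior_variance_m1, config$corr_length)
  pr2 <- if (!config$known_scattering)
    calibrate_prior(fem, config$prior_variance_m2, config$corr_length)
  prior <- joint_prior(pr1, pr2)
  geom <- acoustic_geometry(n_transducers = config$n_transducers,
                            ring_radius = config$transducer_radius,
                            n_times = config$n_times, dt = config$dt,
                            c0 = config$c0, domain_radius = config$radius)
  say("assembling CRT (%d x %d)", geom$K, fem$n_nodes)
  crt <- build_crt(mesh, geom)
  models <- lapply(config$schemes, function(sch) {
    d <- make_design(sch, ring_radius = config$source_ring_radius,
                     S = config$S, I = config$I, aperture = config$aperture,
                     mu_a_prime = config$mu_a_prime)
    d <- normalize_power(d, fem)
    qpact_model(fem, d, crt, sigma2 = config$sigma2,
                mu_a_bar = config$mu_a_bar, mu_s_bar = config$mu_s_bar,
                known_scattering = config$known_scattering)
  })
  names(models) <- config$schemes
  list(config = config, mesh = mesh, fem = fem, prior = prior, geom = geom,
       crt = crt, models = models)
}

#' Run a study end to end
#'
#' Estimates the Bayesian CRB design metric for every scheme of the
#' configuration and, optionally, validates it against the expected MAP
#' reconstruction error.  Artifacts (resolved configuration, summary
#' table, pointwise maps as VTK) are written to `out_dir` when given.
#'
#' @param config a `qp_study_config`.
#' @param seed base seed for every Monte Carlo stage.
#' @param with_mse also run the MAP error validation.
#' @param out_dir optional output directory.
#' @param quiet suppress progress messages.
#' @return list with per-scheme `bounds` (and `mse`), and a `summary`
#'   data frame with columns `MSE_m1`, `Bound_m1`, `MSE_mua`,
#'   `Bound_mua` (MSE columns `NA` unless `with_mse`).
#' @export
run_study <- function(config, seed = 1L, with_mse = FALSE, out_dir = NULL,
                      quiet = TRUE) {
  st <- build_study(config, quiet = quiet)
  say <- function(...) if (!quiet) message(sprintf(...))
  bounds <- list(); mses <- list()
  for (sch in names(st$models)) {
    say("bound stage: %s (N_s = %d)", sch, config$N_s)
    jd <- estimate_JD(st$models[[sch]], st$prior, N_s = config$N_s, seed = seed)
    bounds[[sch]] <- assemble_bound(jd, st$prior, st$fem,
                                    mu_a_bar = config$mu_a_bar,
                                    cov_N_s = config$cov_N_s, seed = seed)
    if (with_mse) {
      say("MSE stage: %s (%d trials)", sch, config$n_trials)
      mses[[sch]] <- expected_mse(st$models[[sch]], st$prior,
                                  n_trials = config$n_trials,
                                  seed = seed, mu_a_bar = config$mu_a_bar)
    }
  }
  summary <- data.frame(
    scheme = names(st$models),
    MSE_m1 = vapply(names(st$models), function(s)
      if (with_mse) mses[[s]]$tr_m1 else NA_real_, numeric(1)),
    Bound_m1 = vapply(bounds, function(b) b$tr_m1, numeric(1)),
    MSE_mua = vapply(names(st$models), function(s)
      if (with_mse) mses[[s]]$tr_mua else NA_real_, numeric(1)),
    Bound_mua = vapply(bounds, function(b) b$tr_mua, numeric(1)),
    row.names = NULL)
  out <- list(config = config, study = st, bounds = bounds, mse = mses,
              summary = summary, seed = seed)
  if (!is.null(out_dir)) write_study_artifacts(out, out_dir)
  out
}

write_study_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  cfg <- run$config; class(cfg) <- NULL
  writeLines(yaml::as.yaml(c(cfg, list(seed = run$seed))),
             file.path(out_dir, "config.yaml"))
  for (sch in names(run$bounds)) {
    b <- run$bounds[[sch]]
    pd <- list(bound_m1 = b$pointwise_m1, bound_mua = b$pointwise_mua)
    if (length(run$mse)) {
      pd$mse_m1 <- run$mse[[sch]]$pointwise_m1
      pd$mse_mua <- run$mse[[sch]]$pointwise_mua
    }
    write_mesh_vtk(run$study$mesh, file.path(out_dir, paste0(sch, "_maps.vtk")),
                   point_data = pd)
  }
  invisible(out_dir)
}

#' Rank design schemes by the bound metric
#'
#' Sorts the schemes of a completed run by \eqn{tr_M(\hat V_{\mu_a})}
#' with half-sample Monte Carlo error intervals; a ranking between two
#' schemes is declared only when their intervals are disjoint.
#'
#' @param run result of [run_study()] (bounds must carry their score
#'   matrices).
#' @return a data frame sorted by metric with columns `metric`, `lo`,
#'   `hi`, and a logical `ranking_decisive` attribute.
#' @export
compare_designs <- function(run) {
  st <- run$study
  rows <- lapply(names(run$bounds), function(sch) {
    b <- run$bounds[[sch]]
    hs <- half_sample_metrics(list(scores = b$scores, N_s = b$N_s),
                              st$prior, st$fem,
                              mu_a_bar = run$config$mu_a_bar,
                              cov_mode = "closed_form", seed = run$seed)
    data.frame(scheme = sch, metric = b$tr_mua,
               lo = hs$interval[1], hi = hs$interval[2])
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$metric), , drop = FALSE]
  decisive <- nrow(tab) < 2 ||
    all(tab$hi[-nrow(tab)] < tab$lo[-1])
  attr(tab, "ranking_decisive") <- decisive
  tab
}

#' Average signal-to-noise ratio of a model under the prior
#'
#' Reports \eqn{10\log_{10}(\overline{d_0^2}/\sigma^2)} with the mean
#' squared noise-free data averaged over prior draws.  The SNR
#' definition is configuration, not physics; it is reported for
#' orientation only.
#'
#' @param model a `qp_model`.
#' @param prior matching prior.
#' @param n prior draws to average over.
#' @param seed seed.
#' @return SNR in dB.
#' @export
compute_snr <- function(model, prior, n = 5L, seed = 1L) {
  ms <- 0
  for (i in seq_len(n)) {
    m <- joint_draw(model, prior, derive_seed(seed, i, 61L))
    st <- forward_state(model, m)
    ms <- ms + mean(unlist(st$d0)^2)
  }
  10 * log10((ms / n) / model$sigma2)
}
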
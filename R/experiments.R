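#' Experiment configuration
#'
#' Collects every knob of the dura-effect studies.  Defaults encode the study
#' conditions: a six-shell corrugated head phantom (white 40 / gray 44 / CSF /
#' dura 48 / hard skull 54 / scalp 60 mm outer radii, one-voxel dura), 2 mm
#' voxels, one dipole per gray voxel with magnitudes uniform on [0, 0.4] mA m,
#' ten trials, and hard-skull sensitivity factors {0.5, 1, 1.5}.
#'
#' @param voxel_size Voxel edge, mm.
#' @param dura_thickness_vox Dura thickness in voxels.
#' @param radii Shell outer radii (named, mm); default
#'   [default_shell_radii()].
#' @param corrugation List `amplitude` (mm), `frequency` for the cortical
#'   interfaces.
#' @param grid_shape Optional grid dimensions (default auto).
#' @param seed Master integer seed; trial `t` uses `seed + t - 1`.
#' @param amplitude_min,amplitude_max Dipole magnitude range (A m).
#' @param smoothing_width Gaussian sd (mm) for cortical normal estimation.
#' @param tol,max_iter Solver tolerance and iteration cap.
#' @param n_trials Number of trial repetitions (>= 1).
#' @param z_cut Scalp cap plane (mm); default the phantom center plane.
#' @param skull_factors Multipliers applied to the mean hard-skull
#'   conductivity in the sensitivity study (> 0).
#' @param n_bins Histogram bins for distribution summaries.
#' @param table A `conductivity_table`.
#' @param verbose Log per-stage timings to stderr.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(voxel_size = 2,
                              dura_thickness_vox = 1,
                              radii = default_shell_radii(voxel_size,
                                                          dura_thickness_vox),
                              corrugation = list(amplitude = 1.5,
                                                 frequency = 8),
                              grid_shape = NULL,
                              seed = 1L,
                              amplitude_min = 0,
                              amplitude_max = 4e-4,
                              smoothing_width = 2 * voxel_size,
                              tol = 1e-8,
                              max_iter = 20000L,
                              n_trials = 10L,
                              z_cut = NULL,
                              skull_factors = c(0.5, 1, 1.5),
                              n_bins = 50L,
                              table = default_conductivity_table(),
                              verbose = FALSE) {
  stopifnot(n_trials >= 1L, all(skull_factors > 0))
  structure(list(voxel_size = voxel_size,
                 dura_thickness_vox = dura_thickness_vox, radii = radii,
                 corrugation = corrugation, grid_shape = grid_shape,
                 seed = as.integer(seed), amplitude_min = amplitude_min,
                 amplitude_max = amplitude_max,
                 smoothing_width = smoothing_width, tol = tol,
                 max_iter = as.integer(max_iter),
                 n_trials = as.integer(n_trials), z_cut = z_cut,
                 skull_factors = skull_factors, n_bins = as.integer(n_bins),
                 table = table, verbose = verbose),
            class = "experiment_config")
}

.log_stage <- function(config, fmt, ...) {
  if (isTRUE(config$verbose))
    message(sprintf("[durasim %s] ", format(Sys.time(), "%H:%M:%S")),
            sprintf(fmt, ...))
}

# build the phantom + cortical normals for a config (shared by all studies)
.build_study_phantom <- function(config) {
  t0 <- proc.time()[3]
  model <- build_shell_phantom(config$radii, config$voxel_size,
                               grid_shape = config$grid_shape,
                               corrugation = config$corrugation)
  normals <- compute_cortical_normals(model, config$smoothing_width)
  .log_stage(config, "phantom %s, %d cortical voxels (%.1f s)",
             paste(dim(model$labels), collapse = "x"), nrow(normals),
             proc.time()[3] - t0)
  list(model = model, normals = normals)
}

# solve one conductivity realization for a given dipole field
.solve_model <- function(config, model, dipoles, overrides = NULL) {
  t0 <- proc.time()[3]
  sigma <- realize_conductivity(model, config$table, overrides)
  op <- assemble_system(sigma)
  src <- dipoles_to_currents(dipoles, op)
  pot <- solve_potential(op, src, tol = config$tol,
                         max_iter = config$max_iter)
  .log_stage(config, "solved in %d CG iterations (%.1f s)",
             pot$iterations, proc.time()[3] - t0)
  list(op = op, potential = pot)
}

# capped, average-referenced scalp map for one solved model
.scalp_map <- function(config, model, potential) {
  m <- extract_interface(model, potential, "scalp", "air_external")
  m <- cap_above_plane(m, config$z_cut)
  apply_average_reference(m)
}

#' Dura-vs-CSF substitution experiment
#'
#' Builds one phantom and one cortical dipole field, solves the forward
#' problem for the dura-bearing model (the reference) and for an otherwise
#' identical model whose dura compartment is relabeled CSF (the test),
#' extracts capped and average-referenced scalp maps, and compares them
#' (RDM*, MAG, K-S, histogram/CDF summaries, peak reduction at the test
#' model's peak location).
#'
#' @param config An [experiment_config()].
#' @param seed Seed for the dipole magnitudes (default `config$seed`).
#' @param overrides Optional conductivity overrides (S/m) applied to both
#'   models (used by the skull-sensitivity study).
#' @param phantom Optional prebuilt `.build_study_phantom()` result, to share
#'   a phantom across trials.
#' @return An `experiment_report` with elements `comparison`
#'   (`comparison_result`), `peak_reduction_percent`, `scalp_reference`,
#'   `scalp_test` (surface maps), `seed`, `config`, `provenance`.
#' @export
run_dura_comparison <- function(config = experiment_config(),
                                seed = config$seed, overrides = NULL,
                                phantom = NULL) {
  if (is.null(phantom)) phantom <- .build_study_phantom(config)
  model_ref <- phantom$model
  model_test <- replace_tissue(model_ref, "dura", "csf")
  dipoles <- sample_dipole_field(model_ref, phantom$normals,
                                 source_config(config$amplitude_min,
                                               config$amplitude_max, seed))
  ref <- .solve_model(config, model_ref, dipoles, overrides)
  tst <- .solve_model(config, model_test, dipoles, overrides)
  map_ref <- .scalp_map(config, model_ref, ref$potential)
  map_tst <- .scalp_map(config, model_test, tst$potential)
  cmp <- compare_topographies(map_ref$potential, map_tst$potential,
                              config$n_bins)
  ipk <- which.max(map_tst$potential)
  peak <- percent_peak_reduction(map_tst$potential[ipk],
                                 map_ref$potential[ipk])
  structure(list(comparison = cmp, peak_reduction_percent = peak,
                 scalp_reference = map_ref, scalp_test = map_tst,
                 seed = seed, config = config,
                 provenance = .provenance(config, seed)),
            class = "experiment_report")
}

.provenance <- function(config, seeds) {
  list(package = "durasim",
       version = as.character(utils::packageVersion("durasim")),
       seeds = seeds, timestamp = format(Sys.time(), tz = "UTC"))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Dura-substitution experiment (seed ", x$seed, ")\n", sep = "")
  print(x$comparison)
  cat("  peak reduction at test-model maximum: ",
      signif(x$peak_reduction_percent, 4), "%\n", sep = "")
  invisible(x)
}

#' Multi-trial dura-comparison statistics
#'
#' Repeats [run_dura_comparison()] with per-trial seeds `seed + t - 1`
#' (t = 1..n_trials), resampling only the dipole magnitudes, and reports the
#' mean and standard deviation of RDM* and MAG across trials.
#'
#' @param config An [experiment_config()].
#' @return A `trial_report`: list with `trials` (data frame of seed, rdm_star,
#'   mag, peak_reduction_percent), `rdm_mean`, `rdm_sd`, `mag_mean`,
#'   `mag_sd`, `config`, `provenance`.
#' @export
run_trials <- function(config = experiment_config()) {
  phantom <- .build_study_phantom(config)
  seeds <- config$seed + seq_len(config$n_trials) - 1L
  rows <- lapply(seeds, function(s) {
    rep <- run_dura_comparison(config, seed = s, phantom = phantom)
    data.frame(seed = s, rdm_star = rep$comparison$rdm_star,
               mag = rep$comparison$mag,
               peak_reduction_percent = rep$peak_reduction_percent)
  })
  trials <- do.call(rbind, rows)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  structure(list(trials = trials,
                 rdm_mean = mean(trials$rdm_star),
                 rdm_sd = sd0(trials$rdm_star),
                 mag_mean = mean(trials$mag),
                 mag_sd = sd0(trials$mag),
                 config = config, provenance = .provenance(config, seeds)),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  n <- nrow(x$trials)
  cat("Dura-substitution trials (n = ", n, ")\n",
      "  RDM* = ", signif(x$rdm_mean, 4), " +/- ",
      signif(x$rdm_sd, 3), "\n",
      "  MAG  = ", signif(x$mag_mean, 4), " +/- ",
      signif(x$mag_sd, 3), "\n", sep = "")
  invisible(x)
}

#' Surface-by-surface smoothing cascade
#'
#' Solves the dura-bearing model once and extracts average-referenced
#' potential maps on the cortical surface (gray voxels facing CSF), inner and
#' outer dura, inner and outer skull, and the scalp.  Reports per-surface
#' distribution summaries (the standard deviations quantify progressive
#' spatial smoothing), pairwise K-S tests, and RDM*/MAG between the inner and
#' outer faces of the dura and of the skull (points paired by nearest angular
#' position; the outer face is the reference).
#'
#' @param config An [experiment_config()].
#' @return A `cascade_report`: list with `surfaces` (named list of
#'   `surface_map`s), `summaries` (named list of `distribution_summary`s),
#'   `sds` (named vector, V), `ks_pairs` (data frame), `dura_faces`,
#'   `skull_faces` (each: list with rdm_star, mag, n), `config`,
#'   `provenance`.
#' @export
run_surface_cascade <- function(config = experiment_config()) {
  phantom <- .build_study_phantom(config)
  model <- phantom$model
  dipoles <- sample_dipole_field(model, phantom$normals,
                                 source_config(config$amplitude_min,
                                               config$amplitude_max,
                                               config$seed))
  sol <- .solve_model(config, model, dipoles)
  spec <- list(cortex = c("gray", "csf"),
               dura_inner = c("dura", "csf"),
               dura_outer = c("dura", "skull_hard"),
               skull_inner = c("skull_hard", "dura"),
               skull_outer = c("skull_hard", "scalp"),
               scalp = c("scalp", "air_external"))
  surfaces <- lapply(spec, function(p)
    apply_average_reference(extract_interface(model, sol$potential,
                                              p[1], p[2])))
  summaries <- lapply(surfaces, function(m)
    distribution_summary(m$potential, config$n_bins))
  sds <- vapply(summaries, `[[`, 0, "sd")
  pairs <- utils::combn(names(surfaces), 2)
  ks_pairs <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(q) {
    a <- pairs[1, q]; b <- pairs[2, q]
    ks <- ks_two_sample(surfaces[[a]]$potential, surfaces[[b]]$potential)
    data.frame(surface_a = a, surface_b = b, ks_statistic = ks$statistic,
               ks_p = ks$p_value, different = ks$different)
  }))
  face_cmp <- function(inner, outer) {
    m <- match_surface_points(surfaces[[inner]], surfaces[[outer]])
    if (sum(m$potential_a^2) == 0 || sum(m$potential_b^2) == 0)
      return(list(rdm_star = NA_real_, mag = NA_real_, n = nrow(m)))
    list(rdm_star = rdm_star(m$potential_b, m$potential_a),
         mag = mag(m$potential_b, m$potential_a), n = nrow(m))
  }
  structure(list(surfaces = surfaces, summaries = summaries, sds = sds,
                 ks_pairs = ks_pairs,
                 dura_faces = face_cmp("dura_inner", "dura_outer"),
                 skull_faces = face_cmp("skull_inner", "skull_outer"),
                 config = config,
                 provenance = .provenance(config, config$seed)),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Surface smoothing cascade (per-surface population sd, V):\n")
  for (nm in names(x$sds))
    cat(sprintf("  %-12s %.4g\n", nm, x$sds[[nm]]))
  cat("  inner/outer dura : RDM* = ", signif(x$dura_faces$rdm_star, 3),
      ", MAG = ", signif(x$dura_faces$mag, 3), "\n",
      "  inner/outer skull: RDM* = ", signif(x$skull_faces$rdm_star, 3),
      ", MAG = ", signif(x$skull_faces$mag, 3), "\n", sep = "")
  invisible(x)
}

#' Hard-skull conductivity sensitivity of the dura effect
#'
#' Repeats the dura comparison with the hard-skull conductivity overridden to
#' `factor x` its tabulated mean, keeping the phantom and dipole field
#' identical throughout, and tabulates (factor, RDM*, MAG, peak reduction).
#'
#' @param config An [experiment_config()] (factors taken from
#'   `config$skull_factors`).
#' @return A `sensitivity_report`: list with `table` (data frame), `reports`
#'   (per-factor `experiment_report`s), `config`, `provenance`.
#' @export
run_skull_sensitivity <- function(config = experiment_config()) {
  phantom <- .build_study_phantom(config)
  base <- tissue_conductivity(config$table, "skull_hard")
  reports <- lapply(config$skull_factors, function(f)
    run_dura_comparison(config, overrides = c(skull_hard = f * base),
                        phantom = phantom))
  tab <- data.frame(
    factor = config$skull_factors,
    skull_conductivity_S_m = config$skull_factors * base,
    rdm_star = vapply(reports, function(r) r$comparison$rdm_star, 0),
    mag = vapply(reports, function(r) r$comparison$mag, 0),
    peak_reduction_percent = vapply(reports,
                                    function(r) r$peak_reduction_percent, 0))
  structure(list(table = tab, reports = reports, config = config,
                 provenance = .provenance(config, config$seed)),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Hard-skull conductivity sensitivity of the dura effect:\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
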
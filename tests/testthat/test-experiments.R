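test_that("identical conductivity realizations give RDM* 0 and MAG 1", {
  cfg <- fast_config()
  csf <- tissue_conductivity(cfg$table, "csf")
  # overriding dura to the CSF value makes both pipelines solve the same
  # conductivity field, so the comparison must collapse to identity
  rep <- run_dura_comparison(cfg, overrides = c(dura = csf))
  expect_equal(rep$comparison$rdm_star, 0, tolerance = 1e-9)
  expect_equal(rep$comparison$mag, 1, tolerance = 1e-9)
  expect_equal(rep$peak_reduction_percent, 0, tolerance = 1e-6)
})

test_that("the comparison is invariant to a global source rescaling", {
  cfg1 <- fast_config()
  cfg2 <- fast_config(amplitude_max = 8e-4)   # doubles every magnitude
  r1 <- run_dura_comparison(cfg1)
  r2 <- run_dura_comparison(cfg2)
  expect_equal(r2$comparison$rdm_star, r1$comparison$rdm_star,
               tolerance = 1e-6)
  expect_equal(r2$comparison$mag, r1$comparison$mag, tolerance = 1e-6)
})

test_that("a fixed seed reproduces the experiment bit-identically", {
  cfg <- fast_config()
  r1 <- run_dura_comparison(cfg)
  r2 <- run_dura_comparison(cfg)
  expect_identical(r1$comparison$rdm_star, r2$comparison$rdm_star)
  expect_identical(r1$comparison$mag, r2$comparison$mag)
  expect_identical(r1$scalp_reference$potential, r2$scalp_reference$potential)
  expect_identical(r1$seed, cfg$seed)
})

test_that("finite-volume dura effect agrees with the analytic prediction", {
  # paired single-dipole runs: the numeric MAG must track the multishell
  # oracle's attenuation ratio, in the tabulated-dura regime (ratio < 1)
  # and in the near-insulating regime (ratio > 1)
  cfg <- fast_config()
  ph <- build_shell_phantom(cfg$radii, cfg$voxel_size)
  ctr <- ph$center
  dip <- single_dipole_field(ph, c(15, 0, 0), c(0, 0, 1), 4e-4)
  solve_map <- function(model, overrides = NULL) {
    sig <- realize_conductivity(model, cfg$table, overrides)
    op <- assemble_system(sig)
    pot <- solve_potential(op, dipoles_to_currents(dip, op))
    apply_average_reference(
      extract_interface(model, pot, "scalp", "air_external"))
  }
  m_rep <- solve_map(replace_tissue(ph, "dura", "csf"))
  cond <- tissue_conductivity(cfg$table, names(cfg$radii))
  mk_shells <- function(dura_sigma)
    shell_spec(cfg$radii / 1000, replace(cond, 4, dura_sigma))
  for (dura_sigma in c(0.06, 0.001)) {
    m_ref <- solve_map(ph, overrides = c(dura = dura_sigma))
    fv_mag <- mag(m_ref$potential, m_rep$potential)
    oracle <- attenuation_ratio(mk_shells(dura_sigma), mk_shells(1.54),
                                c(0.015, 0, 0), c(0, 0, 4e-4),
                                n_terms = 80)
    expect_lt(abs(fv_mag - oracle) / oracle, 0.25)
    expect_identical(fv_mag > 1, oracle > 1)
  }
})

test_that("trial statistics are reproducible and degenerate correctly", {
  cfg <- fast_config(n_trials = 1L)
  tr1 <- run_trials(cfg)
  expect_identical(tr1$rdm_sd, 0)
  expect_identical(tr1$mag_sd, 0)
  base <- run_dura_comparison(cfg)
  expect_identical(tr1$trials$rdm_star, base$comparison$rdm_star)
  cfg2 <- fast_config(n_trials = 3L)
  tr2 <- run_trials(cfg2)
  tr3 <- run_trials(cfg2)
  expect_identical(tr2$trials, tr3$trials)
  expect_identical(tr2$trials$seed, cfg2$seed + 0:2)
  expect_gt(tr2$rdm_sd, 0)
})

test_that("skull sensitivity tabulates one row per factor, base row exact", {
  cfg <- fast_config(skull_factors = c(0.5, 1, 1.5))
  sens <- run_skull_sensitivity(cfg)
  expect_identical(nrow(sens$table), 3L)
  base <- run_dura_comparison(cfg)
  i1 <- which(sens$table$factor == 1)
  expect_equal(sens$table$rdm_star[i1], base$comparison$rdm_star)
  expect_equal(sens$table$mag[i1], base$comparison$mag)
  expect_equal(sens$table$skull_conductivity_S_m,
               c(0.5, 1, 1.5) * tissue_conductivity(cfg$table, "skull_hard"))
})

test_that("the smoothing cascade attenuates outward and handles zero sources", {
  cfg <- fast_config(dura_thickness_vox = 2)
  cfg$radii[["dura"]] <- cfg$radii[["csf"]] + 2 * cfg$voxel_size
  cfg$radii[c("skull_hard", "scalp")] <- cfg$radii[["dura"]] + c(6, 12)
  casc <- run_surface_cascade(cfg)
  expect_gt(casc$sds[["cortex"]], casc$sds[["dura_outer"]])
  expect_gt(casc$sds[["dura_outer"]], casc$sds[["skull_outer"]])
  expect_gte(casc$sds[["skull_outer"]], casc$sds[["scalp"]])
  # with a two-voxel dura the inner/outer dura distributions are
  # distinguishable
  kd <- subset(casc$ks_pairs, surface_a == "dura_inner" &
                 surface_b == "dura_outer")
  expect_true(kd$different)
  expect_true(is.finite(casc$dura_faces$rdm_star))
  # zero dipole field: every surface is identically zero
  czero <- fast_config(amplitude_max = 0)
  c0 <- run_surface_cascade(czero)
  expect_true(all(c0$sds == 0))
})
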
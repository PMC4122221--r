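test_that("uncorrugated shell phantom labels depend only on radius", {
  radii <- c(white = 40, gray = 44, csf = 47, dura = 48, skull_hard = 54,
             scalp = 60)
  ph <- build_shell_phantom(radii, voxel_size = 2)
  counts <- tissue_counts(ph)
  bf <- brute_force_shell_counts(ph, radii)
  for (nm in names(radii))
    expect_identical(unname(counts[nm]), unname(as.integer(bf[nm])))
  # spherical symmetry: identical radius implies identical label
  ctr <- ph$center
  pos <- voxel_centers(ph)
  r <- round(sqrt(rowSums(sweep(pos, 2, ctr)^2)), 9)
  lab <- as.integer(ph$labels)
  expect_true(all(tapply(lab, r, function(v) length(unique(v))) == 1L))
})

test_that("corrugation only perturbs the cortical band", {
  radii <- c(white = 20, gray = 24, csf = 28, dura = 30, skull_hard = 36,
             scalp = 42)
  p0 <- build_shell_phantom(radii, voxel_size = 2,
                            corrugation = list(amplitude = 0, frequency = 6))
  p2 <- build_shell_phantom(radii, voxel_size = 2,
                            corrugation = list(amplitude = 2, frequency = 6))
  ctr <- p0$center
  pos <- voxel_centers(p0)
  r <- sqrt(rowSums(sweep(pos, 2, ctr)^2))
  outside <- r < radii[["white"]] - 2 | r > radii[["gray"]] + 2
  expect_identical(as.integer(p0$labels)[outside],
                   as.integer(p2$labels)[outside])
  expect_false(identical(p0$labels, p2$labels))
})

test_that("shell nesting holds along random rays", {
  cfg_order <- c("white", "gray", "csf", "dura", "skull_hard", "scalp",
                 "air_external")
  ph <- build_shell_phantom(default_shell_radii(2), voxel_size = 2,
                            corrugation = list(amplitude = 1.5,
                                               frequency = 8))
  ctr_ijk <- (dim(ph$labels) + 1) / 2  # odd grid: center voxel index
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1),
                 c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
                 c(1, 1, 1), c(-1, 1, 1), c(1, -1, 1), c(1, 1, -1))
  for (q in seq_len(nrow(steps))) {
    s <- steps[q, ]
    nmax <- floor((min(dim(ph$labels)) - 1) / 2 / max(abs(s)))
    ijk <- sweep(outer(0:nmax, s), 2, ctr_ijk, "+")
    labs <- ph$labels[ijk]
    ord <- match(ph$tissues[labs], cfg_order)
    # tissue order along a lattice ray never decreases (skips allowed)
    expect_true(all(diff(ord) >= 0))
  }
})

test_that("invalid phantom configurations are rejected", {
  expect_error(build_shell_phantom(c(white = 40, gray = 38), 2),
               "strictly increasing")
  expect_error(
    build_shell_phantom(c(white = 40, gray = 44, csf = 47, dura = 48,
                          skull_hard = 54, scalp = 60), 2,
                        grid_shape = c(40, 65, 65)),
    "grid boundary")
  expect_error(
    build_shell_phantom(c(white = 20, gray = 24, csf = 25, dura = 27,
                          skull_hard = 33, scalp = 39), 2,
                        corrugation = list(amplitude = 1.5, frequency = 6)),
    "amplitude")
})

test_that("replace_tissue conserves voxels and relabels completely", {
  ph <- build_shell_phantom(default_shell_radii(2), voxel_size = 2)
  before <- tissue_counts(ph)
  rep <- replace_tissue(ph, "dura", "csf")
  after <- tissue_counts(rep)
  expect_identical(unname(after["dura"]), 0L)
  expect_identical(unname(after["csf"]),
                   unname(before["csf"] + before["dura"]))
  expect_identical(sum(after), sum(before))
  expect_identical(replace_tissue(ph, "gray", "gray")$labels, ph$labels)
  # replacing an absent tissue is a no-op
  expect_identical(replace_tissue(ph, "thalamus", "gray")$labels, ph$labels)
})

test_that("conductivity table reproduces tabulated conversions", {
  tab <- default_conductivity_table()
  expect_equal(tab$mean_conductivity_S_cm[tab$tissue == "dura"], 1 / 1667)
  expect_equal(round(tab$mean_conductivity_S_cm[tab$tissue == "dura"], 5),
               6e-4)
  expect_equal(round(tab$mean_conductivity_S_cm[tab$tissue == "csf"], 4),
               1.54e-2)
  expect_equal(tab$conductivity_S_m[tab$tissue == "csf"],
               100 / 65)
  expect_equal(conductivity_from_table(
    data.frame(tissue = "gray", mean_resistivity = 100)
  )$mean_conductivity_S_cm, 0.01)
  # reciprocity invariant (air_external stores a quoted, non-reciprocal value)
  ok <- tab$tissue != "air_external"
  expect_true(all(abs(tab$mean_conductivity_S_cm[ok] *
                        tab$mean_resistivity[ok] - 1) < 1e-12))
  expect_true(all(tab$lower_resistivity <= tab$mean_resistivity &
                    tab$mean_resistivity <= tab$upper_resistivity))
  expect_error(conductivity_from_table(
    data.frame(tissue = "x", mean_resistivity = -5)), "positive")
})

test_that("conductivity realization maps labels and applies overrides last", {
  ph <- build_shell_phantom(default_shell_radii(2), voxel_size = 2)
  tab <- default_conductivity_table()
  cv <- realize_conductivity(ph, tab)
  present <- names(tissue_counts(ph))[tissue_counts(ph) > 0]
  vals <- sort(unique(as.numeric(cv$sigma)))
  expected <- sort(unique(c(0, tissue_conductivity(
    tab, setdiff(present, "air_external")))))
  expect_equal(vals, expected)
  # override locality: only hard-skull voxels change
  cv2 <- realize_conductivity(ph, tab, overrides = c(skull_hard = 0.5 *
    tissue_conductivity(tab, "skull_hard")))
  skull <- ph$labels == match("skull_hard", ph$tissues)
  expect_equal(cv2$sigma[!skull], cv$sigma[!skull])
  expect_equal(unique(cv2$sigma[skull]),
               0.5 * tissue_conductivity(tab, "skull_hard"))
  # tabulated sensitivity override: 24,000 Ohm cm -> 4.167e-5 S/cm
  sigma_low <- 1 / 24000 * 100
  expect_equal(round(1 / 24000, 9), round(4.1667e-5, 9), tolerance = 1e-4)
  cv3 <- realize_conductivity(ph, tab, overrides = c(skull_hard = sigma_low))
  expect_equal(unique(cv3$sigma[skull]), sigma_low)
  # unmapped label
  small_tab <- conductivity_from_table(
    data.frame(tissue = c("white", "gray"),
               mean_resistivity = c(700, 300)))
  expect_error(realize_conductivity(ph, small_tab), "no conductivity")
})
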
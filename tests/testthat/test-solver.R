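test_that("face conductances follow the harmonic-mean circuit rule", {
  s <- array(0, c(8, 8, 8))
  s[4, 4, 4] <- 1; s[5, 4, 4] <- 1          # two-voxel conductor, 1 S/m
  op <- assemble_system(s, voxel_size = 1)
  # sigma * area / distance = 1 * (1e-3)^2 / 1e-3 = 1e-3 S
  expect_equal(op$gx[4, 4, 4], 1e-3)
  # insulating neighbor carries zero conductance
  s2 <- array(0, c(8, 8, 8))
  s2[4, 4, 4] <- 2
  s2[5, 4, 4] <- 2
  s2[6, 4, 4] <- 0
  op2 <- assemble_system(s2, voxel_size = 1)
  expect_identical(op2$gx[5, 4, 4], 0)
  # harmonic mean between unequal conductivities
  s3 <- array(0, c(8, 8, 8)); s3[4, 4, 4] <- 1; s3[5, 4, 4] <- 3
  op3 <- assemble_system(s3, voxel_size = 2)
  expect_equal(op3$gx[4, 4, 4], 2 * 1 * 3 / (1 + 3) * 2e-3)
})

test_that("the operator conserves current and is symmetric", {
  set.seed(5)
  s <- array(stats::runif(1000, 0.1, 2), c(10, 10, 10))
  op <- assemble_system(s, voxel_size = 1.7)
  # pure Neumann: row sums are zero <=> constant vector is in the null space
  const <- array(1, dim(s))
  expect_lt(max(abs(apply_operator(op, const))), 1e-12)
  A <- as_sparse_operator(op)
  expect_lt(max(abs(A - Matrix::t(A))), 1e-15)
  # sparse form agrees with the stencil application
  x <- array(stats::rnorm(1000), dim(s))
  expect_equal(as.numeric(A %*% as.numeric(x)[op$mask]),
               as.numeric(apply_operator(op, x))[op$mask])
})

test_that("disconnected conductive regions are rejected with sizes", {
  s <- array(0, c(9, 9, 9))
  s[2:3, 2:3, 2:3] <- 1    # 8 voxels
  s[7:8, 7:8, 7:8] <- 1    # 8 voxels, not 6-connected to the first
  expect_error(assemble_system(s, 1), "8, 8")
})

test_that("dipole discretization carries the exact dipole moment", {
  s <- array(1, c(9, 9, 9))
  op <- assemble_system(s, voxel_size = 1)
  m <- voxel_model(array(match("gray", tissue_labels()), c(9, 9, 9)),
                   tissue_labels(), 1, center = c(4, 4, 4))
  # axis-aligned worked case: p = 4e-4 A m along +z, 1 mm voxels
  # -> +/- p/(2h) = 0.2 A in the two z-neighbors
  dip <- single_dipole_field(m, c(0, 0, 0), c(0, 0, 1), 4e-4)
  src <- dipoles_to_currents(dip, op)
  expect_equal(src$I[5, 5, 6], 0.2)
  expect_equal(src$I[5, 5, 4], -0.2)
  expect_equal(sum(src$I != 0), 2L)
  expect_equal(sum(src$I), 0)
  # oblique orientation: zeroth moment vanishes, first moment equals p * n
  u <- c(1, 2, -0.5); u <- u / sqrt(sum(u^2))
  dip2 <- single_dipole_field(m, c(0.3, -0.2, 0.1), u, 2.5e-4)
  src2 <- dipoles_to_currents(dip2, op)
  expect_lt(abs(sum(src2$I)), 1e-12 * sum(abs(src2$I)))
  idx <- which(src2$I != 0, arr.ind = TRUE)
  pos_m <- (idx - 1) * 1e-3   # voxel centers in meters
  mom <- colSums(src2$I[idx] * pos_m)
  expect_equal(as.numeric(mom), 2.5e-4 * u, tolerance = 1e-10)
  # zero magnitude -> empty source volume
  dip0 <- single_dipole_field(m, c(0, 0, 0), c(0, 0, 1), 0)
  expect_true(all(dipoles_to_currents(dip0, op)$I == 0))
  # injection into non-conductive tissue is an error naming the dipole
  s_ins <- array(1, c(9, 9, 9)); s_ins[5, 5, 6] <- 0
  op_ins <- assemble_system(s_ins, voxel_size = 1)
  expect_error(dipoles_to_currents(dip, op_ins), "non-conductive")
})

test_that("potential solve is linear, gauged, and conserves current", {
  set.seed(9)
  s <- array(stats::runif(1000, 0.05, 3), c(10, 10, 10))
  op <- assemble_system(s, voxel_size = 2)
  b <- array(0, dim(s))
  b[2, 3, 4] <- 1e-3; b[8, 7, 5] <- -1e-3
  src <- structure(list(I = b, voxel_size = 2, origin = c(0, 0, 0)),
                   class = "current_sources")
  pot <- solve_potential(op, src, tol = 1e-10)
  expect_lt(abs(mean(pot$phi[op$mask])), 1e-13 * max(abs(pot$phi)))
  # conservation: div(flux) = injected currents
  fl <- compute_flux(op, pot)
  dv <- flux_divergence(fl)
  expect_lt(max(abs(dv - b)), 1e-6 * max(abs(b)))
  # linearity in the sources
  src3 <- structure(list(I = 3 * b, voxel_size = 2, origin = c(0, 0, 0)),
                    class = "current_sources")
  pot3 <- solve_potential(op, src3, tol = 1e-10)
  expect_equal(pot3$phi, 3 * pot$phi, tolerance = 1e-5)
  # zero sources -> identically zero potential
  src0 <- structure(list(I = array(0, dim(s)), voxel_size = 2,
                         origin = c(0, 0, 0)), class = "current_sources")
  expect_true(all(solve_potential(op, src0)$phi == 0))
  # imbalanced sources are rejected
  bad <- structure(list(I = abs(b), voxel_size = 2, origin = c(0, 0, 0)),
                   class = "current_sources")
  expect_error(solve_potential(op, bad), "imbalance")
})

test_that("uniform potential produces zero flux and a single face carries I", {
  s <- array(0, c(8, 8, 8)); s[4:5, 4, 4] <- 1
  op <- assemble_system(s, voxel_size = 1)
  b <- array(0, dim(s)); b[4, 4, 4] <- 2e-3; b[5, 4, 4] <- -2e-3
  src <- structure(list(I = b, voxel_size = 1, origin = c(0, 0, 0)),
                   class = "current_sources")
  pot <- solve_potential(op, src, tol = 1e-12)
  fl <- compute_flux(op, pot)
  expect_equal(fl$fx[4, 4, 4], 2e-3, tolerance = 1e-9)
  flat <- structure(list(phi = array(5, dim(s)), mask = op$mask),
                    class = "potential_volume")
  fl0 <- compute_flux(op, flat)
  expect_true(all(fl0$fx == 0) && all(fl0$fy == 0) && all(fl0$fz == 0))
})

test_that("discrete reciprocity holds on a random conductor", {
  set.seed(21)
  s <- array(stats::runif(1000, 0.1, 4), c(10, 10, 10))
  op <- assemble_system(s, voxel_size = 1)
  mk <- function(i1, i2) {
    b <- array(0, dim(s)); b[i1[1], i1[2], i1[3]] <- 1e-3
    b[i2[1], i2[2], i2[3]] <- -1e-3
    structure(list(I = b, voxel_size = 1, origin = c(0, 0, 0)),
              class = "current_sources")
  }
  A <- c(2, 2, 2); Aref <- c(9, 9, 9)
  B <- c(5, 7, 3); Bref <- c(9, 9, 9)
  phiA <- solve_potential(op, mk(A, Aref), tol = 1e-11)$phi
  phiB <- solve_potential(op, mk(B, Bref), tol = 1e-11)$phi
  # potential difference at B due to pair at A equals that at A from pair at B
  dA <- phiA[B[1], B[2], B[3]] - phiA[Bref[1], Bref[2], Bref[3]]
  dB <- phiB[A[1], A[2], A[3]] - phiB[Aref[1], Aref[2], Aref[3]]
  expect_equal(dA, dB, tolerance = 1e-5)
})

test_that("homogeneous sphere solve matches the closed-form dipole solution", {
  ph <- build_shell_phantom(c(gray = 30), voxel_size = 2)
  sig <- realize_conductivity(ph)
  op <- assemble_system(sig)
  dip <- single_dipole_field(ph, c(15, 0, 0), c(0, 0, 1), 4e-4)
  src <- dipoles_to_currents(dip, op)
  pot <- solve_potential(op, src)
  smap <- apply_average_reference(
    extract_interface(ph, pot, "gray", "air_external"))
  pts <- cbind(smap$x - ph$center[1], smap$y - ph$center[2],
               smap$z - ph$center[3]) / 1000
  vcf <- closed_form_homogeneous_sphere(
    c(0.015, 0, 0), c(0, 0, 4e-4), 0.030,
    tissue_conductivity(default_conductivity_table(), "gray"), pts)
  expect_lt(rdm_star(vcf, smap$potential), 0.1)
  expect_gt(mag(vcf, smap$potential), 0.8)
  expect_lt(mag(vcf, smap$potential), 1.2)
})
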
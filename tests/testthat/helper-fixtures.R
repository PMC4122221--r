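# Shared fixtures and independent oracles for the test suite.

# A small, fast experiment configuration: same layer topology and tissue
# table as the default study, scaled-down radii so a solve takes ~1 s.
fast_config <- function(...) {
  base <- list(
    voxel_size = 2.5,
    radii = c(white = 20, gray = 24, csf = 28, dura = 30.5,
              skull_hard = 36.5, scalp = 42.5),
    corrugation = list(amplitude = 1.5, frequency = 6),
    n_trials = 2L)
  do.call(experiment_config, utils::modifyList(base, list(...)))
}

# Independent closed-form surface potential of a dipole in a homogeneous
# conducting sphere with insulating exterior (derived by summing the Legendre
# series in closed form; independent of the package's per-degree recursion).
closed_form_homogeneous_sphere <- function(position, moment, R, sigma,
                                           points, reference = TRUE) {
  b <- sqrt(sum(position^2))
  stopifnot(b > 0, b < R)
  zhat <- position / b
  pr <- sum(moment * zhat)
  tvec <- moment - pr * zhat
  pt <- sqrt(sum(tvec^2))
  xhat <- if (pt > 0) tvec / pt else c(0, 0, 0)
  vr <- points / sqrt(rowSums(points^2))
  x <- as.numeric(vr %*% zhat)
  vx <- as.numeric(vr %*% xhat)
  t <- b / R
  g <- sqrt(1 - 2 * t * x + t^2)
  Sr <- (2 * t * (x - t) / g^3 + 1 / g - 1) / t
  St <- 2 / g^3 + (g + 1) / (g * (1 - t * x + g))
  V <- (pr * Sr + pt * vx * St) / (4 * pi * sigma * R^2)
  if (reference) V - mean(V) else V
}

# Brute-force two-sample KS statistic: evaluate both ECDFs at every pooled
# point and take the maximum discrepancy.
brute_force_ks <- function(x, y) {
  grid <- sort(c(x, y))
  max(abs(vapply(grid, function(t) mean(x <= t) - mean(y <= t), 0)))
}

# Brute-force per-tissue voxel count of a shell phantom with no corrugation:
# classify each voxel center by its distance band.
brute_force_shell_counts <- function(model, radii) {
  ctr <- model$center
  pos <- voxel_centers(model)
  r <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2 +
            (pos[, 3] - ctr[3])^2)
  band <- findInterval(r, radii, left.open = FALSE)
  # band 0 = innermost tissue ... length(radii) = air
  counts <- tabulate(band + 1L, nbins = length(radii) + 1L)
  names(counts) <- c(names(radii), "air_external")
  counts
}

# A one-shell "homogeneous sphere" phantom plus a single dipole field at a
# given offset (mm) from the center.
single_dipole_field <- function(model, offset_mm, orientation, magnitude) {
  ctr <- model$center
  p <- ctr + offset_mm
  d <- data.frame(i = NA_integer_, j = NA_integer_, k = NA_integer_,
                  x = p[1], y = p[2], z = p[3],
                  nx = orientation[1], ny = orientation[2],
                  nz = orientation[3], magnitude = magnitude)
  class(d) <- c("dipole_field", "data.frame")
  d
}
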
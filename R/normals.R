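#' Separable Gaussian smoothing of a 3-D array
#'
#' Truncated (+/- 3 sd) Gaussian kernel applied along each axis with
#' renormalized edge weights, so a constant field is preserved at boundaries.
#'
#' @param x 3-D numeric array.
#' @param sd Kernel standard deviation in voxels.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth_3d <- function(x, sd) {
  stopifnot(is.array(x), length(dim(x)) == 3L, sd >= 0)
  if (sd == 0) return(x)
  half <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  smooth_axis <- function(a) {
    # banded n x n weight matrix with rows renormalized at the edges
    n <- dim(a)[1]
    W <- matrix(0, n, n)
    for (off in seq(-half, half)) {
      idx <- seq_len(n)
      j <- idx + off
      ok <- j >= 1 & j <= n
      W[cbind(idx[ok], j[ok])] <- k[off + half + 1]
    }
    W <- W / rowSums(W)
    d <- dim(a)
    array(W %*% matrix(a, d[1]), d)
  }
  for (axis in 1:3) {
    perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    x <- aperm(smooth_axis(aperm(x, perm)), order(perm))
  }
  x
}

# central-difference gradient of a 3-D array (per-voxel, spacing h); one-sided
# at the grid faces
.gradient3 <- function(f, h) {
  d <- dim(f)
  g <- function(ax) {
    n <- d[ax]
    lo <- pmax(seq_len(n) - 1L, 1L)
    hi <- pmin(seq_len(n) + 1L, n)
    sp <- (hi - lo) * h
    idx <- function(v) switch(ax,
      `1` = f[v, , , drop = FALSE],
      `2` = f[, v, , drop = FALSE],
      `3` = f[, , v, drop = FALSE])
    sweep(idx(hi) - idx(lo), ax, sp, "/")
  }
  list(g(1L), g(2L), g(3L))
}

#' Cortical surface normals from the gray/white boundary
#'
#' Estimates, for every gray-matter voxel, the unit direction normal to the
#' local white/gray interface, pointing from white toward gray.  The white
#' matter indicator volume is Gaussian-smoothed and its (negated) gradient is
#' evaluated at gray voxels.  Gray voxels whose gradient vanishes after
#' smoothing fall back to the outward radial direction from the phantom
#' center and are flagged.
#'
#' @param model A `voxel_model` containing `white` and `gray` tissue.
#' @param smoothing_width Gaussian sd in mm (default two voxels).
#' @return Data frame with one row per gray voxel: `i,j,k` (1-based voxel
#'   index), `x,y,z` (mm), `nx,ny,nz` (unit normal), `fallback` (logical).
#'   Attribute `n_fallback` counts radial fallbacks.
#' @export
compute_cortical_normals <- function(model,
                                     smoothing_width = 2 * model$voxel_size) {
  cw <- label_code(model, "white")
  cg <- label_code(model, "gray")
  if (!any(model$labels == cw) || !any(model$labels == cg))
    stop("model must contain both white and gray tissue")
  ind <- array(0, dim(model$labels))
  ind[model$labels == cw] <- 1
  sm <- gaussian_smooth_3d(ind, smoothing_width / model$voxel_size)
  gr <- .gradient3(sm, model$voxel_size)
  sel <- which(model$labels == cg)
  v <- cbind(-gr[[1]][sel], -gr[[2]][sel], -gr[[3]][sel])
  nrm <- sqrt(rowSums(v^2))
  ijk <- arrayInd(sel, dim(model$labels))
  pos <- voxel_centers(model, ijk)
  fallback <- nrm < 1e-12
  if (any(fallback)) {
    if (is.null(model$center))
      stop("zero-gradient normals and no phantom center for radial fallback")
    rad <- sweep(pos[fallback, , drop = FALSE], 2L, model$center, "-")
    rn <- sqrt(rowSums(rad^2))
    rn[rn < 1e-12] <- 1
    v[fallback, ] <- rad / rn
    nrm[fallback] <- 1
  }
  v <- v / nrm
  out <- data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                    x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    nx = v[, 1], ny = v[, 2], nz = v[, 3],
                    fallback = fallback)
  attr(out, "n_fallback") <- sum(fallback)
  out
}

#' Dipole source configuration
#'
#' Magnitudes of the per-voxel cortical dipoles are drawn i.i.d. uniform on
#' `[amplitude_min, amplitude_max]` (A m).  The default upper bound 4e-4 A m
#' (0.4 mA m) is the study's per-hypercolumn intensity ceiling; because the
#' forward problem is linear and the comparison metrics are scale-invariant,
#' the absolute scale does not affect RDM*/MAG.
#'
#' @param amplitude_min,amplitude_max Magnitude bounds in A m.
#' @param seed Integer RNG seed; every sampled field is a pure function of it.
#' @param normal_smoothing_width Gaussian sd (mm) used when orientations are
#'   recomputed from a model.
#' @return A `source_config` list.
#' @export
source_config <- function(amplitude_min = 0, amplitude_max = 4e-4, seed = 1L,
                          normal_smoothing_width = NULL) {
  stopifnot(amplitude_min >= 0, amplitude_min <= amplitude_max)
  structure(list(amplitude_min = amplitude_min, amplitude_max = amplitude_max,
                 distribution = "uniform", seed = as.integer(seed),
                 normal_smoothing_width = normal_smoothing_width),
            class = "source_config")
}

#' Sample a distributed cortical dipole field
#'
#' Places one dipole per gray-matter voxel (each voxel standing for one
#' cortical hypercolumn), oriented along the supplied white-to-gray normals,
#' with magnitudes i.i.d. uniform on the configured range.  Reproducible from
#' `config$seed`.
#'
#' @param model A `voxel_model`.
#' @param normals Output of [compute_cortical_normals()] for `model`.
#' @param config A [source_config()].
#' @return A `dipole_field`: data frame `i,j,k,x,y,z,nx,ny,nz,magnitude`
#'   (positions mm, unit orientations, magnitudes A m) with the config as an
#'   attribute.
#' @export
sample_dipole_field <- function(model, normals, config = source_config()) {
  if (nrow(normals) == 0L)
    stop("validation error: empty cortex (no gray voxels)")
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(config$seed)
    stats::runif(nrow(normals), config$amplitude_min, config$amplitude_max)
  })
  out <- normals[, c("i", "j", "k", "x", "y", "z", "nx", "ny", "nz")]
  out$magnitude <- rng
  attr(out, "config") <- config
  attr(out, "voxel_size") <- model$voxel_size
  class(out) <- c("dipole_field", "data.frame")
  out
}
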
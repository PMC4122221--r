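#' Assemble the finite-volume volume-conduction operator
#'
#' Discretizes `-div(sigma grad phi)` on the voxel grid as a cell-centered
#' finite-volume operator.  The conductance of the face between two 6-adjacent
#' voxels is the harmonic mean of their conductivities times face area over
#' center distance (`harm(s1,s2) * h` in SI units for isotropic voxels of edge
#' `h`); the harmonic mean is the correct series composition across a face and
#' avoids over-coupling across thin resistive layers such as the dura.  Faces
#' to zero-conductivity voxels carry zero conductance, i.e. a homogeneous
#' Neumann (no current into air) boundary.
#'
#' @param sigma A `conductivity_volume` from [realize_conductivity()], or a
#'   plain 3-D array of conductivities (S/m) with `voxel_size` supplied.
#' @param voxel_size Voxel edge in mm (taken from `sigma` when it is a
#'   `conductivity_volume`).
#' @return An `fv_operator`: face conductance arrays `gx`, `gy`, `gz` (S),
#'   conductive `mask`, grid `dims`, `voxel_size`, `origin`, `center`,
#'   `n_conductive`.
#' @export
assemble_system <- function(sigma, voxel_size = NULL) {
  if (inherits(sigma, "conductivity_volume")) {
    voxel_size <- sigma$voxel_size
    origin <- sigma$origin
    center <- sigma$center
    s <- sigma$sigma
  } else {
    if (is.null(voxel_size)) stop("voxel_size required for a bare array")
    origin <- c(0, 0, 0)
    center <- NULL
    s <- sigma
  }
  stopifnot(is.array(s), length(dim(s)) == 3L)
  if (any(s < 0)) stop("conductivities must be non-negative")
  mask <- s > 0
  if (!any(mask)) stop("no conductive voxels")
  h <- voxel_size * 1e-3  # face_area / distance = h^2 / h = h (meters)
  d <- dim(s)
  harm <- function(a, b) ifelse(a > 0 & b > 0, 2 * a * b / (a + b), 0)
  gx <- harm(s[-d[1], , , drop = FALSE], s[-1, , , drop = FALSE]) * h
  gy <- harm(s[, -d[2], , drop = FALSE], s[, -1, , drop = FALSE]) * h
  gz <- harm(s[, , -d[3], drop = FALSE], s[, , -1, drop = FALSE]) * h
  comp <- .connected_components(mask)
  if (comp$n > 1L)
    stop("disconnected conductive region: component sizes ",
         paste(comp$sizes, collapse = ", "),
         " (gauge would be ill-defined per component)")
  structure(list(gx = gx, gy = gy, gz = gz, mask = mask, dims = d,
                 voxel_size = voxel_size, origin = origin, center = center,
                 n_conductive = sum(mask)),
            class = "fv_operator")
}

# 6-connected component labelling of a logical mask (vectorized frontier BFS)
.connected_components <- function(mask) {
  d <- dim(mask)
  dilate6 <- function(f) {
    g <- array(FALSE, d)
    g[-1, , ] <- g[-1, , ] | f[-d[1], , ]
    g[-d[1], , ] <- g[-d[1], , ] | f[-1, , ]
    g[, -1, ] <- g[, -1, ] | f[, -d[2], ]
    g[, -d[2], ] <- g[, -d[2], ] | f[, -1, ]
    g[, , -1] <- g[, , -1] | f[, , -d[3]]
    g[, , -d[3]] <- g[, , -d[3]] | f[, , -1]
    g
  }
  unvisited <- mask
  sizes <- integer(0)
  while (any(unvisited)) {
    frontier <- array(FALSE, d)
    frontier[which(unvisited)[1]] <- TRUE
    member <- frontier
    repeat {
      frontier <- dilate6(frontier) & unvisited & !member
      if (!any(frontier)) break
      member <- member | frontier
    }
    sizes <- c(sizes, sum(member))
    unvisited <- unvisited & !member
  }
  list(n = length(sizes), sizes = sizes)
}

#' Apply the finite-volume operator to a potential array
#'
#' @param op An `fv_operator`.
#' @param x 3-D array (or vector of grid length) of potentials.
#' @return 3-D array `A x` (amperes); zero on non-conductive voxels.
#' @export
apply_operator <- function(op, x) {
  .apply_stencil_cpp(as.double(op$gx), as.double(op$gy), as.double(op$gz),
                     as.logical(op$mask), as.double(x), as.integer(op$dims))
}

#' Materialize the operator as a sparse matrix over conductive voxels
#'
#' Useful for structural tests (symmetry, row sums, reciprocity) on small
#' grids; the iterative solver never forms this matrix.
#'
#' @param op An `fv_operator`.
#' @return A symmetric `Matrix::dgCMatrix` of dimension `n_conductive`.
#' @export
as_sparse_operator <- function(op) {
  d <- op$dims
  map <- array(0L, d)
  map[op$mask] <- seq_len(op$n_conductive)
  tri_i <- integer(0); tri_j <- integer(0); tri_x <- numeric(0)
  add_axis <- function(g, off) {
    idx <- which(g > 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    a <- map[idx]
    b <- map[sweep(idx, 2L, off, "+")]
    keep <- a > 0L & b > 0L
    list(a = a[keep], b = b[keep], g = g[g > 0][keep])
  }
  for (ax in 1:3) {
    off <- c(0L, 0L, 0L); off[ax] <- 1L
    t <- add_axis(switch(ax, op$gx, op$gy, op$gz), off)
    if (is.null(t)) next
    tri_i <- c(tri_i, t$a, t$b, t$a, t$b)
    tri_j <- c(tri_j, t$b, t$a, t$a, t$b)
    tri_x <- c(tri_x, -t$g, -t$g, t$g, t$g)
  }
  Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x,
                       dims = rep(op$n_conductive, 2L))
}

#' Discretize a dipole field into balanced monopole currents
#'
#' Each dipole of moment magnitude `q` (A m) and unit orientation `n` becomes
#' a balanced monopole pair at `pos +/- (h/2)*n` with `I = q / d`, `d = h`
#' the center-to-center distance of the pair, so the discrete pair carries
#' exactly the dipole's moment.  Each monopole is spread onto its 8
#' surrounding voxel centers by trilinear weights; for an axis-aligned
#' orientation this deposits `+q/(2h)` and `-q/(2h)` in the two axis
#' neighbors of the dipole voxel.  The half-step arm keeps the discrete
#' source compact (within one voxel of the dipole center), which matters for
#' cortical dipoles lying one thin CSF layer below the dura.  The net
#' injected current is zero per dipole by construction.
#'
#' @param dipoles A `dipole_field`.
#' @param op The `fv_operator` of the grid the currents will drive (supplies
#'   grid geometry and the conductive mask used to validate placements).
#' @return A `current_sources`: list with `I` (3-D array, amperes),
#'   `voxel_size`, `origin`.
#' @export
dipoles_to_currents <- function(dipoles, op) {
  h <- op$voxel_size
  h_m <- h * 1e-3
  d <- op$dims
  pos <- as.matrix(dipoles[, c("x", "y", "z")])
  ori <- as.matrix(dipoles[, c("nx", "ny", "nz")])
  q <- dipoles$magnitude
  I_arr <- array(0, d)
  active <- q > 0
  if (!any(active))
    return(structure(list(I = I_arr, voxel_size = h, origin = op$origin),
                     class = "current_sources"))
  pos <- pos[active, , drop = FALSE]
  ori <- ori[active, , drop = FALSE]
  Imono <- q[active] / h_m
  offenders <- logical(nrow(pos))
  for (sgn in c(1, -1)) {
    pts <- pos + sgn * (h / 2) * ori
    u <- sweep(pts, 2L, op$origin, "-") / h   # continuous voxel coordinate
    if (any(u < 0) || any(sweep(u, 2L, d - 1L, ">")))
      stop("dipole injection point outside the grid")
    i0 <- floor(u)
    fr <- u - i0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- (if (cx) fr[, 1] else 1 - fr[, 1]) *
           (if (cy) fr[, 2] else 1 - fr[, 2]) *
           (if (cz) fr[, 3] else 1 - fr[, 3])
      nz <- w > 0
      if (!any(nz)) next
      ii <- pmin(i0[nz, 1] + cx + 1L, d[1])
      jj <- pmin(i0[nz, 2] + cy + 1L, d[2])
      kk <- pmin(i0[nz, 3] + cz + 1L, d[3])
      lin <- ii + d[1] * (jj - 1L) + d[1] * d[2] * (kk - 1L)
      offenders[nz] <- offenders[nz] | !op$mask[lin]
      acc <- rowsum(sgn * Imono[nz] * w[nz], lin)
      tgt <- as.integer(rownames(acc))
      I_arr[tgt] <- I_arr[tgt] + acc[, 1]
    }
  }
  if (any(offenders))
    stop("dipole injection into non-conductive tissue for dipole(s): ",
         paste(utils::head(which(active)[offenders], 20L), collapse = ", "))
  structure(list(I = I_arr, voxel_size = h, origin = op$origin),
            class = "current_sources")
}

#' Solve for the electric potential
#'
#' Jacobi-preconditioned conjugate-gradient solution of the symmetric
#' positive-semidefinite finite-volume system `A phi = I`; the gauge (the
#' additive constant of the pure-Neumann problem) is fixed to zero mean over
#' conductive voxels by projection at every iteration.
#'
#' @param op An `fv_operator`.
#' @param sources A `current_sources` (must sum to ~0 for solvability).
#' @param tol Relative residual tolerance (default 1e-8).
#' @param max_iter Iteration cap.
#' @return A `potential_volume`: `phi` (3-D array, volts; 0 outside the
#'   conductive mask), `mask`, `iterations`, `relres`, `gauge`,
#'   `voxel_size`, `origin`, `center`.
#' @export
solve_potential <- function(op, sources, tol = 1e-8, max_iter = 20000L) {
  stopifnot(inherits(op, "fv_operator"), inherits(sources, "current_sources"))
  if (!identical(dim(sources$I), op$dims))
    stop("source grid does not match operator grid")
  b <- sources$I
  l1 <- sum(abs(b))
  if (l1 > 0 && abs(sum(b)) > 1e-9 * l1)
    stop("source imbalance: net current ", signif(sum(b), 4),
         " A exceeds 1e-9 of the L1 norm")
  res <- .cg_solve_cpp(as.double(op$gx), as.double(op$gy), as.double(op$gz),
                       as.logical(op$mask), as.double(b),
                       as.integer(op$dims), tol, as.integer(max_iter))
  if (!res$converged)
    stop("conjugate gradients did not converge in ", max_iter,
         " iterations (relative residual ", signif(res$relres, 3), ")")
  phi <- res$phi
  phi[op$mask] <- phi[op$mask] - mean(phi[op$mask])
  structure(list(phi = phi, mask = op$mask, iterations = res$iterations,
                 relres = res$relres, gauge = "zero-mean",
                 voxel_size = op$voxel_size, origin = op$origin,
                 center = op$center),
            class = "potential_volume")
}

#' @export
print.potential_volume <- function(x, ...) {
  cat("Potential volume: ", paste(dim(x$phi), collapse = " x "),
      " grid; CG iterations ", x$iterations,
      ", relative residual ", signif(x$relres, 3), "\n", sep = "")
  invisible(x)
}

#' Face current densities of a solved potential
#'
#' Ohmic face currents `g_f * (phi_i - phi_j)` (amperes, positive along the
#' +axis direction).  Their discrete divergence equals the injected currents.
#'
#' @param op An `fv_operator`.
#' @param potential A `potential_volume`.
#' @return A `flux_field`: list of face-current arrays `fx`, `fy`, `fz`.
#' @export
compute_flux <- function(op, potential) {
  phi <- potential$phi
  d <- op$dims
  fx <- op$gx * (phi[-d[1], , , drop = FALSE] - phi[-1, , , drop = FALSE])
  fy <- op$gy * (phi[, -d[2], , drop = FALSE] - phi[, -1, , drop = FALSE])
  fz <- op$gz * (phi[, , -d[3], drop = FALSE] - phi[, , -1, drop = FALSE])
  structure(list(fx = fx, fy = fy, fz = fz, dims = d), class = "flux_field")
}

#' Discrete divergence of a flux field
#'
#' Per-voxel net outflow (amperes); equals the injected current distribution
#' of the solve within solver tolerance (discrete charge conservation).
#'
#' @param flux A `flux_field` from [compute_flux()].
#' @return 3-D array of net outflow per voxel.
#' @export
flux_divergence <- function(flux) {
  d <- flux$dims
  div <- array(0, d)
  div[-d[1], , ] <- div[-d[1], , ] + flux$fx
  div[-1, , ] <- div[-1, , ] - flux$fx
  div[, -d[2], ] <- div[, -d[2], ] + flux$fy
  div[, -1, ] <- div[, -1, ] - flux$fy
  div[, , -d[3]] <- div[, , -d[3]] + flux$fz
  div[, , -1] <- div[, , -1] - flux$fz
  div
}
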
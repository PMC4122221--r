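#' Concentric-shell conductor specification
#'
#' Geometry and conductivities for the analytic multi-shell sphere solution:
#' shell `s` occupies radii `(radii[s-1], radii[s]]` (innermost shell is the
#' central ball), the exterior is insulating air.
#'
#' @param radii Strictly increasing outer radii in meters.
#' @param conductivities Conductivity (S/m) per shell, innermost first.
#' @return A `shell_spec`.
#' @export
shell_spec <- function(radii, conductivities) {
  stopifnot(length(radii) == length(conductivities), length(radii) >= 1L)
  if (any(diff(radii) <= 0)) stop("shell radii must be strictly increasing")
  if (any(conductivities <= 0)) stop("shell conductivities must be positive")
  structure(list(radii = as.numeric(radii),
                 conductivities = as.numeric(conductivities)),
            class = "shell_spec")
}

#' Quasi-uniform points on a sphere (Fibonacci spiral)
#'
#' @param n Number of points (default 500).
#' @param radius Sphere radius.
#' @return `n` x 3 matrix of Cartesian coordinates.
#' @export
fibonacci_sphere_points <- function(n = 500L, radius = 1) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  s <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(x = s * cos(phi), y = s * sin(phi), z = z)
}

# running Legendre recurrences: returns an environment-style iterator is
# overkill; we just accumulate inside multishell_potential.

#' Analytic potential of a dipole in a layered sphere
#'
#' Truncated Legendre-series solution for a current dipole inside `N`
#' concentric spherical shells of distinct conductivities, with an insulating
#' exterior.  The primary dipole field is expanded in the shell containing the
#' dipole and matched across every interface (continuity of potential and of
#' radial current density); per-shell radial basis functions are normalized by
#' the shell radii so the recursion is stable to high series order.
#'
#' Evaluation points may lie on the outer surface or anywhere inside the
#' conductor at radius greater than the dipole's radius.
#'
#' @param position Dipole position (meters, length 3).
#' @param moment Dipole moment (A m, length 3).
#' @param shells A [shell_spec()].
#' @param points Matrix (m x 3) of evaluation points (meters).
#' @param n_terms Series truncation order (default 60).
#' @param reference `"average"` (subtract the mean over `points`, matching the
#'   common-average referencing applied to solver outputs) or `"none"`.
#' @return Numeric vector of potentials (V), with attribute `converged`
#'   (FALSE if the last term still contributes more than 1e-8 of the running
#'   solution scale).
#' @export
multishell_potential <- function(position, moment, shells, points,
                                 n_terms = 60L,
                                 reference = c("average", "none")) {
  reference <- match.arg(reference)
  stopifnot(inherits(shells, "shell_spec"), n_terms >= 1L)
  points <- matrix(as.numeric(points), ncol = 3L)
  radii <- shells$radii
  sig <- shells$conductivities
  L <- length(radii)
  b <- sqrt(sum(position^2))
  if (any(abs(b - radii) < 1e-12 * radii[L]))
    stop("dipole lies on a shell interface")
  if (b >= radii[L]) stop("dipole must be inside the conductor")
  sD <- findInterval(b, radii) + 1L  # shell containing the dipole

  # dipole-aligned frame
  pmag <- sqrt(sum(moment^2))
  if (pmag == 0) {
    out <- rep(0, nrow(points))
    attr(out, "converged") <- TRUE
    return(out)
  }
  if (b > 0) {
    zhat <- position / b
  } else {
    zhat <- moment / pmag
  }
  pr <- sum(moment * zhat)
  tvec <- moment - pr * zhat
  pt <- sqrt(sum(tvec^2))
  xhat <- if (pt > 1e-14 * pmag) tvec / pt else {
    # any unit vector orthogonal to zhat
    a <- if (abs(zhat[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- a - sum(a * zhat) * zhat
    v / sqrt(sum(v^2))
  }

  rp <- sqrt(rowSums(points^2))
  if (any(rp > radii[L] * (1 + 1e-9)))
    stop("evaluation points must lie inside or on the outer surface")
  if (any(rp <= b))
    stop("evaluation points must lie at radius greater than the dipole radius")
  ps <- findInterval(pmin(rp, radii[L] * (1 - 1e-15)), radii) + 1L
  ct <- pmin(1, pmax(-1, (points %*% zhat)[, 1] / rp))    # cos(theta')
  sc <- (points %*% xhat)[, 1] / rp                       # sin(theta')cos(phi')

  # column layout of the per-degree linear system
  colA <- function(s) if (s == 1L) 1L else 2L * s - 2L
  colB <- function(s) 2L * s - 1L
  ncol_sys <- 2L * L - 1L
  rho <- c(0, radii)[seq_len(L)]  # inner radius of each shell

  fA <- function(s, r, n) (r / radii[s])^n
  fB <- function(s, r, n) (rho[s] / r)^(n + 1)
  # primary-field radial profiles in the dipole shell (per unit channel moment)
  prim_out <- function(r, n, channel) {
    base <- (b / r)^(n - 1) / (4 * pi * sig[sD] * r^2)
    if (channel == "r") n * base else base
  }
  prim_in <- function(r, n, channel) {
    base <- (r / b)^n / (4 * pi * sig[sD] * b^2)
    if (channel == "r") -(n + 1) * base else base
  }
  prim_val <- function(r, n, channel) {
    if (r >= b) prim_out(r, n, channel) else prim_in(r, n, channel)
  }
  prim_dval <- function(r, n, channel) {
    if (r >= b) -(n + 1) / r * prim_out(r, n, channel)
    else n / r * prim_in(r, n, channel)
  }

  solve_coeffs <- function(n, channel) {
    M <- matrix(0, ncol_sys, ncol_sys)
    rhs <- numeric(ncol_sys)
    row <- 0L
    for (i in seq_len(L - 1L)) {
      ri <- radii[i]
      # continuity of potential
      row <- row + 1L
      M[row, colA(i)] <- fA(i, ri, n)
      if (i > 1L) M[row, colB(i)] <- fB(i, ri, n)
      M[row, colA(i + 1L)] <- -fA(i + 1L, ri, n)
      M[row, colB(i + 1L)] <- -fB(i + 1L, ri, n)
      if (sD == i) rhs[row] <- -prim_val(ri, n, channel)
      if (sD == i + 1L) rhs[row] <- prim_val(ri, n, channel)
      # continuity of radial current density
      row <- row + 1L
      M[row, colA(i)] <- sig[i] * n / ri * fA(i, ri, n)
      if (i > 1L) M[row, colB(i)] <- -sig[i] * (n + 1) / ri * fB(i, ri, n)
      M[row, colA(i + 1L)] <- -sig[i + 1L] * n / ri * fA(i + 1L, ri, n)
      M[row, colB(i + 1L)] <- sig[i + 1L] * (n + 1) / ri * fB(i + 1L, ri, n)
      if (sD == i) rhs[row] <- -sig[sD] * prim_dval(ri, n, channel)
      if (sD == i + 1L) rhs[row] <- sig[sD] * prim_dval(ri, n, channel)
    }
    # insulating outer boundary
    row <- row + 1L
    rL <- radii[L]
    M[row, colA(L)] <- n / rL * fA(L, rL, n)
    if (L > 1L) M[row, colB(L)] <- -(n + 1) / rL * fB(L, rL, n)
    if (sD == L) rhs[row] <- -prim_dval(rL, n, channel)
    solve(M, rhs)
  }

  V <- numeric(nrow(points))
  # Legendre recurrences over evaluation points
  Pm2 <- rep(1, length(ct)); Pm1 <- ct          # P_0, P_1
  dPm2 <- rep(0, length(ct)); dPm1 <- rep(1, length(ct))
  last_term <- 0
  for (n in seq_len(n_terms)) {
    if (n == 1L) {
      Pn <- Pm1; dPn <- dPm1
    } else {
      Pn <- ((2 * n - 1) * ct * Pm1 - (n - 1) * Pm2) / n
      dPn <- dPm2 + (2 * n - 1) * Pm1
      Pm2 <- Pm1; Pm1 <- Pn
      dPm2 <- dPm1; dPm1 <- dPn
    }
    term <- numeric(length(V))
    for (channel in c("r", "t")) {
      pm <- if (channel == "r") pr else pt
      if (pm == 0) next
      co <- solve_coeffs(n, channel)
      rad <- numeric(length(V))
      for (s in unique(ps)) {
        w <- ps == s
        r <- rp[w]
        val <- co[colA(s)] * fA(s, r, n)
        if (s > 1L) val <- val + co[colB(s)] * fB(s, r, n)
        if (s == sD) {
          base <- (b / r)^(n - 1) / (4 * pi * sig[sD] * r^2)
          val <- val + (if (channel == "r") n * base else base)
        }
        rad[w] <- val
      }
      ang <- if (channel == "r") Pn else dPn * sc
      term <- term + pm * rad * ang
    }
    V <- V + term
    last_term <- max(abs(term))
  }
  scale <- max(abs(V), .Machine$double.eps)
  converged <- last_term <= 1e-8 * scale
  if (reference == "average") V <- V - mean(V)
  attr(V, "converged") <- converged
  V
}

#' Magnitude ratio of surface potentials between two layered-sphere models
#'
#' Root-sum-square surface potential of the layer-replaced model divided by
#' that of the layered model (a MAG-style ratio): values above 1 mean the
#' replaced model produces larger surface potentials, i.e. the original layer
#' attenuates.
#'
#' @param shells_with_layer,shells_layer_replaced Two [shell_spec()]s with
#'   identical radii differing in at most one shell's conductivity.
#' @param position,moment Dipole position (m) and moment (A m).
#' @param points Surface evaluation points (m); default 500 Fibonacci points
#'   on the outer sphere.
#' @param n_terms Series truncation order.
#' @return The ratio (dimensionless).
#' @export
attenuation_ratio <- function(shells_with_layer, shells_layer_replaced,
                              position, moment, points = NULL, n_terms = 60L) {
  a <- shells_with_layer; bsp <- shells_layer_replaced
  if (!isTRUE(all.equal(a$radii, bsp$radii)))
    stop("mismatched geometry: shell radii differ")
  ndiff <- sum(a$conductivities != bsp$conductivities)
  if (ndiff > 1L)
    stop("the two specs must differ in at most one shell's conductivity")
  if (is.null(points))
    points <- fibonacci_sphere_points(500L, a$radii[length(a$radii)])
  va <- multishell_potential(position, moment, a, points, n_terms)
  vb <- multishell_potential(position, moment, bsp, points, n_terms)
  sqrt(sum(vb^2) / sum(va^2))
}
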
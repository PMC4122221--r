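#' Construct a voxel model
#'
#' A `voxel_model` is the geometric substrate of every simulation: a 3-D grid
#' of tissue labels with an isotropic voxel size (mm) and an origin giving the
#' mm position of the center of voxel (1,1,1).
#'
#' @param labels Integer 3-D array of indices into `tissues`.
#' @param tissues Character vector of tissue names the indices refer to.
#' @param voxel_size Edge length of a voxel in mm (isotropic).
#' @param origin Length-3 mm offset of the center of voxel (1,1,1).
#' @param center Optional phantom center in mm (used for radial fallbacks,
#'   angular point matching and default cap planes).
#' @return A `voxel_model`.
#' @export
voxel_model <- function(labels, tissues, voxel_size, origin = c(0, 0, 0),
                        center = NULL) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L,
            voxel_size > 0, length(origin) == 3L)
  if (any(dim(labels) < 8L))
    stop("grid dimensions must be at least 8 per axis")
  bad <- stats::na.omit(setdiff(unique(as.integer(labels)), seq_along(tissues)))
  if (length(bad))
    stop("label codes outside tissue list: ", paste(bad, collapse = ", "))
  structure(
    list(labels = labels, tissues = tissues,
         voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin),
         center = if (is.null(center)) NULL else as.numeric(center)),
    class = "voxel_model")
}

#' @export
print.voxel_model <- function(x, ...) {
  cat("Voxel model: ", paste(dim(x$labels), collapse = " x "),
      " grid, ", x$voxel_size, " mm voxels\n", sep = "")
  cnt <- tissue_counts(x)
  cnt <- cnt[cnt > 0]
  for (nm in names(cnt)) cat(sprintf("  %-16s %d\n", nm, cnt[[nm]]))
  invisible(x)
}

# integer code of a tissue name within a model (NA if the model does not know it)
label_code <- function(model, tissue) {
  match(tissue, model$tissues)
}

#' Per-tissue voxel counts
#'
#' @param model A `voxel_model`.
#' @return Named integer vector over the model's tissue list.
#' @export
tissue_counts <- function(model) {
  tab <- tabulate(model$labels, nbins = length(model$tissues))
  names(tab) <- model$tissues
  tab
}

#' Voxel-center coordinates
#'
#' @param model A `voxel_model`.
#' @param which Optional integer matrix of (i,j,k) indices (1-based); default
#'   all voxels in array order.
#' @return Matrix with columns x, y, z in mm.
#' @export
voxel_centers <- function(model, which = NULL) {
  d <- dim(model$labels)
  if (is.null(which)) {
    which <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                   k = seq_len(d[3])))
  }
  sweep((which - 1) * model$voxel_size, 2L, model$origin, "+",
        check.margin = FALSE)
}

# grid of distances (mm) from `center` to every voxel center, plus the
# direction angles needed by the corrugation; returned as a list of arrays
.radial_geometry <- function(dims, voxel_size, origin, center) {
  ax <- function(n, o, c) o + (seq_len(n) - 1) * voxel_size - c
  dx <- ax(dims[1], origin[1], center[1])
  dy <- ax(dims[2], origin[2], center[2])
  dz <- ax(dims[3], origin[3], center[3])
  X <- array(dx, dims)
  Y <- array(rep(dy, each = dims[1]), dims)
  Z <- array(rep(dz, each = dims[1] * dims[2]), dims)
  R <- sqrt(X^2 + Y^2 + Z^2)
  list(X = X, Y = Y, Z = Z, R = R)
}

# smooth angular corrugation field delta(theta, phi) = A sin(k theta) cos(k phi);
# vanishes at the poles for integer k, so the azimuthal discontinuity is benign
corrugation_delta <- function(geom, amplitude, frequency) {
  if (amplitude == 0) return(0)
  R <- pmax(geom$R, .Machine$double.eps)
  theta <- acos(pmin(1, pmax(-1, geom$Z / R)))
  phi <- atan2(geom$Y, geom$X)
  amplitude * sin(frequency * theta) * cos(frequency * phi)
}

#' Default shell radii for the head phantom
#'
#' Nested-shell outer radii (mm) for a desk-scale head phantom: white matter,
#' gray matter (cortex), CSF, dura, hard skull, scalp.  The dura is one voxel
#' layer thick by default (its anatomical thickness of roughly 0.8--0.9 mm is
#' below typical voxel sizes, so a single voxel layer is the thinnest
#' representable and slightly overestimating choice); the CSF outer radius
#' adapts so that the dura band spans `dura_thickness_vox` voxels.
#'
#' The CSF shell is 4 mm thick so that the discrete cortical sources (whose
#' trilinear support extends up to one voxel beyond the corrugated gray
#' surface) always remain below the dura: a validity requirement of the
#' source model, not a tunable.
#'
#' @param voxel_size Voxel edge in mm.
#' @param dura_thickness_vox Dura thickness in voxels (default 1).
#' @return Named numeric vector of increasing outer radii (mm).
#' @export
default_shell_radii <- function(voxel_size = 2, dura_thickness_vox = 1) {
  csf_outer <- 48
  dura_outer <- csf_outer + dura_thickness_vox * voxel_size
  c(white = 40, gray = 44, csf = csf_outer,
    dura = dura_outer, skull_hard = dura_outer + 6, scalp = dura_outer + 12)
}

#' Build a nested-shell head phantom
#'
#' Voxelizes concentric tissue shells (innermost to outermost order given by
#' `radii` names, wrapped in external air).  A voxel's label is determined by
#' the radius band its center falls in.  An optional angular corrugation
#' perturbs the two cortical interfaces (white/gray and gray/CSF) by the same
#' smooth field `amplitude * sin(f*theta) * cos(f*phi)`, emulating
#' gyri/sulci-like folding while keeping the cortical ribbon thickness and all
#' outer shells unchanged.
#'
#' @param radii Named numeric vector of strictly increasing outer radii (mm),
#'   innermost first, e.g. `c(white=40, gray=44, csf=46, dura=48,
#'   skull_hard=54, scalp=60)`.
#' @param voxel_size Voxel edge in mm.
#' @param grid_shape Optional integer length-3 grid dimensions; default is the
#'   smallest odd cube holding the outer radius plus a two-voxel air margin.
#' @param corrugation List with `amplitude` (mm) and `frequency` (angular
#'   oscillation count); amplitude must be smaller than the CSF shell
#'   thickness so nesting is preserved.
#' @param center Phantom center in mm; default the central voxel center.
#' @return A `voxel_model` whose tissue list is `tissue_labels()`.
#' @export
build_shell_phantom <- function(radii, voxel_size = 2, grid_shape = NULL,
                                corrugation = list(amplitude = 0, frequency = 8),
                                center = NULL) {
  if (is.null(names(radii)) || any(!nzchar(names(radii))))
    stop("radii must be a named vector (innermost tissue first)")
  if (any(diff(radii) <= 0))
    stop("configuration error: shell radii must be strictly increasing")
  unknown <- setdiff(names(radii), tissue_labels())
  if (length(unknown)) stop("unknown tissues in radii: ",
                            paste(unknown, collapse = ", "))
  amp <- corrugation$amplitude %||% 0
  freq <- corrugation$frequency %||% 8
  ci <- match(c("gray", "csf"), names(radii))
  if (amp > 0) {
    if (anyNA(ci))
      stop("corrugation requires gray and csf shells")
    if (amp >= radii[ci[2]] - radii[ci[1]])
      stop("configuration error: corrugation amplitude must be below the CSF",
           " shell thickness (", radii[ci[2]] - radii[ci[1]], " mm)")
  }
  outer_r <- radii[length(radii)]
  if (is.null(grid_shape)) {
    n_half <- ceiling(outer_r / voxel_size) + 2L
    grid_shape <- rep(2L * n_half + 1L, 3L)
  }
  grid_shape <- as.integer(grid_shape)
  origin <- c(0, 0, 0)
  if (is.null(center)) center <- (grid_shape - 1) / 2 * voxel_size
  geom <- .radial_geometry(grid_shape, voxel_size, origin, center)
  delta <- corrugation_delta(geom, amp, freq)

  all_t <- tissue_labels()
  lab <- array(match("air_external", all_t), grid_shape)
  # assign outermost-first so inner thresholds overwrite
  wg <- match(names(radii), c("white", "gray"))
  for (s in rev(seq_along(radii))) {
    thr <- radii[s] + if (!is.na(wg[s])) delta else 0
    lab[geom$R < thr] <- match(names(radii)[s], all_t)
  }
  model <- voxel_model(lab, all_t, voxel_size, origin, center)
  # outermost layer must be air on all six grid faces
  d <- grid_shape
  air <- match("air_external", all_t)
  faces <- c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
             lab[, , 1], lab[, , d[3]])
  if (any(faces != air))
    stop("geometry error: phantom touches the grid boundary; enlarge the grid")
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relabel every voxel of one tissue as another
#'
#' Used for the dura-substitution experiment (relabel `dura` as `csf` so the
#' dura compartment takes CSF conductivity on realization).  Relabeling an
#' absent tissue is a no-op; total voxel count is conserved.
#'
#' @param model A `voxel_model`.
#' @param from,to Tissue names.
#' @return A modified copy of `model`.
#' @export
replace_tissue <- function(model, from, to) {
  cf <- label_code(model, from)
  ct <- label_code(model, to)
  if (is.na(cf) || is.na(ct))
    stop("unknown tissue label: ", if (is.na(cf)) from else to)
  model$labels[model$labels == cf] <- ct
  model
}

#' Realize a per-voxel conductivity volume
#'
#' Maps each voxel's tissue label to its SI conductivity (S/m).  Both air
#' compartments are realized as perfect insulators (0 S/m) --- the finite
#' volume operator carries no current into air --- while their literature
#' values remain available in the table as metadata.  `overrides` (named
#' vector, S/m) are applied last and are how the skull-conductivity
#' sensitivity experiment perturbs single tissues.
#'
#' @param model A `voxel_model`.
#' @param table A `conductivity_table`.
#' @param overrides Named numeric vector of tissue -> conductivity (S/m).
#' @return A `conductivity_volume`: list with `sigma` (3-D array, S/m),
#'   `voxel_size`, `origin`, `center`.
#' @export
realize_conductivity <- function(model, table = default_conductivity_table(),
                                 overrides = NULL) {
  present <- model$tissues[sort(unique(as.integer(model$labels)))]
  value <- numeric(length(model$tissues))
  names(value) <- model$tissues
  mapped <- model$tissues %in% table$tissue
  value[mapped] <- tissue_conductivity(table, model$tissues[mapped])
  value[model$tissues %in% c("air_external", "air_internal")] <- 0
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a named vector")
    bad <- setdiff(names(overrides), model$tissues)
    if (length(bad)) stop("override for unknown tissue: ",
                          paste(bad, collapse = ", "))
    value[names(overrides)] <- overrides
    mapped[match(names(overrides), model$tissues)] <- TRUE
  }
  unmapped <- setdiff(present, c(model$tissues[mapped],
                                 "air_external", "air_internal"))
  if (length(unmapped))
    stop("validation error: no conductivity for label(s): ",
         paste(unmapped, collapse = ", "))
  sigma <- array(value[as.integer(model$labels)], dim(model$labels))
  structure(list(sigma = sigma, voxel_size = model$voxel_size,
                 origin = model$origin, center = model$center),
            class = "conductivity_volume")
}
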
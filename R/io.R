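#' Read a label volume from NIfTI
#'
#' Ingests a user-supplied segmentation (integer labels) as a `voxel_model`.
#' Integer values are mapped to tissue names via `label_map`; unmapped values
#' are an error (naming them), and several integers may map to one tissue.
#' Near-anisotropic voxels (spread > 10%) raise a warning and the mean edge
#' is used.
#'
#' @param path NIfTI file (.nii / .nii.gz).
#' @param label_map Named integer vector: `c(white = 1, gray = 2, ...)`,
#'   names from [tissue_labels()].
#' @return A `voxel_model`.
#' @export
read_label_volume <- function(path, label_map) {
  if (is.null(names(label_map)) || any(!nzchar(names(label_map))))
    stop("label_map must be a named integer vector (tissue = integer)")
  bad_t <- setdiff(names(label_map), tissue_labels())
  if (length(bad_t)) stop("unknown tissue in label_map: ",
                          paste(bad_t, collapse = ", "))
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)[1:3]
  if (diff(range(pd)) > 0.1 * mean(pd))
    warning("voxel anisotropy exceeds 10%; using the mean edge length")
  vals <- as.integer(round(img))
  unmapped <- setdiff(unique(vals), as.integer(label_map))
  if (length(unmapped))
    stop("unmapped integer label(s) in volume: ",
         paste(sort(unmapped), collapse = ", "))
  all_t <- tissue_labels()
  lut_codes <- match(names(label_map), all_t)
  lab <- array(lut_codes[match(vals, as.integer(label_map))], dim(img))
  voxel_model(lab, all_t, mean(pd))
}

#' Write a label volume as NIfTI
#'
#' Inverse of [read_label_volume()]: writes integer labels (per `label_map`,
#' default the tissue's code in the model's tissue list) with the voxel size
#' in the header.
#'
#' @param model A `voxel_model`.
#' @param path Output path (.nii or .nii.gz).
#' @param label_map Optional named integer vector tissue -> integer.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(model, path, label_map = NULL) {
  if (is.null(label_map)) {
    vals <- as.integer(model$labels)
  } else {
    idx <- match(model$tissues[as.integer(model$labels)], names(label_map))
    if (anyNA(idx))
      stop("label_map misses tissue(s): ",
           paste(setdiff(model$tissues[as.integer(model$labels)],
                         names(label_map)), collapse = ", "))
    vals <- as.integer(label_map)[idx]
  }
  img <- array(vals, dim(model$labels))
  nif <- RNifti::asNifti(img)
  RNifti::pixdim(nif) <- rep(model$voxel_size, 3)
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' Write a scalar volume (potential, conductivity, flux magnitude) as NIfTI
#'
#' @param values 3-D numeric array aligned with the model grid.
#' @param voxel_size Voxel edge, mm.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scalar_volume <- function(values, voxel_size, path) {
  nif <- RNifti::asNifti(values)
  RNifti::pixdim(nif) <- rep(voxel_size, 3)
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' Render a top-view contour map of a surface potential map
#'
#' Projects the points of a (typically capped) surface map onto the x-y plane
#' viewed from above, bins them onto a regular raster, and writes a filled
#' image with contour lines.  Anterior (+y) is up and subject-left is
#' plot-left.  A shared `zlim` across panels gives comparable color scales.
#'
#' @param map A `surface_map`.
#' @param path Output image path (.png).
#' @param zlim Color-scale limits (V); default symmetric about 0 for this
#'   map.  Pass the same value for every compared panel.
#' @param n_grid Raster resolution (default 80).
#' @param title Plot title.
#' @return Invisibly, a list with the `zlim` used and the raster.
#' @export
render_contour_map <- function(map, path, zlim = NULL, n_grid = 80L,
                               title = attr(map, "surface")) {
  if (nrow(map) == 0L) stop("cannot render an empty surface map")
  gx <- seq(min(map$x), max(map$x), length.out = n_grid)
  gy <- seq(min(map$y), max(map$y), length.out = n_grid)
  ix <- findInterval(map$x, gx, all.inside = TRUE)
  iy <- findInterval(map$y, gy, all.inside = TRUE)
  acc <- tapply(map$potential, list(factor(ix, levels = seq_len(n_grid)),
                                    factor(iy, levels = seq_len(n_grid))),
                mean)
  z <- matrix(as.numeric(acc), n_grid, n_grid)
  if (is.null(zlim)) {
    m <- max(abs(map$potential))
    zlim <- c(-m, m)
  }
  z[!is.na(z)] <- pmin(pmax(z[!is.na(z)], zlim[1]), zlim[2])
  grDevices::png(path, width = 700, height = 700)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(gx, gy, z, col = pal, zlim = zlim, asp = 1,
                  xlab = "x (mm)  [subject left = plot left]",
                  ylab = "y (mm)  [anterior up]", main = title,
                  useRaster = FALSE)
  if (any(!is.na(z)) && diff(range(z, na.rm = TRUE)) > 0)
    graphics::contour(gx, gy, z, add = TRUE, nlevels = 8,
                      drawlabels = FALSE)
  invisible(list(zlim = zlim, raster = z, x = gx, y = gy))
}

#' Write a run manifest
#'
#' Records the configuration, seeds, package version, input/output paths and
#' a timestamp as JSON, sufficient to reproduce the run; written atomically
#' (temp file + rename).
#'
#' @param path Output JSON path.
#' @param config An `experiment_config` (the conductivity table is embedded
#'   as a data frame).
#' @param seeds Integer seeds used.
#' @param files Named list/vector of produced file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seeds, files = list()) {
  cfg <- unclass(config)
  cfg$table <- as.data.frame(cfg$table)
  manifest <- list(
    package = "durasim",
    version = as.character(utils::packageVersion("durasim")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seeds = seeds,
    config = cfg,
    config_hash = .config_hash(cfg),
    files = files)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  file.rename(tmp, path)
  invisible(path)
}

# order-stable hash of the serialized config (no digest dependency)
.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                        dataframe = "rows")
  raw <- utf8ToInt(as.character(s))
  h <- 5381
  for (v in raw) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Read an experiment configuration from YAML or JSON
#'
#' Single-document config with keys matching the arguments of
#' [experiment_config()]; unknown keys are an error (this protects against
#' silently misspelled conductivity overrides or solver settings).
#'
#' @param path YAML (.yml/.yaml) or JSON (.json) file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$radii)) raw$radii <- unlist(raw$radii)
  if (!is.null(raw$table) && is.character(raw$table))
    raw$table <- read_conductivity_csv(raw$table)
  do.call(experiment_config, raw)
}
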
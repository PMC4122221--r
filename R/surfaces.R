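#' Extract a tissue-interface potential map
#'
#' Collects every voxel labeled `tissue` that has at least one 6-neighbor
#' labeled `neighbor`, with its solved potential.  The surface belongs to the
#' named tissue's voxels (potentials are sampled just inside that tissue), so
#' e.g. the outer dura surface is `(dura, skull_hard)`, the inner dura surface
#' `(dura, csf)`, and the scalp surface `(scalp, air_external)`.
#'
#' @param model A `voxel_model`.
#' @param potential A `potential_volume` solved on the same grid.
#' @param tissue Tissue whose voxels carry the surface.
#' @param neighbor Partner tissue across the interface.
#' @return A `surface_map`: data frame `i,j,k,x,y,z,potential` with
#'   attributes `surface` (name), `referenced` (logical), `center`.
#' @export
extract_interface <- function(model, potential, tissue, neighbor) {
  if (identical(tissue, neighbor))
    stop("empty interface: a tissue has no interface with itself")
  ct <- label_code(model, tissue)
  cn <- label_code(model, neighbor)
  if (is.na(ct) || is.na(cn))
    stop("unknown tissue: ", if (is.na(ct)) tissue else neighbor)
  if (!identical(dim(model$labels), dim(potential$phi)))
    stop("potential grid does not match model grid")
  d <- dim(model$labels)
  is_t <- model$labels == ct
  is_n <- model$labels == cn
  adj <- array(FALSE, d)
  adj[-d[1], , ] <- adj[-d[1], , ] | is_n[-1, , ]
  adj[-1, , ] <- adj[-1, , ] | is_n[-d[1], , ]
  adj[, -d[2], ] <- adj[, -d[2], ] | is_n[, -1, ]
  adj[, -1, ] <- adj[, -1, ] | is_n[, -d[2], ]
  adj[, , -d[3]] <- adj[, , -d[3]] | is_n[, , -1]
  adj[, , -1] <- adj[, , -1] | is_n[, , -d[3]]
  sel <- which(is_t & adj)
  if (length(sel) == 0L)
    stop("empty interface between ", tissue, " and ", neighbor)
  ijk <- arrayInd(sel, d)
  pos <- voxel_centers(model, ijk)
  out <- data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                    x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    potential = potential$phi[sel])
  attr(out, "surface") <- paste0(tissue, "|", neighbor)
  attr(out, "referenced") <- FALSE
  attr(out, "center") <- model$center
  class(out) <- c("surface_map", "data.frame")
  out
}

#' Common-average reference a surface map
#'
#' Shifts potentials by minus their mean so the map averages to zero;
#' idempotent, and preserves all pairwise potential differences.
#'
#' @param map A `surface_map`.
#' @return The referenced `surface_map`.
#' @export
apply_average_reference <- function(map) {
  if (nrow(map) == 0L) stop("cannot reference an empty surface map")
  map$potential <- map$potential - mean(map$potential)
  attr(map, "referenced") <- TRUE
  map
}

#' Restrict a surface map to points above a horizontal plane
#'
#' Retains points with `z >= z_cut` (the phantom analog of "above eye
#' level").  Re-referencing is not automatic: the caller decides whether to
#' reference before or after capping (the experiments cap first, then
#' average-reference over the retained points).
#'
#' @param map A `surface_map`.
#' @param z_cut Cut plane height in mm; default the phantom center plane
#'   (upper hemisphere).
#' @return The capped `surface_map`.
#' @export
cap_above_plane <- function(map, z_cut = NULL) {
  if (is.null(z_cut)) {
    ctr <- attr(map, "center")
    if (is.null(ctr)) stop("no phantom center stored; supply z_cut")
    z_cut <- ctr[3]
  }
  keep <- map$z >= z_cut
  if (!any(keep)) stop("empty surface map after capping at z = ", z_cut)
  at <- attributes(map)
  out <- map[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "surface") <- at$surface
  attr(out, "referenced") <- at$referenced
  attr(out, "center") <- at$center
  out
}

#' Pair two surface maps by nearest angular position
#'
#' For each point of `map_a`, finds the point of `map_b` with the closest
#' angular direction from the phantom center.  Used to compare potentials on
#' nested surfaces (inner vs outer dura, inner vs outer skull) that have
#' different voxel counts.
#'
#' @param map_a,map_b `surface_map`s from the same phantom.
#' @param center Phantom center (mm); default the stored center.
#' @return Data frame with `potential_a`, `potential_b` (matched), and the
#'   matched index `index_b`.
#' @export
match_surface_points <- function(map_a, map_b, center = NULL) {
  if (is.null(center)) center <- attr(map_a, "center")
  if (is.null(center)) stop("no phantom center available")
  dirs <- function(m) {
    v <- cbind(m$x - center[1], m$y - center[2], m$z - center[3])
    n <- sqrt(rowSums(v^2))
    n[n < 1e-12] <- 1
    v / n
  }
  da <- dirs(map_a)
  db <- dirs(map_b)
  nb <- nrow(db)
  idx <- integer(nrow(da))
  chunk <- max(1L, floor(2e6 / nb))
  for (s in seq(1L, nrow(da), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(da))
    idx[s:e] <- max.col(da[s:e, , drop = FALSE] %*% t(db), ties.method = "first")
  }
  data.frame(potential_a = map_a$potential,
             potential_b = map_b$potential[idx],
             index_b = idx)
}

#' Write a surface map as CSV
#'
#' Columns: `i,j,k` (voxel index), `x_mm,y_mm,z_mm`, `potential_V`,
#' `surface_name`.
#'
#' @param map A `surface_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(map, path) {
  df <- data.frame(i = map$i, j = map$j, k = map$k,
                   x_mm = map$x, y_mm = map$y, z_mm = map$z,
                   potential_V = map$potential,
                   surface_name = attr(map, "surface"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
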
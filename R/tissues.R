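#' Canonical head-tissue labels
#'
#' The full set of tissue identities known to the package.  Shell phantoms use
#' the subset `white`, `gray`, `csf`, `dura`, `skull_hard`, `scalp` plus
#' `air_external`; user-supplied segmentations may carry any of the others
#' (basal ganglia, blood, cerebellum, corpus callosum, eye, fat, muscle,
#' salivary glands, soft tissue, thalamus, soft skull, internal air).
#'
#' @return Character vector of tissue names.
#' @export
tissue_labels <- function() {
  c("air_external", "air_internal", "scalp", "fat", "muscle",
    "skull_hard", "skull_soft", "dura", "csf", "gray", "white",
    "basal_ganglia", "blood", "cerebellum", "corpus_callosum",
    "eye", "salivary_glands", "soft_tissue", "thalamus")
}

# Literature head-tissue resistivities (Ohm cm) with lower/upper bounds and the
# conventionally quoted conductivity in S/cm.  For air_external the quoted
# conductivity (1e-6 S/cm) is not the reciprocal of the quoted resistivity;
# it is kept verbatim as printed_conductivity_S_cm and flagged, while the
# reciprocal is used for the derived columns.  Both airs are treated as perfect
# insulators by the solver regardless (see assemble_system), so these entries
# are metadata only.
.tissue_resistivity_data <- function() {
  rows <- list(
    #            tissue            mean     lower    upper   printed S/cm
    list("air_internal",           5e4,     5e4,     1e5,    2e-5),
    list("air_external",           1e5,     1e5,     1e5,    1e-6),
    list("basal_ganglia",          700,     700,     700,    1.42e-3),
    list("blood",                  160,     80,      240,    6.25e-3),
    list("white",                  700,     350,     1050,   1.42e-3),
    list("gray",                   300,     150,     450,    3.334e-3),
    list("cerebellum",             650,     325,     975,    1.54e-3),
    list("csf",                    65,      32.5,    97.5,   1.54e-2),
    list("corpus_callosum",        834,     834,     834,    1.199e-3),
    list("dura",                   1667,    1000,    5000,   6e-4),
    list("eye",                    200,     100,     400,    5e-3),
    list("fat",                    2500,    1250,    5000,   4e-4),
    list("muscle",                 1000,    200,     1800,   1e-3),
    list("salivary_glands",        576,     576,     576,    1.74e-3),
    list("scalp",                  230,     115,     345,    4.35e-3),
    list("skull_hard",             16000,   8000,    40000,  6.25e-5),
    list("skull_soft",             2500,    1250,    3750,   4e-4),
    list("soft_tissue",            500,     250,     750,    2e-3),
    list("thalamus",               112,     112,     112,    8.93e-3)
  )
  data.frame(
    tissue = vapply(rows, `[[`, "", 1L),
    mean_resistivity = vapply(rows, `[[`, 0, 2L),
    lower_resistivity = vapply(rows, `[[`, 0, 3L),
    upper_resistivity = vapply(rows, `[[`, 0, 4L),
    printed_conductivity_S_cm = vapply(rows, `[[`, 0, 5L),
    stringsAsFactors = FALSE
  )
}

#' Build a conductivity table from resistivity entries
#'
#' Converts tissue resistivities (Ohm cm) into conductivities, adding a
#' `mean_conductivity_S_cm` column (the reciprocal of the mean resistivity)
#' and its SI equivalent `conductivity_S_m` (S/cm multiplied by 100).  Lower
#' and upper resistivity bounds are propagated unchanged.
#'
#' @param table_rows Data frame with columns `tissue`, `mean_resistivity`,
#'   and optionally `lower_resistivity`, `upper_resistivity` (Ohm cm) and
#'   `printed_conductivity_S_cm` (a conventionally quoted S/cm value; kept for
#'   reference and never recomputed).
#' @return A `conductivity_table` (data frame subclass) with one row per
#'   tissue.
#' @export
conductivity_from_table <- function(table_rows) {
  stopifnot(is.data.frame(table_rows),
            all(c("tissue", "mean_resistivity") %in% names(table_rows)))
  if (anyDuplicated(table_rows$tissue))
    stop("duplicate tissue entries in conductivity table")
  if (any(!is.finite(table_rows$mean_resistivity)) ||
      any(table_rows$mean_resistivity <= 0))
    stop("resistivities must be positive and finite")
  tab <- table_rows
  if (is.null(tab$lower_resistivity)) tab$lower_resistivity <- tab$mean_resistivity
  if (is.null(tab$upper_resistivity)) tab$upper_resistivity <- tab$mean_resistivity
  if (any(tab$lower_resistivity > tab$mean_resistivity) ||
      any(tab$upper_resistivity < tab$mean_resistivity))
    stop("resistivity bounds must bracket the mean")
  tab$mean_conductivity_S_cm <- 1 / tab$mean_resistivity
  tab$conductivity_S_m <- tab$mean_conductivity_S_cm * 100
  class(tab) <- c("conductivity_table", "data.frame")
  tab
}

#' Default head-tissue conductivity table
#'
#' The package's built-in 19-tissue resistivity/conductivity table compiled
#' from the literature.  Units: resistivity Ohm cm, conductivity S/cm and S/m.
#' Note that the quoted external-air conductivity (1e-6 S/cm) is an
#' intentionally insulating convention, not the reciprocal of its quoted
#' resistivity; the solver treats both air compartments as perfect insulators.
#'
#' @return A `conductivity_table`.
#' @export
default_conductivity_table <- function() {
  conductivity_from_table(.tissue_resistivity_data())
}

#' @export
print.conductivity_table <- function(x, ...) {
  cat("Conductivity table:", nrow(x), "tissues\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Look up the SI conductivity of one tissue
#'
#' @param table A `conductivity_table`.
#' @param tissue Tissue name.
#' @return Conductivity in S/m.
#' @export
tissue_conductivity <- function(table, tissue) {
  i <- match(tissue, table$tissue)
  if (anyNA(i)) stop("tissue not in table: ", paste(tissue[is.na(i)], collapse = ", "))
  table$conductivity_S_m[i]
}

#' Read / write a conductivity table as CSV
#'
#' The CSV mirrors the literature table columns: `tissue`,
#' `mean_resistivity`, `lower_resistivity`, `upper_resistivity` (Ohm cm) and
#' optionally `printed_conductivity_S_cm`.
#'
#' @param path File path.
#' @return `read_conductivity_csv` returns a `conductivity_table`;
#'   `write_conductivity_csv` returns `path` invisibly.
#' @export
read_conductivity_csv <- function(path) {
  conductivity_from_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_conductivity_csv
#' @param table A `conductivity_table` to serialize.
#' @export
write_conductivity_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
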
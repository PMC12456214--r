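#' Equivalent spherical diameter
#'
#' Diameter of the sphere with the same volume as the cell,
#' `d = (6 V / pi)^(1/3)` (equivalently `2 * (3V / 4pi)^(1/3)`).
#'
#' @param volume cell volume(s) in cubic micrometres; must be positive.
#' @return diameter(s) in micrometres.
#' @export
equivalent_diameter <- function(volume) {
  if (!is.numeric(volume) || any(!is.finite(volume)) || any(volume <= 0))
    stop("`volume` must be positive and finite", call. = FALSE)
  (6 * volume / pi)^(1 / 3)
}

#' Sphericity
#'
#' Wadell's sphericity `psi = (36 pi V^2)^(1/3) / A`: the ratio of the
#' surface area of the volume-equivalent sphere to the measured surface
#' area. Equals 1 for a perfect sphere, lower for angular cells, and is
#' invariant under uniform scaling (`V -> k^3 V`, `A -> k^2 A`).
#'
#' @param volume volume(s), cubic micrometres; positive.
#' @param surface surface area(s), square micrometres; positive.
#' @return dimensionless sphericity value(s).
#' @export
sphericity <- function(volume, surface) {
  if (!is.numeric(volume) || any(!is.finite(volume)) || any(volume <= 0))
    stop("`volume` must be positive and finite", call. = FALSE)
  if (!is.numeric(surface) || any(!is.finite(surface)) || any(surface <= 0))
    stop("`surface` must be positive and finite", call. = FALSE)
  (36 * pi * volume^2)^(1 / 3) / surface
}

#' Measure every cell of a label stack
#'
#' Computes, per label: voxel count, volume (count x voxel volume), surface
#' area (multi-directional Crofton estimator, 13 directions with
#' solid-angle weights, physical spacing; out-of-stack neighbours count as
#' background so surfaces are closed at the faces), equivalent spherical
#' diameter, sphericity, voxel-centre centroid in physical coordinates
#' (0-based indices scaled by spacing), and whether the label touches any
#' of the six stack faces.
#'
#' Sphericity of very small digitised objects can slightly exceed 1; values
#' are reported unclamped and flagged via `sphericity_gt1`.
#'
#' @param labels a `label_stack`.
#' @param metadata named list of per-sample metadata copied onto every row
#'   (e.g. `sample_id`, `tissue`, `condition`, `sex`, `body_weight`).
#' @param surface compute surfaces and sphericities (set `FALSE` for
#'   size-only studies; the columns are then `NA`).
#' @return a cell table: one `data.frame` row per non-empty label, with a
#'   `provenance` attribute recording spacing and estimator.
#' @export
measure_regions <- function(labels, metadata = list(), surface = TRUE) {
  stopifnot(inherits(labels, "label_stack"))
  d <- stack_dim(labels$labels)
  sp <- labels$spacing
  st <- cpp_region_stats(labels$labels, d)
  k <- length(st$count)
  keep <- which(st$count > 0)
  vx <- voxel_volume(sp)
  vol <- st$count[keep] * vx
  if (surface && k > 0) {
    areas <- cpp_crofton_areas(labels$labels, d, sp, crofton_dirs(),
                               crofton_weights(sp))[keep]
    sph <- sphericity(vol, areas)
  } else {
    areas <- rep(NA_real_, length(keep))
    sph <- rep(NA_real_, length(keep))
  }
  tab <- data.frame(
    label_id = keep,
    voxel_count = st$count[keep],
    volume = vol,
    surface = areas,
    equivalent_diameter = if (length(keep)) equivalent_diameter(vol) else numeric(0),
    sphericity = sph,
    sphericity_gt1 = !is.na(sph) & sph > 1,
    centroid_z = st$sum_z[keep] / st$count[keep] * sp[1],
    centroid_y = st$sum_y[keep] / st$count[keep] * sp[2],
    centroid_x = st$sum_x[keep] / st$count[keep] * sp[3],
    touches_border = st$border[keep]
  )
  for (nm in names(metadata)) tab[[nm]] <- metadata[[nm]]
  attr(tab, "provenance") <- list(
    spacing = sp, surface_estimator = if (surface) "crofton13" else NA_character_,
    package_version = as.character(packageVersion("adipo3d")))
  tab
}

#' Per-sample morphometry summaries
#'
#' Collapses a (QC-filtered) cell table to one row per sample: mean
#' equivalent diameter, mean sphericity, cell count, plus the sample
#' metadata. This is the input of [fit_effects_model()]; fitting on
#' per-sample means avoids pseudo-replicating thousands of cells per
#' sample.
#'
#' @param table a cell table with a `sample_id` column.
#' @return a data.frame, one row per sample.
#' @export
sample_summaries <- function(table) {
  if (is.null(table$sample_id))
    stop("schema error: missing column `sample_id`", call. = FALSE)
  dt <- data.table::as.data.table(table)
  meta <- intersect(c("tissue", "condition", "sex", "body_weight"), names(dt))
  out <- dt[, c(list(n_cells = .N,
                     mean_diameter = mean(equivalent_diameter),
                     mean_sphericity = if ("sphericity" %in% names(dt))
                       mean(sphericity) else NA_real_),
                lapply(.SD, data.table::first)),
            by = "sample_id", .SDcols = meta]
  as.data.frame(out)
}
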
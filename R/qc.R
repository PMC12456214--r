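#' Mask quality-control parameters
#'
#' The post-segmentation filters applied to adipocyte masks: discard masks
#' touching the stack border, then masks under a minimum voxel volume, then
#' masks under a minimum sphericity. The volume threshold is expressed in
#' voxels (not um^3) because that is how acquisition-side filtering is
#' specified; at 1.15 um isotropic spacing, 5000 voxels corresponds to an
#' equivalent diameter of about 24.4 um, i.e. the "less than 25 um"
#' excluded-cell population.
#'
#' @param min_voxels minimum voxel count; masks with strictly fewer voxels
#'   are removed (default 5000).
#' @param min_sphericity minimum sphericity; masks strictly under it are
#'   removed (default 0.35).
#' @param drop_border discard masks touching any stack face (default TRUE).
#' @return an object of class `qc_params`.
#' @export
qc_params <- function(min_voxels = 5000, min_sphericity = 0.35, drop_border = TRUE) {
  if (min_voxels < 0) stop("`min_voxels` must be >= 0", call. = FALSE)
  if (min_sphericity < 0 || min_sphericity > 1)
    stop("`min_sphericity` must be in [0, 1]", call. = FALSE)
  structure(list(min_voxels = min_voxels, min_sphericity = min_sphericity,
                 drop_border = isTRUE(drop_border)),
            class = "qc_params")
}

#' Remove border-touching cells
#'
#' @param table a cell table with a `touches_border` column.
#' @return list with `retained` (rows with `touches_border == FALSE`) and
#'   `removed` (the discarded rows).
#' @export
remove_border_labels <- function(table) {
  if (is.null(table$touches_border))
    stop("schema error: missing column `touches_border`", call. = FALSE)
  keep <- !table$touches_border
  list(retained = table[keep, , drop = FALSE],
       removed = table[!keep, , drop = FALSE])
}

#' Apply the mask QC filters
#'
#' Filters a cell table in the order border -> volume -> sphericity (each
#' cell is attributed to the first filter that removes it; since the
#' filters are conjunctive the retained set does not depend on the order,
#' only the attribution does). All comparisons are strict ("under"):
#' a cell with exactly `min_voxels` voxels or exactly `min_sphericity`
#' is retained.
#'
#' @param table a cell table from [measure_regions()].
#' @param params a [qc_params()] object.
#' @param exclude_ids optional label_ids removed up front (the
#'   manual-review hook; counted as `n_removed_manual`).
#' @return list with `retained` (filtered table) and `report`
#'   (a `qc_report`: per-stage removal counts satisfying
#'   `n_input = n_retained + sum(removals)`).
#' @export
apply_filters <- function(table, params = qc_params(), exclude_ids = NULL) {
  stopifnot(inherits(params, "qc_params"))
  for (col in c("touches_border", "voxel_count", "sphericity"))
    if (is.null(table[[col]]))
      stop(sprintf("schema error: missing column `%s`", col), call. = FALSE)
  n_input <- nrow(table)
  cur <- table
  n_manual <- 0L
  if (!is.null(exclude_ids) && nrow(cur)) {
    drop <- cur$label_id %in% exclude_ids
    n_manual <- sum(drop)
    cur <- cur[!drop, , drop = FALSE]
  }
  n_border <- 0L
  if (params$drop_border && nrow(cur)) {
    res <- remove_border_labels(cur)
    n_border <- nrow(res$removed)
    cur <- res$retained
  }
  small <- cur$voxel_count < params$min_voxels
  n_volume <- sum(small)
  cur <- cur[!small, , drop = FALSE]
  aspher <- !is.na(cur$sphericity) & cur$sphericity < params$min_sphericity
  n_spher <- sum(aspher)
  cur <- cur[!aspher, , drop = FALSE]
  report <- structure(list(
    n_input = n_input,
    n_removed_manual = n_manual,
    n_removed_border = n_border,
    n_removed_volume = n_volume,
    n_removed_sphericity = n_spher,
    n_retained = nrow(cur),
    params = unclass(params)), class = "qc_report")
  list(retained = cur, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("<qc_report> %d cells in -> %d retained ",
                     "(removed: %d manual, %d border, %d volume, %d sphericity)\n"),
              x$n_input, x$n_retained, x$n_removed_manual, x$n_removed_border,
              x$n_removed_volume, x$n_removed_sphericity))
  invisible(x)
}

#' Serialize a QC report as JSON
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
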
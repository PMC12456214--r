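#' Multi-channel 3D image stack
#'
#' Container for a fluorescence stack: one or two channels of non-negative
#' intensities on a common voxel grid with physical spacing. Arrays use axis
#' order (Z, Y, X); by convention channel `"ecm"` holds the extracellular
#' matrix stain (5-DTAF-like, green) and `"lipid"` the lipid droplet stain
#' (Nile-red-like). Intensities are kept in `[0, 1]` for 16-bit TIFF round
#' trips.
#'
#' @param channels a 3D numeric array (single channel) or a named list of 3D
#'   arrays with identical dimensions.
#' @param spacing numeric length-3, voxel spacing in micrometres for the
#'   (Z, Y, X) axes. Defaults to the isotropic 1.15 um confocal grid.
#' @param channel_names names for the channels; defaults to `"lipid"` for a
#'   single channel and `c("ecm", "lipid")` for two.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, spacing = c(1.15, 1.15, 1.15), channel_names = NULL) {
  if (is.array(channels) && length(dim(channels)) == 3L) channels <- list(channels)
  if (!is.list(channels) || !length(channels) %in% c(1L, 2L))
    stop("`channels` must hold 1 (ex situ) or 2 (in situ) 3D arrays", call. = FALSE)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L) ||
      !all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("all channels must be 3D arrays of identical dimensions", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (Z, Y, X) in micrometres", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- if (length(channels) == 1L) "lipid" else c("ecm", "lipid")
  names(channels) <- channel_names
  structure(list(channels = channels, spacing = spacing),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d x %d x %d voxels (Z,Y,X), %d channel(s): %s\n",
              d[1], d[2], d[3], length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  spacing %s um\n", paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' Labelled segmentation stack
#'
#' A 3D array of non-negative integers sharing the voxel grid of its source
#' stack: 0 is background, each positive value marks one cell instance.
#'
#' @param labels 3D integer array (Z, Y, X).
#' @param spacing voxel spacing in micrometres, (Z, Y, X).
#' @return an object of class `label_stack`.
#' @export
label_stack <- function(labels, spacing = c(1.15, 1.15, 1.15)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be non-negative", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values", call. = FALSE)
  structure(list(labels = labels, spacing = spacing), class = "label_stack")
}

#' @export
print.label_stack <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_stack> %d x %d x %d voxels (Z,Y,X), %d label(s), spacing %s um\n",
              d[1], d[2], d[3], n_labels(x), paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' Number of distinct positive labels in a label stack
#' @param x a `label_stack`.
#' @return integer count of non-empty labels.
#' @export
n_labels <- function(x) {
  stopifnot(inherits(x, "label_stack"))
  length(unique(x$labels[x$labels > 0L]))
}

#' Write an image stack as 16-bit TIFF, one file per channel
#'
#' Each channel goes to its own multi-page TIFF (`<base>_<channel>.tif`,
#' one Z plane per page) so very large stacks never need both channels'
#' page lists in memory at once. Intensities are clipped to `[0, 1]`.
#' Spacing and channel roles are not stored in the TIFF; keep them in a
#' manifest (see [generate_cohort()]).
#'
#' @param stack an `image_stack`.
#' @param base_path output path stem (a trailing `.tif` is stripped).
#' @return named character vector of the written paths, invisibly.
#' @export
write_stack <- function(stack, base_path) {
  stopifnot(inherits(stack, "image_stack"))
  base <- sub("\\.tiff?$", "", base_path)
  d <- dim(stack$channels[[1]])
  paths <- character(0)
  for (nm in names(stack$channels)) {
    p <- paste0(base, "_", nm, ".tif")
    write_channel_tiff(stack$channels[[nm]], p)
    paths[[nm]] <- p
  }
  invisible(paths)
}

# one (Z, Y, X) channel -> multi-page 16-bit TIFF, intensities clipped to [0, 1]
write_channel_tiff <- function(ch, path) {
  d <- dim(ch)
  pages <- lapply(seq_len(d[1]), function(z) {
    m <- matrix(ch[z, , ], d[2], d[3])
    m[m < 0] <- 0
    m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate")
  rm(pages)
  reclaim_memory()
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param paths named character vector of per-channel TIFF paths (names are
#'   the channel names); a single unnamed path is read as the lipid
#'   channel.
#' @param spacing voxel spacing in micrometres, (Z, Y, X).
#' @return an `image_stack`.
#' @export
read_stack <- function(paths, spacing = c(1.15, 1.15, 1.15)) {
  if (is.null(names(paths)) && length(paths) == 1L) names(paths) <- "lipid"
  chans <- lapply(paths, read_channel_tiff)
  image_stack(chans, spacing, names(paths))
}

# one multi-page TIFF -> (Z, Y, X) array
read_channel_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  a <- array(0, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) a[z, , ] <- pages[[z]]
  rm(pages)
  reclaim_memory()
  a
}

#' Write a label stack as multi-page 16-bit TIFF
#'
#' Label values are preserved exactly through the 16-bit round trip
#' (maximum 65535 labels per stack).
#'
#' @param labels a `label_stack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_stack"))
  mx <- max(labels$labels)
  if (mx > 65535L) stop("more than 65535 labels cannot be stored as 16-bit TIFF",
                        call. = FALSE)
  d <- dim(labels$labels)
  pages <- lapply(seq_len(d[1]), function(z)
    matrix(labels$labels[z, , ], d[2], d[3]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate")
  rm(pages)
  reclaim_memory()
  invisible(path)
}

#' Load an integer label stack from TIFF
#'
#' Reads any integer multi-page TIFF of instance labels -- including masks
#' produced by external segmenters -- preserving values verbatim.
#'
#' @param path TIFF path, one Z plane per page.
#' @param spacing voxel spacing in micrometres, (Z, Y, X).
#' @return a `label_stack`.
#' @export
load_labels <- function(path, spacing = c(1.15, 1.15, 1.15)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  a <- array(0L, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) a[z, , ] <- as.integer(round(pages[[z]]))
  label_stack(a, spacing)
}
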
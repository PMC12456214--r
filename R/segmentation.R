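#' Segmentation parameters
#'
#' Parameters of the classical seeded-watershed segmenter. The expected
#' diameter defaults follow the inference settings used for adipocyte
#' stacks: 60 um in situ, 40 um ex situ (interpreted in micrometres).
#'
#' @param expected_diameter typical cell diameter, micrometres.
#' @param smoothing_sigma Gaussian smoothing of the channels before
#'   thresholding, micrometres.
#' @param lipid_threshold `"otsu"` or a fixed numeric threshold for the
#'   lipid channel (foreground is strictly above it).
#' @param ecm_threshold `"otsu"` or a fixed numeric threshold for the ECM
#'   channel (voxels strictly below it count as non-wall).
#' @param h_maxima_depth seed suppression depth as a fraction of
#'   `expected_diameter / 2`; distance-map maxima shallower than
#'   `h = h_maxima_depth * expected_diameter / 2` are merged away.
#' @param min_seed_separation seeds closer than this (centroid distance,
#'   micrometres) are merged; defaults to `expected_diameter / 3`.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(expected_diameter = 60, smoothing_sigma = 1.15,
                                lipid_threshold = "otsu", ecm_threshold = "otsu",
                                h_maxima_depth = 0.3, min_seed_separation = NULL) {
  if (expected_diameter <= 0) stop("`expected_diameter` must be positive", call. = FALSE)
  if (is.null(min_seed_separation)) min_seed_separation <- expected_diameter / 3
  structure(list(expected_diameter = expected_diameter,
                 smoothing_sigma = smoothing_sigma,
                 lipid_threshold = lipid_threshold,
                 ecm_threshold = ecm_threshold,
                 h_maxima_depth = h_maxima_depth,
                 min_seed_separation = min_seed_separation),
            class = "segmentation_params")
}

resolve_threshold <- function(spec_value, img, degenerate) {
  if (identical(spec_value, "otsu")) {
    t <- otsu_threshold(img)
    if (is.na(t)) degenerate else t
  } else if (is.numeric(spec_value)) {
    spec_value
  } else stop("threshold must be \"otsu\" or a number", call. = FALSE)
}

# distance-transform seeding + marker watershed, shared by both modes
watershed_from_foreground <- function(fg, d, sp, params) {
  if (!any(fg)) return(array(0L, dim = d))
  # distance to background (invert: background voxels are the EDT features)
  dist <- cpp_edt_sq(fg, d, sp, invert = TRUE, take_sqrt = TRUE)
  h <- params$h_maxima_depth * params$expected_diameter / 2
  rec <- cpp_hmax_reconstruct(dist, h, d)
  seeds <- cpp_regional_maxima(rec, d, fg)
  rm(rec)
  reclaim_memory()
  markers <- cpp_label26(seeds, d)
  rm(seeds)
  markers <- merge_close_markers(markers, d, sp, params$min_seed_separation)
  lab <- cpp_watershed(dist, markers, fg, d, negate = TRUE)
  rm(dist, markers, fg)
  reclaim_memory()
  relabel_sequential(lab, d, in_place = TRUE) # `lab` has no other reference
}

# single-linkage merge of marker components whose centroids are closer than
# `min_sep`; returns the relabelled marker image
merge_close_markers <- function(markers, d, sp, min_sep) {
  st <- cpp_region_stats(markers, d)
  k <- length(st$count)
  if (k <= 1L) return(markers)
  cz <- st$sum_z / st$count * sp[1]
  cy <- st$sum_y / st$count * sp[2]
  cx <- st$sum_x / st$count * sp[3]
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(k - 1)) {
    if (st$count[i] == 0) next
    for (j in seq(i + 1, k)) {
      if (st$count[j] == 0) next
      dd <- sqrt((cz[i] - cz[j])^2 + (cy[i] - cy[j])^2 + (cx[i] - cx[j])^2)
      if (dd < min_sep) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(k), find, 1L)
  map <- c(0L, as.integer(root))
  array(map[markers + 1L], dim = d)
}

relabel_sequential <- function(lab, d, in_place = FALSE) {
  out <- cpp_relabel_sequential(lab, in_place)
  dim(out) <- d
  out
}

#' Segment adipocytes in a two-channel in situ stack
#'
#' Classical stand-in for a learned segmenter: both channels are Gaussian
#' smoothed; foreground is "high lipid OR low ECM" (thresholds per
#' `params`, Otsu by default); the Euclidean distance map of the foreground
#' (physical units, so anisotropic spacing is handled) is seeded at its
#' h-maxima (depth `h_maxima_depth * expected_diameter / 2`, seeds merged
#' within `min_seed_separation`), and a marker-controlled watershed on the
#' negated distance map, restricted to the foreground, produces labels
#' 1..K.
#'
#' @param stack a two-channel `image_stack` (channels `ecm`, `lipid`).
#' @param params a [segmentation_params()] object.
#' @return a `label_stack`; attribute `thresholds` logs the resolved
#'   channel thresholds.
#' @export
segment_in_situ <- function(stack, params = segmentation_params(60)) {
  stopifnot(inherits(stack, "image_stack"), inherits(params, "segmentation_params"))
  if (length(stack$channels) != 2L)
    stop("input error: in situ segmentation needs the ECM and lipid channels",
         call. = FALSE)
  d <- stack_dim(stack$channels[[1]])
  sp <- stack$spacing
  sig <- params$smoothing_sigma / sp
  # channels are smoothed and thresholded one at a time to cap peak memory
  ecm <- cpp_gauss3d(stack$channels$ecm, d, sig)
  t_ecm <- resolve_threshold(params$ecm_threshold, ecm, degenerate = -Inf)
  fg <- ecm < t_ecm
  rm(ecm)
  lipid <- cpp_gauss3d(stack$channels$lipid, d, sig)
  t_lip <- resolve_threshold(params$lipid_threshold, lipid, degenerate = Inf)
  fg <- fg | (lipid > t_lip)
  rm(lipid)
  lab <- watershed_from_foreground(fg, d, sp, params)
  out <- label_stack(lab, sp)
  attr(out, "thresholds") <- c(lipid = t_lip, ecm = t_ecm)
  attr(out, "params") <- unclass(params)
  out
}

#' Segment adipocytes in a single-channel ex situ stack
#'
#' Threshold (Otsu by default on the smoothed channel), fill interior
#' holes, then split touching cells by the same distance-transform
#' watershed as the in situ path.
#'
#' @param stack a single-channel `image_stack`.
#' @param params a [segmentation_params()] object (default expected
#'   diameter 40 um).
#' @return a `label_stack` with a `thresholds` attribute.
#' @export
segment_ex_situ <- function(stack, params = segmentation_params(40)) {
  stopifnot(inherits(stack, "image_stack"), inherits(params, "segmentation_params"))
  if (length(stack$channels) != 1L)
    stop("input error: ex situ segmentation expects a single channel", call. = FALSE)
  d <- stack_dim(stack$channels[[1]])
  sp <- stack$spacing
  img <- cpp_gauss3d(stack$channels[[1]], d, params$smoothing_sigma / sp)
  t_lip <- resolve_threshold(params$lipid_threshold, img, degenerate = Inf)
  fg <- img > t_lip
  if (any(fg)) fg <- cpp_fill_holes(fg, d)
  lab <- watershed_from_foreground(fg, d, sp, params)
  out <- label_stack(lab, sp)
  attr(out, "thresholds") <- c(lipid = t_lip)
  attr(out, "params") <- unclass(params)
  out
}

#' Match predicted labels against ground truth by IoU
#'
#' Greedy one-to-one matching by descending intersection-over-union: each
#' ground-truth cell is paired with at most one predicted cell and vice
#' versa; pairs at or above `iou_threshold` count as matched.
#'
#' @param predicted,truth `label_stack`s on the same grid.
#' @param iou_threshold IoU at or above which a pair counts as matched.
#' @return a `match_report`: counts (`n_truth`, `n_predicted`,
#'   `n_matched_at_iou`), the threshold, and a `pairs` data.frame
#'   (truth_label, predicted_label, iou) of the greedy matches.
#' @export
match_labels <- function(predicted, truth, iou_threshold = 0.5) {
  stopifnot(inherits(predicted, "label_stack"), inherits(truth, "label_stack"))
  if (!identical(dim(predicted$labels), dim(truth$labels)))
    stop("input error: label stacks differ in shape", call. = FALSE)
  if (!isTRUE(all.equal(predicted$spacing, truth$spacing)))
    stop("input error: label stacks differ in spacing", call. = FALSE)
  ov <- cpp_overlap_counts(truth$labels, predicted$labels)
  n_truth <- sum(ov$count_a > 0)
  n_pred <- sum(ov$count_b > 0)
  if (!length(ov$pair_a)) {
    return(structure(list(n_truth = n_truth, n_predicted = n_pred,
                          n_matched_at_iou = 0L, iou_threshold = iou_threshold,
                          pairs = data.frame(truth_label = integer(0),
                                             predicted_label = integer(0),
                                             iou = numeric(0))),
                     class = "match_report"))
  }
  iou <- ov$pair_n / (ov$count_a[ov$pair_a] + ov$count_b[ov$pair_b] - ov$pair_n)
  ord <- order(-iou, ov$pair_a, ov$pair_b)
  used_t <- logical(length(ov$count_a))
  used_p <- logical(length(ov$count_b))
  sel <- logical(length(ord))
  for (i in ord) {
    ta <- ov$pair_a[i]; pb <- ov$pair_b[i]
    if (!used_t[ta] && !used_p[pb]) {
      used_t[ta] <- TRUE
      used_p[pb] <- TRUE
      sel[i] <- TRUE
    }
  }
  pairs <- data.frame(truth_label = ov$pair_a[sel],
                      predicted_label = ov$pair_b[sel],
                      iou = iou[sel])
  pairs <- pairs[order(pairs$truth_label), , drop = FALSE]
  structure(list(n_truth = n_truth, n_predicted = n_pred,
                 n_matched_at_iou = sum(pairs$iou >= iou_threshold),
                 iou_threshold = iou_threshold, pairs = pairs),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %d/%d ground-truth cells matched at IoU >= %.2f (%d predicted)\n",
              x$n_matched_at_iou, x$n_truth, x$iou_threshold, x$n_predicted))
  invisible(x)
}


#' Segment a stack directly from its per-channel TIFF files
#'
#' Streaming variant of [segment_in_situ()] / [segment_ex_situ()] for large
#' stacks: channels are read, smoothed and thresholded one at a time so
#' only one intensity array is in memory at once.
#'
#' @param paths named character vector of per-channel TIFFs as written by
#'   [write_stack()] (`ecm` and `lipid` in situ, `lipid` ex situ).
#' @param spacing voxel spacing, micrometres (Z, Y, X).
#' @param condition `"in_situ"` (2 channels) or `"ex_situ"` (1 channel).
#' @param params a [segmentation_params()] object.
#' @return a `label_stack` with a `thresholds` attribute.
#' @export
segment_stack_file <- function(paths, spacing = c(1.15, 1.15, 1.15),
                               condition = c("in_situ", "ex_situ"),
                               params = NULL) {
  condition <- match.arg(condition)
  if (is.null(params))
    params <- segmentation_params(if (condition == "in_situ") 60 else 40)
  sig <- params$smoothing_sigma / spacing
  if (condition == "in_situ") {
    if (!all(c("ecm", "lipid") %in% names(paths)))
      stop("input error: in situ segmentation needs `ecm` and `lipid` files",
           call. = FALSE)
    ecm <- read_channel_tiff(paths[["ecm"]])
    d <- stack_dim(ecm)
    # in_place: the freshly read channel has no other reference
    ecm <- cpp_gauss3d(ecm, d, sig, in_place = TRUE)
    t_ecm <- resolve_threshold(params$ecm_threshold, ecm, degenerate = -Inf)
    fg <- ecm < t_ecm
    rm(ecm)
    reclaim_memory()
    lipid <- read_channel_tiff(paths[["lipid"]])
    lipid <- cpp_gauss3d(lipid, d, sig, in_place = TRUE)
    t_lip <- resolve_threshold(params$lipid_threshold, lipid, degenerate = Inf)
    fg <- fg | (lipid > t_lip)
    rm(lipid)
    reclaim_memory()
    thresholds <- c(lipid = t_lip, ecm = t_ecm)
  } else {
    img <- read_channel_tiff(paths[[if ("lipid" %in% names(paths)) "lipid" else 1L]])
    d <- stack_dim(img)
    img <- cpp_gauss3d(img, d, sig, in_place = TRUE)
    t_lip <- resolve_threshold(params$lipid_threshold, img, degenerate = Inf)
    fg <- img > t_lip
    rm(img)
    reclaim_memory()
    if (any(fg)) fg <- cpp_fill_holes(fg, d)
    thresholds <- c(lipid = t_lip)
  }
  lab <- watershed_from_foreground(fg, d, spacing, params)
  out <- label_stack(lab, spacing)
  attr(out, "thresholds") <- thresholds
  attr(out, "params") <- unclass(params)
  out
}
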
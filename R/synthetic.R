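#' Draw cell diameters from a preset's size distribution
#'
#' Samples the preset's lognormal (or lognormal-mixture) diameter
#' distribution, parameterised so the arithmetic mean and coefficient of
#' variation equal the preset values: for one component,
#' `sdlog^2 = log(1 + cv^2)` and `meanlog = log(mean) - sdlog^2 / 2`.
#'
#' @param preset a [tissue_preset()].
#' @param n number of draws (>= 0).
#' @param seed integer seed; draws are reproducible for a fixed seed.
#' @return numeric vector of `n` diameters in micrometres.
#' @export
sample_diameters <- function(preset, n, seed = 1L) {
  stopifnot(inherits(preset, "tissue_preset"))
  if (!is.numeric(n) || length(n) != 1L || n < 0)
    stop("`n` must be a non-negative count", call. = FALSE)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  with_seed(seed, {
    if (is.null(preset$mixture)) {
      rlnorm_mean_cv(n, preset$diameter_mean, preset$diameter_cv)
    } else {
      w <- vapply(preset$mixture, function(m) m[[1]], 1.0)
      comp <- sample.int(length(w), n, replace = TRUE, prob = w)
      d <- numeric(n)
      for (k in seq_along(w)) {
        idx <- comp == k
        if (any(idx))
          d[idx] <- rlnorm_mean_cv(sum(idx), preset$mixture[[k]][[2]],
                                   preset$mixture[[k]][[3]])
      }
      d
    }
  })
}

# lognormal draws matched to arithmetic mean and cv
rlnorm_mean_cv <- function(n, mean, cv) {
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# shared placement: sequential rejection sampling of sphere centres with a
# per-pair minimum centre distance rule, all balls kept a margin inside the
# physical box. `min_dist(ri, rj)` gives the admissible centre distance.
# Sequential insertion can jam on an unlucky order even when a packing
# exists, so an exhausted pass restarts from an empty box (continuing the
# same RNG stream, hence still deterministic under the caller's seed).
place_spheres <- function(radii, box, margin, min_dist, max_tries = 3000L,
                          restarts = 4L) {
  k <- length(radii)
  margin <- rep_len(margin, k)
  ord <- order(radii, decreasing = TRUE)
  n_done <- 0L
  for (attempt in seq_len(restarts + 1L)) {
    centers <- matrix(NA_real_, k, 3)
    placed_r <- numeric(0)
    placed_c <- matrix(numeric(0), 0, 3)
    jammed <- FALSE
    for (i in ord) {
      r <- radii[i]
      lo <- r + margin[i]
      hi <- box - r - margin[i]
      if (any(hi <= lo))
        stop(sprintf("geometry error: a %.1f um cell does not fit the %s um box",
                     2 * r, paste(round(box, 1), collapse = " x ")), call. = FALSE)
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        p <- lo + runif(3) * (hi - lo)
        if (nrow(placed_c) == 0L ||
            all(sqrt(rowSums((placed_c - rep(p, each = nrow(placed_c)))^2)) >=
                min_dist(r, placed_r))) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        jammed <- TRUE
        n_done <- nrow(placed_c)
        break
      }
      centers[i, ] <- p
      placed_c <- rbind(placed_c, p)
      placed_r <- c(placed_r, r)
    }
    if (!jammed) return(centers)
  }
  stop(sprintf("geometry error: placed %d of %d cells before running out of room",
               n_done, k), call. = FALSE)
}

#' Pack cells as a wall-separated in situ tissue
#'
#' Builds a ground-truth label stack of space-filling, angular cells: sphere
#' seeds with radii from `diameters` are placed by collision-bounded
#' rejection sampling (centre distance at least `overlap_factor` times the
#' radius sum, so neighbouring balls interpenetrate and cut each other),
#' voxels are assigned by a ball-clipped Laguerre (power diagram) rule, and
#' an extracellular wall of `ecm_thickness` is carved along every
#' cell--cell interface. A deterministic fixed-point radius correction
#' rescales each seed radius by `(V_target/V_measured)^(1/3)` (capped at
#' `inflate_headroom` cumulative growth) so the final per-cell volumes
#' approximate their target sphere volumes despite clipping and wall
#' carving.
#'
#' All balls are kept wholly inside the stack so the ground truth is not
#' censored at the faces (border handling is exercised by the QC filters on
#' real or externally segmented data).
#'
#' @param diameters cell diameters, micrometres.
#' @param shape stack shape in voxels, (Z, Y, X).
#' @param spacing voxel spacing, micrometres (Z, Y, X).
#' @param seed integer seed for placement.
#' @param ecm_thickness wall thickness carved between touching cells, um.
#' @param overlap_factor fraction of the radius sum enforced as minimum
#'   centre distance (< 1 means neighbours interpenetrate and develop flat
#'   contact faces).
#' @param volume_match_iters fixed-point radius-correction iterations.
#' @param inflate_headroom maximum cumulative relative radius growth the
#'   correction may apply (also reserved as placement margin).
#' @param max_tries placement attempts per cell before a geometry error.
#' @return a `label_stack` with attributes `centers`, `radii` and
#'   `target_diameter` (one entry per label).
#' @export
pack_in_situ <- function(diameters, shape, spacing = c(1.15, 1.15, 1.15), seed = 1L,
                         ecm_thickness = 3.45, overlap_factor = 0.78,
                         volume_match_iters = 2L, inflate_headroom = 0.2,
                         max_tries = 3000L) {
  stopifnot(length(diameters) >= 1L, all(diameters > 0))
  shape <- as.integer(shape)
  box <- shape * spacing
  radii <- diameters / 2
  r0 <- radii
  if ((2 + 2 * inflate_headroom) * max(radii) + 2 * max(spacing) >= min(box))
    stop("geometry error: stack too small for the largest cell", call. = FALSE)
  # the margin reserves headroom so radius corrections never push a cell
  # through a stack face (ground truth stays uncensored)
  centers <- with_seed(seed, place_spheres(
    radii, box, margin = inflate_headroom * radii + max(spacing),
    min_dist = function(r, rs) overlap_factor * (r + rs),
    max_tries = max_tries))
  carve_r <- max(0, (ecm_thickness - min(spacing)) / 2)
  build <- function(r) {
    lab <- cpp_laguerre_assign(shape, spacing, centers, r)
    cpp_carve_walls(lab, shape, spacing, carve_r) # fresh vector: in-place is safe
    lab
  }
  lab <- build(radii)
  vx <- voxel_volume(spacing)
  target_v <- pi / 6 * diameters^3
  for (it in seq_len(volume_match_iters)) {
    st <- cpp_region_stats(lab, shape)
    vm <- st$count[seq_along(radii)] * vx
    f <- ifelse(vm > 0, (target_v / vm)^(1 / 3), 1)
    radii <- pmin((1 + inflate_headroom) * r0, pmax(0.8 * r0, radii * f))
    lab <- build(radii)
  }
  out <- array(lab, dim = shape)
  res <- label_stack(out, spacing)
  attr(res, "centers") <- centers
  attr(res, "radii") <- radii
  attr(res, "target_diameter") <- diameters
  res
}

#' Pack cells as an ex situ extracted-cell preparation
#'
#' Places non-touching digitised spheres at random positions (rejection
#' sampling on overlap, with a guaranteed surface-to-surface gap of at
#' least one voxel), emulating freshly extracted adipocytes which round up
#' outside their tissue.
#'
#' @inheritParams pack_in_situ
#' @param min_gap minimum surface distance between spheres, micrometres
#'   (default two voxel spacings).
#' @return a `label_stack` with attributes `centers`, `radii`,
#'   `target_diameter`.
#' @export
pack_ex_situ <- function(diameters, shape, spacing = c(1.15, 1.15, 1.15), seed = 1L,
                         min_gap = NULL, max_tries = 3000L) {
  stopifnot(length(diameters) >= 1L, all(diameters > 0))
  shape <- as.integer(shape)
  box <- shape * spacing
  radii <- diameters / 2
  if (is.null(min_gap)) min_gap <- 2 * max(spacing)
  if (2 * max(radii) + 2 * max(spacing) >= min(box))
    stop("geometry error: stack too small for the largest cell", call. = FALSE)
  centers <- with_seed(seed, place_spheres(
    radii, box, margin = max(spacing),
    min_dist = function(r, rs) r + rs + min_gap,
    max_tries = max_tries))
  lab <- cpp_paint_spheres(shape, spacing, centers, radii)
  res <- label_stack(array(lab, dim = shape), spacing)
  attr(res, "centers") <- centers
  attr(res, "radii") <- radii
  attr(res, "target_diameter") <- diameters
  res
}

#' Render fluorescence channels from a ground-truth label stack
#'
#' Paints the two stains: the ECM channel as a bright shell along every
#' cell boundary (walls between cells and a thin rim around free surfaces)
#' and the lipid channel as a uniform interior intensity; both decay with
#' depth as `exp(-z * spacing_z / attenuation_length)` and receive additive
#' Gaussian noise (clipped at 0) plus a constant background. Ex situ
#' presets produce a single lipid channel.
#'
#' @param labels a `label_stack`.
#' @param preset a [tissue_preset()] supplying wall thickness, attenuation,
#'   noise and background.
#' @param seed integer seed for the noise stream.
#' @param intensity peak signal intensity on the `[0, 1]` scale.
#' @return an `image_stack` (channels `ecm`+`lipid` in situ, `lipid` ex situ).
#' @export
render_channels <- function(labels, preset, seed = 1L, intensity = 0.85) {
  stopifnot(inherits(labels, "label_stack"), inherits(preset, "tissue_preset"))
  d <- stack_dim(labels$labels)
  sp <- labels$spacing
  cellmask <- labels$labels > 0L
  if (preset$packing == "ex_situ")
    return(image_stack(list(lipid = render_one(cellmask, d, sp, preset, seed,
                                               2L, intensity)), sp))
  shell <- ecm_shell_mask(cellmask, d, sp, preset)
  ecm <- render_one(shell, d, sp, preset, seed, 1L, intensity)
  rm(shell)
  image_stack(list(ecm = ecm,
                   lipid = render_one(cellmask, d, sp, preset, seed, 2L, intensity)),
              sp)
}

# wall voxels outside the cells: the dilation ring of the cell mask, computed
# in one C++ pass so no intermediate full-size logical arrays are allocated
ecm_shell_mask <- function(cellmask, d, sp, preset) {
  shell_r <- max(preset$ecm_thickness / 2 + min(sp) / 2, max(sp))
  shell <- cpp_dilate_ball(cellmask, d, sp, shell_r, ring = TRUE)
  dim(shell) <- d
  shell
}

# render one stain (k = 1 ECM stream, k = 2 lipid stream) from its mask
render_one <- function(mask, d, sp, preset, seed, k, intensity) {
  ch <- with_seed(derive_seed(seed, k),
                  cpp_render_channel(mask, d, intensity, sp[1],
                                     preset$attenuation_length,
                                     preset$noise_sd, preset$background))
  dim(ch) <- d
  ch
}

# box side (voxels) that hosts `diameters` at a bulk fill fraction, with
# headroom for the largest cell and the placement margins. The third term
# guarantees the two largest cells fit along one axis fully separated,
# each with its placement margin; for few large cells the bulk-fill term
# alone is far too small to admit the pairwise centre-distance rule.
auto_shape <- function(diameters, spacing, fill) {
  vol <- sum(pi / 6 * diameters^3) / fill
  r <- sort(diameters / 2, decreasing = TRUE)
  m <- 0.2 * r + max(spacing)
  pair_um <- if (length(r) >= 2L)
    (r[1] + m[1]) + (r[2] + m[2]) + (r[1] + r[2]) else 0
  side_um <- max(vol^(1 / 3) + 0.25 * max(diameters),
                 1.45 * max(diameters) + 6 * max(spacing),
                 pair_um)
  as.integer(ceiling(rep(side_um, 3) / spacing) + 2L)
}

#' Simulate one tissue sample end to end
#'
#' Draws diameters from the preset, packs them (in situ or ex situ per the
#' preset), measures the ground-truth label stack and optionally renders
#' the fluorescence channels. The stack shape defaults to a cube sized for
#' the drawn cells (bulk fill fraction 0.62 in situ, 0.20 ex situ).
#'
#' @param preset a [tissue_preset()].
#' @param n_cells number of cells to draw.
#' @param seed master sample seed; child streams (sampling, placement,
#'   noise) are derived from it deterministically.
#' @param spacing voxel spacing, micrometres (Z, Y, X).
#' @param shape optional stack shape in voxels, (Z, Y, X).
#' @param render render fluorescence channels (skip for ground-truth-only
#'   studies).
#' @param measure_surface compute Crofton surfaces/sphericities in the
#'   ground-truth table (disable when only sizes are needed).
#' @param metadata named list merged into the ground-truth table
#'   (sample_id, tissue, condition, sex, body_weight).
#' @return list with elements `labels` (`label_stack`), `truth` (ground
#'   truth cell table), `diameters` (the drawn targets) and `stack`
#'   (`image_stack` or `NULL`).
#' @export
simulate_sample <- function(preset, n_cells, seed = 1L,
                            spacing = c(1.15, 1.15, 1.15), shape = NULL,
                            render = TRUE, measure_surface = TRUE,
                            metadata = list()) {
  stopifnot(inherits(preset, "tissue_preset"))
  diameters <- sample_diameters(preset, n_cells, derive_seed(seed, 1L))
  auto_sized <- is.null(shape)
  if (auto_sized)
    shape <- auto_shape(diameters, spacing,
                        fill = if (preset$packing == "in_situ") 0.70 else 0.20)
  pack_once <- function(shp) {
    if (preset$packing == "in_situ") {
      pack_in_situ(diameters, shp, spacing, seed = derive_seed(seed, 2L),
                   ecm_thickness = preset$ecm_thickness)
    } else {
      pack_ex_situ(diameters, shp, spacing, seed = derive_seed(seed, 2L))
    }
  }
  # the auto-derived cube is a sufficient size for typical draws, not a
  # guarantee; if rejection packing still jams, grow it deterministically
  labels <- NULL
  for (grow in 0:3) {
    labels <- tryCatch(pack_once(shape), error = function(e) e)
    if (!inherits(labels, "error")) break
    if (!auto_sized || grow == 3L ||
        !grepl("geometry error", conditionMessage(labels)))
      stop(labels)
    shape <- as.integer(ceiling(shape * 1.1))
  }
  truth <- measure_regions(labels, metadata = metadata, surface = measure_surface)
  truth$target_diameter <- attr(labels, "target_diameter")[truth$label_id]
  stack <- if (render) render_channels(labels, preset, seed = derive_seed(seed, 3L))
           else NULL
  list(labels = labels, truth = truth, diameters = diameters, stack = stack)
}

#' Generate a full synthetic cohort on disk
#'
#' Simulates every sample of a [cohort_design()] and writes, per sample, the
#' rendered stack (`<id>_stack.tif`), the ground-truth label stack
#' (`<id>_labels.tif`) and the ground-truth cell table (`<id>_truth.csv`),
#' plus one JSON manifest recording seeds, presets, spacing and file paths.
#'
#' @param design a [cohort_design()] data.frame.
#' @param out_dir output directory (created if missing).
#' @param spacing voxel spacing, micrometres.
#' @param render write rendered fluorescence stacks.
#' @param measure_surface include surface/sphericity in ground truth tables.
#' @return the manifest, invisibly.
#' @export
generate_cohort <- function(design, out_dir, spacing = c(1.15, 1.15, 1.15),
                            render = TRUE, measure_surface = TRUE) {
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  samples <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    preset <- row$preset[[1]]
    sim <- simulate_sample(preset, row$n_cells_target, seed = row$seed,
                           spacing = spacing, render = FALSE,
                           measure_surface = measure_surface,
                           metadata = list(sample_id = row$sample_id,
                                           tissue = row$tissue,
                                           condition = row$condition,
                                           sex = row$sex,
                                           body_weight = row$body_weight))
    files <- list(truth = file.path(out_dir, paste0(row$sample_id, "_truth.csv")),
                  labels = file.path(out_dir, paste0(row$sample_id, "_labels.tif")))
    data.table::fwrite(sim$truth, files$truth)
    write_labels(sim$labels, files$labels)
    n_truth <- nrow(sim$truth)
    if (render) {
      # channels are rendered and written one at a time so at most one
      # full-size intensity array (plus the cell mask) is alive at once
      d <- stack_dim(sim$labels$labels)
      cellmask <- sim$labels$labels > 0L
      rseed <- derive_seed(row$seed, 3L)
      sim <- NULL
      reclaim_memory()
      base <- file.path(out_dir, paste0(row$sample_id, "_stack"))
      files$stack <- list()
      if (preset$packing == "in_situ") {
        shell <- ecm_shell_mask(cellmask, d, spacing, preset)
        ecm <- render_one(shell, d, spacing, preset, rseed, 1L, 0.85)
        rm(shell)
        files$stack$ecm <- paste0(base, "_ecm.tif")
        write_channel_tiff(ecm, files$stack$ecm)
        rm(ecm)
        reclaim_memory()
      }
      lipid <- render_one(cellmask, d, spacing, preset, rseed, 2L, 0.85)
      rm(cellmask)
      files$stack$lipid <- paste0(base, "_lipid.tif")
      write_channel_tiff(lipid, files$stack$lipid)
      rm(lipid)
      reclaim_memory()
    }
    samples[[i]] <- list(sample_id = row$sample_id, subject_id = row$subject_id,
                         tissue = row$tissue, condition = row$condition,
                         sex = row$sex, body_weight = row$body_weight,
                         seed = row$seed, n_cells_target = row$n_cells_target,
                         preset = row$preset[[1]][c("name", "diameter_mean",
                                                    "diameter_cv", "packing",
                                                    "ecm_thickness",
                                                    "attenuation_length",
                                                    "noise_sd", "background")],
                         n_cells_ground_truth = n_truth,
                         files = rapply(files, basename, how = "replace"))
  }
  manifest <- list(spacing = spacing,
                   axis_order = "ZYX",
                   channel_order = c("ecm", "lipid"),
                   label_tiff_bits = 16L,
                   surface_estimator = "crofton13",
                   package_version = as.character(packageVersion("adipo3d")),
                   samples = samples)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Mean in-cell signal per depth plane
#'
#' Depth profile of the mean lipid-channel intensity inside cells, used to
#' quantify how far into the stack usable signal persists under a given
#' mounting medium.
#'
#' @param stack an `image_stack`.
#' @param labels matching `label_stack` defining the in-cell voxels.
#' @param channel channel name to profile.
#' @return data.frame with `depth_um` and `mean_intensity` per Z plane.
#' @export
depth_profile <- function(stack, labels, channel = "lipid") {
  stopifnot(inherits(stack, "image_stack"), inherits(labels, "label_stack"))
  img <- stack$channels[[channel]]
  stopifnot(!is.null(img), identical(dim(img), dim(labels$labels)))
  inside <- labels$labels > 0L
  nz <- dim(img)[1]
  prof <- vapply(seq_len(nz), function(z) {
    m <- inside[z, , ]
    if (!any(m)) NA_real_ else mean(img[z, , ][m])
  }, 1.0)
  data.frame(depth_um = (seq_len(nz) - 1) * stack$spacing[1],
             mean_intensity = prof)
}

#' Depth at which the in-cell signal falls below a threshold
#'
#' @param profile output of [depth_profile()].
#' @param threshold intensity threshold.
#' @return depth in micrometres of the first plane whose mean in-cell
#'   intensity drops below `threshold` (`Inf` if it never does).
#' @export
crossing_depth <- function(profile, threshold) {
  below <- which(!is.na(profile$mean_intensity) &
                   profile$mean_intensity < threshold)
  if (!length(below)) return(Inf)
  profile$depth_um[below[1]]
}
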
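#' Run the simulate / segment / measure / qc / compare pipeline
#'
#' Orchestrates the analysis stages over a run directory. Each stage reads
#' only the files the previous stage declared in the run manifest, so any
#' stage can start from on-disk intermediates -- in particular, label
#' stacks produced by an external segmenter can be dropped into the
#' `measure` stage via `config$measure$labels_dir`.
#'
#' The config is a named list (or a path to a JSON file with the same
#' structure):
#' \describe{
#'   \item{out_dir}{run directory.}
#'   \item{seed}{master seed.}
#'   \item{spacing}{voxel spacing (Z, Y, X), micrometres.}
#'   \item{stages}{subset of `c("simulate", "segment", "measure", "qc",
#'     "compare")`, executed in that order.}
#'   \item{simulate}{arguments for [cohort_design()] (`n_subjects`,
#'     `tissues`, `n_cells_target`, `condition`) plus `render`.}
#'   \item{segment}{arguments for [segmentation_params()].}
#'   \item{qc}{arguments for [qc_params()].}
#'   \item{compare}{`group_by` (metadata column), `variable` (cell table
#'     column) and `m` (permutations).}
#' }
#'
#' @param config named list or JSON path.
#' @return the run manifest (paths and per-stage counts), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config error: `out_dir` is required", call. = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  spacing <- if (is.null(config$spacing)) c(1.15, 1.15, 1.15) else as.numeric(config$spacing)
  stages <- if (is.null(config$stages))
    c("simulate", "segment", "measure", "qc", "compare") else config$stages
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- list(config = config, spacing = spacing, seed = seed,
              package_version = as.character(packageVersion("adipo3d")))

  sim_dir <- file.path(out_dir, "sim")
  if ("simulate" %in% stages) {
    sc <- config$simulate
    design <- cohort_design(
      n_subjects = if (is.null(sc$n_subjects)) 2L else sc$n_subjects,
      tissues = if (is.null(sc$tissues)) c("VAT", "SCAT") else sc$tissues,
      n_cells_target = if (is.null(sc$n_cells_target)) 40L else sc$n_cells_target,
      condition = if (is.null(sc$condition)) "in_situ" else sc$condition,
      seed = seed)
    message(sprintf("[simulate] %d samples -> %s", nrow(design), sim_dir))
    generate_cohort(design, sim_dir, spacing = spacing,
                    render = !isFALSE(sc$render))
  }
  manifest_path <- file.path(sim_dir, "manifest.json")
  samples <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path)$samples else NULL

  seg_dir <- file.path(out_dir, "seg")
  if ("segment" %in% stages) {
    if (is.null(samples)) stop("stage `segment`: no simulated inputs found", call. = FALSE)
    dir.create(seg_dir, showWarnings = FALSE)
    for (s in samples) {
      in_situ <- identical(s$condition, "in_situ")
      params <- do.call(segmentation_params, c(
        list(expected_diameter = if (!is.null(config$segment$expected_diameter))
          config$segment$expected_diameter else if (in_situ) 60 else 40),
        config$segment[setdiff(names(config$segment), "expected_diameter")]))
      stack_paths <- vapply(s$files$stack, function(p) file.path(sim_dir, p), "")
      lab <- segment_stack_file(stack_paths, spacing,
                                condition = s$condition, params = params)
      message(sprintf("[segment] %s: %d cells (thresholds: %s)", s$sample_id,
                      n_labels(lab),
                      paste(sprintf("%s=%.3g", names(attr(lab, "thresholds")),
                                    attr(lab, "thresholds")), collapse = ", ")))
      write_labels(lab, file.path(seg_dir, paste0(s$sample_id, "_pred.tif")))
      rm(lab)
      reclaim_memory()
    }
  }

  cells_dir <- file.path(out_dir, "cells")
  if ("measure" %in% stages) {
    if (is.null(samples)) stop("stage `measure`: no sample manifest found", call. = FALSE)
    dir.create(cells_dir, showWarnings = FALSE)
    labels_dir <- if (!is.null(config$measure$labels_dir)) config$measure$labels_dir else seg_dir
    suffix <- if (!is.null(config$measure$labels_suffix)) config$measure$labels_suffix else "_pred.tif"
    for (s in samples) {
      lp <- file.path(labels_dir, paste0(s$sample_id, suffix))
      if (!file.exists(lp))
        stop(sprintf("stage `measure`: missing label stack %s", lp), call. = FALSE)
      lab <- load_labels(lp, spacing)
      tab <- measure_regions(lab, metadata = list(
        sample_id = s$sample_id, tissue = s$tissue, condition = s$condition,
        sex = s$sex, body_weight = s$body_weight))
      message(sprintf("[measure] %s: %d cells", s$sample_id, nrow(tab)))
      data.table::fwrite(tab, file.path(cells_dir, paste0(s$sample_id, "_cells.csv")))
      rm(lab)
      reclaim_memory()
    }
  }

  qc_dir <- file.path(out_dir, "qc")
  if ("qc" %in% stages) {
    files <- list.files(cells_dir, pattern = "_cells\\.csv$", full.names = TRUE)
    if (!length(files)) stop("stage `qc`: no cell tables found", call. = FALSE)
    dir.create(qc_dir, showWarnings = FALSE)
    params <- do.call(qc_params, if (is.null(config$qc)) list() else config$qc)
    for (f in sort(files)) {
      tab <- as.data.frame(data.table::fread(f))
      res <- apply_filters(tab, params)
      id <- sub("_cells\\.csv$", "", basename(f))
      message(sprintf("[qc] %s: %d in, %d retained (border %d, volume %d, sphericity %d)",
                      id, res$report$n_input, res$report$n_retained,
                      res$report$n_removed_border, res$report$n_removed_volume,
                      res$report$n_removed_sphericity))
      data.table::fwrite(res$retained, file.path(qc_dir, paste0(id, "_cells_qc.csv")))
      write_qc_report(res$report, file.path(qc_dir, paste0(id, "_qc.json")))
    }
  }

  if ("compare" %in% stages) {
    files <- list.files(qc_dir, pattern = "_cells_qc\\.csv$", full.names = TRUE)
    if (!length(files)) stop("stage `compare`: no QC-filtered tables found", call. = FALSE)
    cc <- config$compare
    group_by <- if (is.null(cc$group_by)) "tissue" else cc$group_by
    variable <- if (is.null(cc$variable)) "equivalent_diameter" else cc$variable
    m <- if (is.null(cc$m)) 10000L else as.integer(cc$m)
    tab <- data.table::rbindlist(lapply(sort(files), data.table::fread))
    groups <- split(tab[[variable]], tab[[group_by]])
    if (length(groups) != 2L)
      stop(sprintf("stage `compare`: need exactly 2 levels of `%s`", group_by),
           call. = FALSE)
    dens <- lapply(groups, estimate_density)
    dens_tab <- data.table::rbindlist(lapply(names(dens), function(g)
      data.frame(group = g, grid = dens[[g]]$grid, density = dens[[g]]$density)))
    data.table::fwrite(dens_tab, file.path(out_dir, "densities.csv"))
    ks <- permutation_ks_test(groups[[1]], groups[[2]], m = m,
                              seed = derive_seed(seed, 9001L))
    message(sprintf("[compare] %s by %s: D = %.4f, p = %.3g",
                    variable, group_by, ks$d_observed, ks$p_value))
    jsonlite::write_json(unclass(ks), file.path(out_dir, "ks_result.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    run$ks <- unclass(ks)
    summ <- sample_summaries(as.data.frame(tab))
    if (length(unique(summ$tissue)) >= 2 && length(unique(summ$sex)) >= 2) {
      em <- fit_effects_model(summ, "mean_diameter")
      jsonlite::write_json(list(response = em$response, n_samples = em$n_samples,
                                coefficients = em$coefficients),
                           file.path(out_dir, "effects_model.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      run$effects_model <- em$coefficients
    }
  }

  jsonlite::write_json(
    list(seed = seed, spacing = spacing, stages = stages,
         package_version = run$package_version),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(run)
}
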
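test_that("diameter sampling matches the requested mean and cv", {
  p <- preset_vat_trout()
  expect_identical(sample_diameters(p, 0, seed = 1), numeric(0))
  d <- sample_diameters(p, 100000, seed = 7)
  # closed-form lognormal moment matching: mu = ln(mean) - s2/2, s2 = ln(1+cv^2)
  expect_equal(mean(d), 81.32, tolerance = 0.01)
  expect_equal(sd(d) / mean(d), 0.30, tolerance = 0.02)
  # reproducible for a fixed seed, different across seeds
  expect_identical(d, sample_diameters(p, 100000, seed = 7))
  expect_false(identical(d[1], sample_diameters(p, 1, seed = 8)))
})

test_that("mixture sampling hits the weighted component mean", {
  d <- sample_diameters(preset_scat_c57(), 100000, seed = 7)
  expect_equal(mean(d), 44.0, tolerance = 0.01 * 44) # 0.5*38 + 0.5*50
  expect_error(tissue_preset("bad", 50, 0.3,
                             mixture = list(list(0.6, 38, 0.1), list(0.5, 50, 0.1))),
               "sum to 1")
  expect_error(tissue_preset("bad", -3, 0.3), "positive")
  expect_error(tissue_preset("bad", 50, 0), "positive")
})

test_that("a single 60 um in situ cell is reproduced within 10%", {
  ls <- pack_in_situ(60, shape = c(80, 80, 80), spacing = iso_spacing, seed = 1)
  tab <- measure_regions(ls)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$equivalent_diameter, 60, tolerance = 0.10)
})

test_that("in situ packing is deterministic and labels are disjoint components", {
  d <- sample_diameters(preset_scat_trout(), 25, seed = 3)
  a <- pack_in_situ(d, shape = c(190, 190, 190), spacing = iso_spacing, seed = 4)
  b <- pack_in_situ(d, shape = c(190, 190, 190), spacing = iso_spacing, seed = 4)
  expect_identical(a$labels, b$labels)
  expect_lte(n_labels(a), 25L)
  # disjointness is structural (one label per voxel); check every label is
  # one 26-connected component
  for (l in unique(a$labels[a$labels > 0])[1:5]) {
    comp <- adipo3d:::cpp_label26(a$labels == l, dim(a$labels))
    expect_equal(max(comp), 1L)
  }
})

test_that("packing reports geometry errors for impossible boxes", {
  expect_error(pack_in_situ(120, shape = c(40, 40, 40)), "geometry error")
  expect_error(pack_ex_situ(rep(50, 60), shape = c(60, 60, 60)), "geometry error")
})

test_that("ex situ spheres never touch and are nearly perfectly spherical", {
  ls <- pack_ex_situ(40, shape = c(60, 60, 60), spacing = iso_spacing, seed = 2)
  tab <- measure_regions(ls)
  expect_equal(nrow(tab), 1L)
  expect_gte(tab$sphericity, 0.95)
  d <- sample_diameters(preset_ex_situ(40, 0.2), 12, seed = 5)
  ls2 <- pack_ex_situ(d, shape = c(170, 170, 170), spacing = iso_spacing, seed = 6)
  centers <- attr(ls2, "centers")
  radii <- attr(ls2, "radii")
  gaps <- c()
  for (i in 1:(nrow(centers) - 1))
    for (j in (i + 1):nrow(centers))
      gaps <- c(gaps, sqrt(sum((centers[i, ] - centers[j, ])^2)) - radii[i] - radii[j])
  expect_gte(min(gaps), 1.15) # at least one voxel of free space everywhere
})

test_that("ex situ cells are rounder than in situ cells from identical draws", {
  d <- sample_diameters(preset_ex_situ(60, 0.3), 30, seed = 9)
  in_t <- measure_regions(pack_in_situ(d, auto_shape_for(d, 0.70), seed = 10))
  ex_t <- measure_regions(pack_ex_situ(d, auto_shape_for(d, 0.20), seed = 10))
  expect_gt(mean(ex_t$sphericity), mean(in_t$sphericity))
})

test_that("rendering: no attenuation means depth-constant in-cell intensity", {
  ls <- pack_ex_situ(30, shape = c(40, 40, 40), spacing = iso_spacing, seed = 2)
  p <- preset_ex_situ(30, 0.2) # attenuation_length Inf, noise 0
  st <- render_channels(ls, p, seed = 1)
  prof <- depth_profile(st, ls)
  vals <- prof$mean_intensity[!is.na(prof$mean_intensity)]
  expect_lt(diff(range(vals)), 1e-12)
})

test_that("rendering: in-cell signal decays to 1/e at one attenuation length", {
  # slab of cell material spanning all depths, L = 46 um
  lab <- label_stack(array(1L, c(80, 20, 20)), iso_spacing)
  p <- preset_ex_situ(30, 0.2, attenuation_length = 46)
  st <- render_channels(lab, p, seed = 1)
  prof <- depth_profile(st, lab)
  z0 <- prof$mean_intensity[1] - p$background
  zL <- prof$mean_intensity[prof$depth_um == 46] - p$background
  expect_equal(zL / z0, exp(-1), tolerance = 1e-6)
})

test_that("in situ rendering paints walls in the ECM channel, interiors in lipid", {
  d <- sample_diameters(preset_scat_trout(), 8, seed = 12)
  ls <- pack_in_situ(d, auto_shape_for(d, 0.70), seed = 13)
  st <- render_channels(ls, preset_scat_trout(), seed = 14)
  expect_named(st$channels, c("ecm", "lipid"))
  inside <- ls$labels > 0
  expect_true(all(st$channels$lipid[inside] > 0.5))
  expect_true(mean(st$channels$ecm[inside] < 0.5) > 0.99)
  # walls (background near cells) are bright in ECM
  expect_gt(max(st$channels$ecm[!inside]), 0.5)
})

test_that("generate_cohort writes all artifacts deterministically", {
  out1 <- file.path(tempdir(), "cohort_a")
  out2 <- file.path(tempdir(), "cohort_b")
  on.exit(unlink(c(out1, out2), recursive = TRUE), add = TRUE)
  design <- cohort_design(n_subjects = 1L, tissues = c("VAT", "SCAT"),
                          presets = list(VAT = preset_vat_trout(),
                                         SCAT = preset_scat_trout()),
                          n_cells_target = 8L, seed = 21)
  m1 <- generate_cohort(design, out1)
  expect_setequal(list.files(out1),
                  c("manifest.json",
                    paste0(rep(design$sample_id, each = 4),
                           c("_truth.csv", "_labels.tif", "_stack_ecm.tif",
                             "_stack_lipid.tif"))))
  generate_cohort(design, out2)
  for (id in design$sample_id)
    expect_identical(readBin(file.path(out1, paste0(id, "_truth.csv")), "raw", 1e6),
                     readBin(file.path(out2, paste0(id, "_truth.csv")), "raw", 1e6))
  expect_equal(length(m1$samples), 2L)
  expect_error(generate_cohort(rbind(design, design), tempdir()), "duplicate")
})

test_that("label stacks round-trip through TIFF verbatim", {
  d <- sample_diameters(preset_scat_trout(), 6, seed = 31)
  ls <- pack_in_situ(d, auto_shape_for(d, 0.70), seed = 32)
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(path), add = TRUE)
  write_labels(ls, path)
  back <- load_labels(path, ls$spacing)
  expect_identical(back$labels, ls$labels)
})
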
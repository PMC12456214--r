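test_that("equivalent diameter inverts the sphere volume formula", {
  # unit sphere identity: V = pi/6 -> d = 1
  expect_equal(equivalent_diameter(pi / 6), 1.0, tolerance = 1e-12)
  # closed-form inverse at 60 um
  expect_equal(equivalent_diameter(pi / 6 * 60^3), 60, tolerance = 1e-9)
  # the 5000-voxel QC cutoff at 1.15 um spacing sits just under 25 um
  d_cut <- equivalent_diameter(5000 * 1.15^3)
  expect_equal(d_cut, (6 * 5000 * 1.15^3 / pi)^(1 / 3), tolerance = 1e-12)
  expect_lt(d_cut, 25)
  expect_gt(d_cut, 24)
  # strictly increasing in V
  v <- seq(10, 1e6, length.out = 50)
  expect_true(all(diff(equivalent_diameter(v)) > 0))
  expect_error(equivalent_diameter(0), "positive")
  expect_error(equivalent_diameter(-3), "positive")
})

test_that("sphericity formula: sphere = 1, cube = (36 pi)^(1/3)/6, scale invariant", {
  for (r in c(0.5, 7, 130))
    expect_equal(sphericity(4 * pi * r^3 / 3, 4 * pi * r^2), 1.0, tolerance = 1e-9)
  for (s in c(1, 46))
    expect_equal(sphericity(s^3, 6 * s^2), (36 * pi)^(1 / 3) / 6, tolerance = 1e-12)
  v <- 1234.5
  a <- 987.6
  expect_equal(sphericity(8 * v, 4 * a), sphericity(v, a), tolerance = 1e-12)
  expect_error(sphericity(-1, 10), "positive")
  expect_error(sphericity(10, 0), "positive")
})

test_that("measured digitized spheres recover diameter and near-unit sphericity", {
  ls <- digitized_sphere(25)
  tab <- measure_regions(ls)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$equivalent_diameter, 57.5, tolerance = 0.02)
  expect_gte(tab$sphericity, 0.97)
  expect_false(tab$touches_border)
})

test_that("diameter error of digitized spheres shrinks with radius", {
  errs <- vapply(c(10, 20, 40), function(r) {
    tab <- measure_regions(digitized_sphere(r))
    abs(tab$equivalent_diameter - 2 * r * 1.15)
  }, 1.0)
  # relative error decreases monotonically with radius
  rel <- errs / (2 * c(10, 20, 40) * 1.15)
  expect_true(all(diff(rel) <= 0))
})

test_that("single voxel volume is exactly the voxel volume", {
  a <- array(0L, c(3, 3, 3))
  a[2, 2, 2] <- 1L
  tab <- measure_regions(label_stack(a, iso_spacing))
  expect_identical(tab$volume, 1.15^3)
  expect_identical(tab$voxel_count, 1)
})

test_that("measured cube sphericity matches the Crofton oracle value", {
  # frozen oracle: independent crossing-count implementation gives 0.8825
  # for a 40^3 voxel cube (axis-aligned flat faces are the estimator's
  # worst case; the analytic cube value 0.806 is covered by the formula
  # tests above)
  tab <- measure_regions(digitized_cube(40))
  expect_equal(tab$sphericity, 0.8825, tolerance = 0.005)
  expect_false(tab$touches_border)
  tb <- measure_regions(digitized_cube(40, touch_border = TRUE))
  expect_true(tb$touches_border)
})

test_that("voxel counts are conserved and match an independent histogram oracle", {
  set.seed(42)
  a <- array(sample(0:5, 15^3, replace = TRUE), c(15, 15, 15))
  ls <- label_stack(a, c(2, 1.5, 1))
  tab <- measure_regions(ls, surface = FALSE)
  expect_equal(sum(tab$voxel_count), sum(a > 0))
  oracle <- table(a[a > 0])
  expect_equal(tab$voxel_count[match(names(oracle), tab$label_id)],
               as.numeric(oracle))
  expect_equal(tab$volume, tab$voxel_count * 3, tolerance = 1e-12)
})

test_that("centroids are voxel-centre based physical coordinates", {
  a <- array(0L, c(5, 5, 5))
  a[2:3, 4, 5] <- 1L # z indices 1,2 (0-based), y = 3, x = 4
  tab <- measure_regions(label_stack(a, c(2, 3, 4)))
  expect_equal(tab$centroid_z, 1.5 * 2)
  expect_equal(tab$centroid_y, 3 * 3)
  expect_equal(tab$centroid_x, 4 * 4)
  expect_true(tab$touches_border)
})

test_that("empty label stacks give empty tables, metadata is passed through", {
  empty <- label_stack(array(0L, c(4, 4, 4)), iso_spacing)
  tab <- measure_regions(empty)
  expect_equal(nrow(tab), 0L)
  expect_true(all(c("volume", "sphericity", "touches_border") %in% names(tab)))
  one <- digitized_sphere(5)
  tab <- measure_regions(one, metadata = list(sample_id = "s1", tissue = "VAT"))
  expect_equal(tab$sample_id, "s1")
  expect_equal(tab$tissue, "VAT")
})
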
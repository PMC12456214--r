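test_that("planted fixture is filtered 3 border / 2 volume / 1 sphericity", {
  tab <- planted_qc_table()
  res <- apply_filters(tab, qc_params())
  expect_equal(res$report$n_input, 10L)
  expect_equal(res$report$n_removed_border, 3L)
  expect_equal(res$report$n_removed_volume, 2L)
  expect_equal(res$report$n_removed_sphericity, 1L)
  expect_equal(res$report$n_retained, 4L)
  expect_setequal(res$retained$label_id, c(7, 8, 9, 10))
  # conservation: input = retained + all removals
  with(res$report, expect_equal(
    n_input, n_retained + n_removed_manual + n_removed_border +
      n_removed_volume + n_removed_sphericity))
})

test_that("thresholds are strict: exactly 5000 voxels and 0.35 sphericity survive", {
  tab <- data.frame(label_id = 1:4,
                    voxel_count = c(5000, 4999, 8000, 8000),
                    sphericity = c(0.8, 0.8, 0.35, 0.34),
                    touches_border = FALSE)
  res <- apply_filters(tab, qc_params())
  expect_setequal(res$retained$label_id, c(1, 3))
  expect_equal(res$report$n_removed_volume, 1L)
  expect_equal(res$report$n_removed_sphericity, 1L)
})

test_that("border removal keeps exactly the interior cells", {
  tab <- planted_qc_table()
  res <- remove_border_labels(tab)
  expect_true(all(!res$retained$touches_border))
  expect_equal(nrow(res$removed), 3L)
  # all-interior table unchanged
  interior <- tab[!tab$touches_border, ]
  expect_identical(remove_border_labels(interior)$retained, interior)
  # empty table stays empty
  empty <- tab[0, ]
  expect_equal(nrow(remove_border_labels(empty)$retained), 0L)
})

test_that("a single voxel on a stack face marks the cell as border", {
  ls <- digitized_cube(4, pad = 2)
  ls$labels[1, 4, 4] <- 1L # one voxel on the z = 0 face
  tab <- measure_regions(ls)
  expect_true(tab$touches_border)
  expect_equal(nrow(apply_filters(tab, qc_params(min_voxels = 0))$retained), 0L)
})

test_that("filtering is idempotent and monotone in the thresholds", {
  tab <- planted_qc_table()
  once <- apply_filters(tab, qc_params())
  twice <- apply_filters(once$retained, qc_params())
  expect_identical(twice$retained, once$retained)
  expect_equal(twice$report$n_removed_border, 0L)
  n_at <- function(mv, ms)
    apply_filters(tab, qc_params(min_voxels = mv, min_sphericity = ms))$report$n_retained
  for (mv in c(0, 2000, 5000, 9000, 20000))
    expect_gte(n_at(mv, 0.35), n_at(mv + 1000, 0.35))
  for (ms in c(0, 0.3, 0.6, 0.9))
    expect_gte(n_at(5000, ms), n_at(5000, ms + 0.1))
})

test_that("manual exclusion hook and schema errors behave", {
  tab <- planted_qc_table()
  res <- apply_filters(tab, qc_params(), exclude_ids = c(8, 9))
  expect_equal(res$report$n_removed_manual, 2L)
  expect_setequal(res$retained$label_id, c(7, 10))
  expect_error(apply_filters(tab[, setdiff(names(tab), "sphericity")]),
               "sphericity")
  expect_error(qc_params(min_sphericity = 1.5), "0, 1")
})

test_that("qc report round-trips through JSON", {
  res <- apply_filters(planted_qc_table(), qc_params())
  path <- tempfile(fileext = ".json")
  write_qc_report(res$report, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$n_retained, 4L)
  expect_equal(back$params$min_voxels, 5000)
})
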
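test_that("blank stacks segment to zero labels", {
  blank2 <- image_stack(list(ecm = array(0.05, c(20, 20, 20)),
                             lipid = array(0.05, c(20, 20, 20))), iso_spacing)
  expect_equal(n_labels(segment_in_situ(blank2)), 0L)
  blank1 <- image_stack(array(0, c(20, 20, 20)), iso_spacing)
  expect_equal(n_labels(segment_ex_situ(blank1)), 0L)
})

test_that("channel-count contracts are enforced", {
  one <- image_stack(array(0, c(5, 5, 5)), iso_spacing)
  two <- image_stack(list(a = array(0, c(5, 5, 5)), b = array(0, c(5, 5, 5))),
                     iso_spacing)
  expect_error(segment_in_situ(one), "input error")
  expect_error(segment_ex_situ(two), "input error")
})

test_that("a rendered 40 um sphere is recovered as one high-IoU label", {
  ls <- pack_ex_situ(40, shape = c(60, 60, 60), spacing = iso_spacing, seed = 2)
  st <- render_channels(ls, preset_ex_situ(40, 0.2), seed = 3)
  pred <- segment_ex_situ(st, segmentation_params(40))
  expect_equal(n_labels(pred), 1L)
  mr <- match_labels(pred, ls, iou_threshold = 0.9)
  expect_equal(mr$n_matched_at_iou, 1L)
})

test_that("well-separated spheres come out as distinct labels, deterministically", {
  d <- c(30, 36, 42)
  ls <- pack_ex_situ(d, shape = c(150, 150, 150), spacing = iso_spacing, seed = 5)
  st <- render_channels(ls, preset_ex_situ(36, 0.2), seed = 6)
  p1 <- segment_ex_situ(st, segmentation_params(36))
  expect_equal(n_labels(p1), 3L)
  p2 <- segment_ex_situ(st, segmentation_params(36))
  expect_identical(p1$labels, p2$labels)
})

test_that("noise-free in situ stacks are segmented near ground truth", {
  d <- sample_diameters(preset_scat_trout(), 12, seed = 41)
  ls <- pack_in_situ(d, auto_shape_for(d, 0.70), seed = 42)
  st <- render_channels(ls, preset_scat_trout(), seed = 43)
  pred <- segment_in_situ(st, segmentation_params(60))
  mr <- match_labels(pred, ls, iou_threshold = 0.7)
  expect_gte(mr$n_matched_at_iou / mr$n_truth, 0.9)
})

test_that("match_labels: self-match is perfect, empty prediction matches nothing", {
  d <- sample_diameters(preset_scat_trout(), 5, seed = 51)
  ls <- pack_in_situ(d, auto_shape_for(d, 0.70), seed = 52)
  self <- match_labels(ls, ls, 0.5)
  expect_equal(self$n_matched_at_iou, self$n_truth)
  expect_true(all(self$pairs$iou == 1))
  empty <- label_stack(array(0L, dim(ls$labels)), ls$spacing)
  expect_equal(match_labels(empty, ls, 0.5)$n_matched_at_iou, 0L)
})

test_that("match_labels computes IoU = 1/3 on the constructed half-shift toy", {
  toy <- shifted_block_pair() # |A| = |B| = 64, overlap 32 -> IoU = 32/96
  mr <- match_labels(toy$pred, toy$truth, 0.2)
  expect_equal(mr$pairs$iou, 1 / 3)
  expect_equal(mr$n_matched_at_iou, 1L)
  expect_equal(match_labels(toy$pred, toy$truth, 0.5)$n_matched_at_iou, 0L)
})

test_that("matching counts are invariant to relabelling the ground truth", {
  d <- sample_diameters(preset_scat_trout(), 8, seed = 61)
  ls <- pack_in_situ(d, auto_shape_for(d, 0.70), seed = 62)
  st <- render_channels(ls, preset_scat_trout(), seed = 63)
  pred <- segment_in_situ(st, segmentation_params(60))
  base <- match_labels(pred, ls, 0.7)
  # permute label ids of the truth
  perm <- c(0L, sample(seq_len(max(ls$labels))))
  shuffled <- label_stack(array(perm[ls$labels + 1L], dim(ls$labels)), ls$spacing)
  mr <- match_labels(pred, shuffled, 0.7)
  expect_equal(mr$n_matched_at_iou, base$n_matched_at_iou)
  expect_equal(sort(mr$pairs$iou), sort(base$pairs$iou))
})

test_that("shape and spacing mismatches are input errors", {
  a <- label_stack(array(0L, c(4, 4, 4)), iso_spacing)
  b <- label_stack(array(0L, c(5, 4, 4)), iso_spacing)
  expect_error(match_labels(a, b), "shape")
  cc <- label_stack(array(0L, c(4, 4, 4)), c(1, 1, 1))
  expect_error(match_labels(a, cc), "spacing")
})

test_that("watershed output is restricted to its foreground", {
  d <- sample_diameters(preset_scat_trout(), 6, seed = 71)
  ls <- pack_in_situ(d, auto_shape_for(d, 0.70), seed = 72)
  st <- render_channels(ls, preset_scat_trout(), seed = 73)
  params <- segmentation_params(60, lipid_threshold = 0.4, ecm_threshold = 0.4)
  pred <- segment_in_situ(st, params)
  # rebuild the exact foreground mask the watershed was flooded on (same
  # smoothing, same fixed thresholds): no label may leak outside it
  dm <- dim(st$channels$lipid)
  sig <- params$smoothing_sigma / st$spacing
  ecm_s <- adipo3d:::cpp_gauss3d(st$channels$ecm, dm, sig)
  lip_s <- adipo3d:::cpp_gauss3d(st$channels$lipid, dm, sig)
  fg <- (ecm_s < attr(pred, "thresholds")[["ecm"]]) |
        (lip_s > attr(pred, "thresholds")[["lipid"]])
  expect_true(all(fg[pred$labels > 0]))
  # and the complement is not all-labelled either: background stays empty
  expect_true(any(pred$labels[!fg] == 0L) || all(fg))
})
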
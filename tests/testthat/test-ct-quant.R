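test_that("threshold segmentation is inclusive and saturates correctly", {
  hu <- array(c(-40L, -32L, 0L, 10L, 11L, 500L, -1000L, 20L), c(2, 2, 2))
  vol <- ct_volume(hu, 1, 0.625, 1.25)
  cand <- threshold_segment(vol, hu_range(-32, 10))
  expect_identical(as.vector(cand),
                   c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(all(threshold_segment(vol, hu_range(-1024, 3071))))
  expect_false(any(threshold_segment(vol, hu_range(1000, 2000))))
})

test_that("widening the HU range never shrinks the candidate set", {
  ph <- small_phantom(seed = 2, grid = c(36L, 34L, 34L))
  widths <- list(c(-20, 5), c(-32.2, 10.1), c(-60, 30), c(-200, 100))
  counts <- vapply(widths, function(w)
    sum(threshold_segment(ph$volume, hu_range(w[1], w[2]))), 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("candidate equals truth adipose plus injected in-range structures", {
  ph <- small_phantom(seed = 5)
  cand <- threshold_segment(ph$volume, adipose_range())
  tr <- ph$truth
  fp <- Reduce(`|`, tr$class_masks)
  expect_true(all(cand[tr$adipose_mask]))            # negligible false negatives
  outside <- cand & !tr$adipose_mask & !fp
  expect_identical(sum(outside), 0L)                 # nothing else in range
})

test_that("oracle removal recovers the truth mask exactly", {
  for (seed in c(1, 8)) {
    ph <- small_phantom(seed = seed)
    cand <- threshold_segment(ph$volume, adipose_range())
    ms <- remove_false_positives(cand, mode = "oracle", truth = ph$truth)
    expect_identical(ms$final_adipose, ph$truth$adipose_mask)
    # mask-set invariant: final = candidate minus union(removed)
    rem <- Reduce(`|`, ms$removed)
    expect_identical(ms$final_adipose, ms$candidate & !rem)
    expect_true(all(ms$candidate[ms$final_adipose]))
  }
  expect_error(remove_false_positives(array(TRUE, c(4, 4, 4)), mode = "oracle"),
               "truth")
})

test_that("rules mode removes the scanner table and near-air voxels", {
  ph <- small_phantom(seed = 6)
  cand <- threshold_segment(ph$volume, adipose_range())
  ms <- remove_false_positives(cand, volume = ph$volume, mode = "rules",
                               git_mask = ph$truth$git_region)
  # table components (disjoint from the body) removed essentially exactly
  tab_truth <- ph$truth$class_masks$table & cand
  expect_gte(dice_coefficient(ms$removed$table, tab_truth), 0.99)
  # every airway-transition false positive sits near enclosed air
  expect_true(all(ms$removed$B[ph$truth$class_masks$B & cand]))
  # gastrointestinal in-range contents removed via the region mask
  expect_true(all((ms$removed$D | ms$removed$B)[ph$truth$class_masks$D]))
})

test_that("no injected false positives makes removal a no-op", {
  ph <- small_phantom(seed = 4, fp = character(0), grid = c(36L, 34L, 34L))
  cand <- threshold_segment(ph$volume, adipose_range())
  ms <- remove_false_positives(cand, mode = "oracle", truth = ph$truth)
  expect_identical(ms$final_adipose, cand)
})

test_that("quantification arithmetic and conservation", {
  # 1000 adipose voxels at 0.5 mm in-plane, 0.625 mm slice spacing
  dims <- c(10L, 10L, 10L)
  hu <- array(0L, dims)
  vol <- ct_volume(hu, 0.5, 0.625, 1.25)
  body <- array(TRUE, dims)
  final <- array(FALSE, dims)
  final[1:10, 1:10, 1:10] <- TRUE # all 1000
  q <- quantify(final, body, vol, 10)
  expect_equal(q$at_volume_cm3, 1000 * 0.15625 / 1000) # 0.15625 cm^3
  expect_equal(q$at_fraction, 1)
  # fractional case by hand
  final2 <- array(FALSE, dims); final2[seq_len(65)] <- TRUE
  q2 <- quantify(final2, body, vol, 10)
  expect_equal(q2$at_fraction, 0.065)
  expect_equal(q2$at_mass, 0.65)
  expect_equal(q2$nonat_mass, 9.35)
  expect_equal(q2$at_mass + q2$nonat_mass, 10)
  # empty mask conserves mass
  q3 <- quantify(array(FALSE, dims), body, vol, 7.3)
  expect_equal(q3$at_mass, 0)
  expect_identical(q3$nonat_mass, 7.3)
  # masks outside the body are a consistency error
  bad_body <- body; bad_body[1, 1, 1] <- FALSE
  expect_error(quantify(final, bad_body, vol, 10), "outside the body")
})

test_that("body volume equals an independent per-slice area summation", {
  ph <- small_phantom(seed = 9, grid = c(36L, 34L, 34L))
  body <- ph$truth$body_mask
  q <- quantify(ph$truth$adipose_mask, body, ph$volume, 10)
  area_mm2 <- vapply(seq_len(dim(body)[1]),
                     function(s) sum(body[s, , ]) * ph$volume$in_plane_spacing^2,
                     0)
  vol_cm3 <- sum(area_mm2) * ph$volume$slice_spacing / 1000
  expect_equal(q$body_volume_cm3, vol_cm3)
})

test_that("HU range estimation brackets the adipose mode", {
  hm <- default_hu_model()
  hm$adipose$sd <- 8
  ph <- build_phantom(phantom_spec(grid_shape = c(48, 40, 40),
                                   hu_model = hm, seed = 31))
  est <- estimate_hu_range(ph$volume, ph$truth$body_mask)
  expect_false(est$fallback)
  expect_lt(est$hu_min, est$hu_max)
  vals <- ph$volume$hu[ph$truth$adipose_mask]
  coverage <- mean(vals >= est$hu_min & vals <= est$hu_max)
  expect_gte(coverage, 0.95)
})

test_that("degenerate histograms fall back to the default printed range", {
  vol <- ct_volume(array(40L, c(32, 32, 32)), 1, 1, 1)
  body <- array(TRUE, c(32, 32, 32))
  est <- estimate_hu_range(vol, body)
  expect_true(est$fallback)
  expect_equal(c(est$hu_min, est$hu_max), c(-32.2, 10.1))
  expect_error(estimate_hu_range(vol, array(FALSE, c(32, 32, 32))), "empty")
})

test_that("connected components and dilation behave on known geometry", {
  m <- array(FALSE, c(8, 8, 8))
  m[1:2, 1:2, 1:2] <- TRUE       # component 1
  m[6:7, 6:7, 6:7] <- TRUE       # component 2 (far away)
  lab <- label_components(m)
  expect_identical(max(lab), 2L)
  expect_true(all(lab[m] > 0) && all(lab[!m] == 0))
  # diagonal touch merges under 26-connectivity
  m2 <- array(FALSE, c(4, 4, 4)); m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE
  expect_identical(max(label_components(m2)), 1L)
  # dilation by 1 of a single voxel is a 3x3x3 block (clipped at borders)
  m3 <- array(FALSE, c(5, 5, 5)); m3[3, 3, 3] <- TRUE
  d3 <- dilate_mask(m3, 1)
  expect_identical(sum(d3), 27L)
  expect_identical(dilate_mask(m3, 0), m3)
})
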
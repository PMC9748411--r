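test_that("phantom hits the target adipose fraction by voxel counting", {
  ph <- small_phantom(seed = 7)
  tr <- ph$truth
  expect_lt(abs(tr$true_at_fraction_voxelized - 0.065), 0.01)
  expect_equal(tr$true_at_fraction_voxelized,
               sum(tr$adipose_mask) / sum(tr$body_mask))
})

test_that("zero-fat phantom and empty fp plan are the identity case", {
  ph <- build_phantom(phantom_spec(grid_shape = c(40, 36, 36),
                                   target_at_fraction = 0,
                                   fp_plan = character(0), seed = 1))
  expect_identical(sum(ph$truth$adipose_mask), 0L)
  expect_identical(ph$truth$true_at_fraction_voxelized, 0)
  expect_length(ph$truth$class_masks, 0)
})

test_that("phantom mask algebra: disjointness and containment", {
  ph <- small_phantom(seed = 13)
  tr <- ph$truth
  expect_true(all(tr$body_mask[tr$adipose_mask]))       # adipose inside body
  masks <- c(list(adipose = tr$adipose_mask), tr$class_masks)
  for (i in seq_along(masks)) {
    for (j in seq_along(masks)) {
      if (i < j) expect_identical(sum(masks[[i]] & masks[[j]]), 0L)
    }
  }
  # table outside the body, inside the scan
  expect_identical(sum(tr$class_masks$table & tr$body_mask), 0L)
  expect_gt(sum(tr$class_masks$table), 0)
  for (cls in c("A", "B", "C", "D")) {
    expect_true(all(tr$body_mask[tr$class_masks[[cls]]]))
  }
})

test_that("adipose HU values stay within the configured range", {
  ph <- small_phantom(seed = 21)
  rng <- ph$spec$hu_model$adipose$range
  vals <- ph$volume$hu[ph$truth$adipose_mask]
  expect_gte(min(vals), floor(rng[1]))
  expect_lte(max(vals), ceiling(rng[2]))
  # soft tissue / air / bone stay clear of the adipose range
  other <- ph$truth$body_mask & !ph$truth$adipose_mask
  for (cm in ph$truth$class_masks) other <- other & !cm
  other <- other & !ph$truth$git_region
  expect_identical(sum(ph$volume$hu[other] >= rng[1] &
                         ph$volume$hu[other] <= rng[2]), 0L)
})

test_that("phantoms are deterministic under a fixed seed", {
  a <- small_phantom(seed = 3, grid = c(36L, 34L, 34L))
  b <- small_phantom(seed = 3, grid = c(36L, 34L, 34L))
  expect_identical(a$volume$hu, b$volume$hu)
  expect_identical(a$truth$adipose_mask, b$truth$adipose_mask)
})

test_that("infeasible targets and bad specs error", {
  expect_error(phantom_spec(grid_shape = c(16, 16, 16)), "32")
  expect_error(phantom_spec(target_at_fraction = 0.6), "0.5")
  expect_error(phantom_spec(depot_shares = c(neck = 1, sub_carapace = 0.5,
                                             mesenteric = 0, hindlimb = 0)),
               "sum to 1")
  expect_error(
    build_phantom(phantom_spec(grid_shape = c(34, 32, 32),
                               target_at_fraction = 0.45, seed = 1)),
    "infeasible")
})
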
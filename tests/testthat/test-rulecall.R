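test_that("spot counting matches constructed geometry", {
  mask <- disk_mask(56, 28.5, 28.5, 15)
  expect_equal(count_cep8_spots(matrix(10, 56, 56), mask), 0L)
  cr3 <- make_rule_crop(3)
  expect_equal(count_cep8_spots(cr3$cep8, mask), 3L)
  expect_error(count_cep8_spots(matrix(0, 10, 10), matrix(0, 5, 5)), "shape")
  # area band: a giant blob is not a signal point
  big <- matrix(10, 56, 56); big[10:45, 10:45] <- 210
  expect_equal(count_cep8_spots(big, mask), 0L)
})

test_that("positivity is a mean-intensity threshold over the mask", {
  expect_false(assess_positivity(matrix(0, 8, 8), 10))
  expect_true(assess_positivity(matrix(200, 8, 8), 10))
  crop <- matrix(0, 10, 10); crop[3:6, 3:6] <- 200
  mask <- matrix(0, 10, 10); mask[3:6, 3:6] <- 1
  expect_true(assess_positivity(crop, 150, mask))
  expect_false(assess_positivity(crop, 150))
})

test_that("aggregate detection flags fused nuclei and oversized blobs", {
  # single convex ellipse: solidity ~ 1
  single <- disk_mask(64, 32, 32, 18)
  expect_false(detect_aggregate(single))
  # dumbbell of two fused disks: concave, solidity below threshold
  dumb <- pmax(disk_mask(90, 45, 30, 16), disk_mask(90, 45, 60, 16))
  expect_true(detect_aggregate(dumb))
  # oversized blob caught by the area cap
  expect_true(detect_aggregate(disk_mask(120, 60, 60, 40)))
  # empty mask is not an aggregate
  expect_false(detect_aggregate(matrix(0, 20, 20)))
})

test_that("the convex-hull solidity oracle agrees with the dumbbell flag", {
  # oracle: solidity of two fused disks (centers 2r*0.85 apart) from geometry:
  # area = 2*pi*r^2 - lens overlap; hull area ~ rectangle + two half disks
  r <- 16; d <- 30
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  area <- 2 * pi * r^2 - lens
  hull <- pi * r^2 + 2 * r * d
  expect_lt(area / hull, 0.94)  # below the default threshold
  dumb <- pmax(disk_mask(90, 45, 28, r), disk_mask(90, 45, 28 + d, r))
  expect_true(detect_aggregate(dumb))
})

test_that("call_cell composes the interpretation criteria with exclusion precedence", {
  for (k in 0:10) {
    cc <- call_cell(make_rule_crop(k))
    expect_equal(cc$cep8_count, k)
    expect_true(cc$dapi_positive)
    expect_false(cc$cd45_positive)
    expect_false(cc$excluded)
    expect_equal(cc$label, if (k >= 3) "CTC" else "non-CTC")
  }
  # CD45-positive cells are never CTCs
  cc <- call_cell(make_rule_crop(3, cd45_positive = TRUE))
  expect_true(cc$cd45_positive)
  expect_equal(cc$label, "non-CTC")
  # an aggregated mask is excluded regardless of counts
  agg <- make_rule_crop(5)
  agg$dapi <- matrix(15, 90, 90)
  agg$dapi[pmax(disk_mask(90, 45, 30, 16), disk_mask(90, 45, 60, 16)) > 0] <- 180
  agg$cep8 <- matrix(10, 90, 90); agg$cd45 <- matrix(15, 90, 90)
  cc <- call_cell(agg)
  expect_true(cc$excluded)
  expect_equal(cc$label, "excluded")
})

test_that("spot counts and positivity agree with simulator truth at high SNR", {
  p <- sim_params(image_width = 256, image_height = 256, n_nuclei = 6,
                  overlap_fraction = 0, spot_clip_fraction = 0, seed = 101)
  n_ok <- 0; n_tot <- 0; cd45_ok <- 0
  for (s in 1:10) {
    p$seed <- 100 + s
    out <- generate_image(p, sprintf("sim%02d", s))
    crops <- truth_crops(list(out$image), out$truth)
    calls <- call_cells(crops)
    n_tot <- n_tot + nrow(calls)
    n_ok <- n_ok + sum(calls$cep8_count == out$truth$spot_count)
    cd45_ok <- cd45_ok + sum(calls$cd45_positive == out$truth$cd45_positive)
  }
  expect_gte(n_ok / n_tot, 0.95)
  expect_gte(cd45_ok / n_tot, 0.99)
})

test_that("increasing the spot count never flips CTC to non-CTC", {
  labels <- vapply(0:10, function(k) call_cell(make_rule_crop(k))$label, "")
  first_ctc <- match("CTC", labels)
  expect_true(all(labels[seq(first_ctc, 11)] == "CTC"))
})
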
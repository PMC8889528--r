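test_that("all-zero raster maps to an empty mask with a warning", {
  expect_warning(m <- preprocess_dapi(matrix(0, 64, 64)), "empty")
  expect_true(all(m == 0))
  expect_error(preprocess_dapi(array(0, c(4, 4, 2))), "2-D")
})

test_that("a single bright disk yields one component overlapping the disk", {
  img <- disk_mask(128, 64, 64, 20) * 200
  mask <- preprocess_dapi(img)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  expect_equal(max(lab), 1)
  expect_gt(sum(mask * (disk_mask(128, 64, 64, 20) > 0)), 0)
})

test_that("isolated single-pixel speckle is erased by the erosion rounds", {
  mask <- matrix(0, 64, 64)
  mask[cbind(c(10, 30, 50), c(12, 40, 20))] <- 1
  p <- segment_params()
  brush <- matrix(1L, p$morph_kernel, p$morph_kernel)
  m <- EBImage::Image(mask)
  for (i in seq_len(p$morph_iterations)) m <- EBImage::erode(m, brush)
  expect_true(all(EBImage::imageData(m) == 0))
  # and alongside real structure, speckle does not produce boxes
  img <- disk_mask(128, 64, 64, 18) * 200
  img[cbind(c(10, 20, 110), c(12, 100, 30))] <- 255
  full <- preprocess_dapi(img, p)
  expect_equal(nrow(find_nucleus_boxes(full, p)), 1)
})

test_that("large disks survive erosion/dilation with bounded area change", {
  disk <- disk_mask(128, 64, 64, 25)
  p <- segment_params()
  brush <- matrix(1L, p$morph_kernel, p$morph_kernel)
  m <- EBImage::Image(disk)
  for (i in seq_len(p$morph_iterations)) m <- EBImage::erode(m, brush)
  for (i in seq_len(p$morph_iterations)) m <- EBImage::dilate(m, brush)
  out <- EBImage::imageData(m)
  expect_lt(abs(sum(out) - sum(disk)) / sum(disk), 0.2)
})

test_that("find_nucleus_boxes returns exact boxes, filters, and sorts", {
  mask <- matrix(0, 60, 60)
  mask[11:20, 6:15] <- 1    # 10x10
  mask[31:40, 31:40] <- 1   # 10x10
  p <- segment_params(min_contour_area = 50)
  boxes <- find_nucleus_boxes(mask, p, image_id = "m")
  expect_equal(nrow(boxes), 2)
  expect_equal(boxes$row_stop - boxes$row_start, c(10, 10))
  expect_equal(boxes$col_stop - boxes$col_start, c(10, 10))
  expect_equal(boxes$row_start, c(10, 30))  # 0-based, sorted
  expect_equal(boxes$area, c(100, 100))

  # area filter: a component below min_contour_area is excluded
  mask[50:52, 50:52] <- 1
  expect_equal(nrow(find_nucleus_boxes(mask, p)), 2)

  # monotonicity: raising min_contour_area never increases box count
  counts <- vapply(c(0, 5, 9, 50, 101), function(a)
    nrow(find_nucleus_boxes(mask, segment_params(min_contour_area = a))), 0L)
  expect_true(all(diff(counts) <= 0))

  # empty mask
  expect_equal(nrow(find_nucleus_boxes(matrix(0, 10, 10), p)), 0)
})

test_that("crop/paste coordinate round-trip is bit-exact", {
  set.seed(42)
  out <- generate_image(test_sim_params(seed = 42))
  crops <- segment_cells(out$image)
  expect_gt(length(crops), 0)
  for (cr in crops) {
    b <- cr$box
    for (ch in c("dapi", "cep8", "cd45")) {
      expect_equal(dim(cr[[ch]]),
                   c(b$row_stop - b$row_start, b$col_stop - b$col_start))
      src <- out$image[[ch]]
      pasted <- src
      pasted[(b$row_start + 1):b$row_stop, (b$col_start + 1):b$col_stop] <- cr[[ch]]
      expect_identical(pasted, src)
    }
  }
})

test_that("segmentation is deterministic and recalls simulated nuclei", {
  p <- sim_params(image_width = 256, image_height = 256, n_nuclei = 6,
                  overlap_fraction = 0, seed = 7)
  out <- generate_image(p, "det")
  mask1 <- preprocess_dapi(out$image$dapi)
  mask2 <- preprocess_dapi(out$image$dapi)
  expect_identical(mask1, mask2)
  boxes <- find_nucleus_boxes(mask1, segment_params(), "det")
  expect_equal(nrow(boxes), 6)
  m <- match_boxes_to_truth(boxes, out$truth)
  expect_equal(m$recall, 1)
  # each box contains exactly one truth center
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    inside <- sum(out$truth$center_row > b$row_start &
                  out$truth$center_row <= b$row_stop &
                  out$truth$center_col > b$col_start &
                  out$truth$center_col <= b$col_stop)
    expect_equal(inside, 1)
  }
})

test_that("the paper-literal subtractive gradient mode is available", {
  img <- disk_mask(128, 64, 64, 20) * 200
  m <- suppressWarnings(
    preprocess_dapi(img, segment_params(gradient_mode = "subtract")))
  expect_true(is.matrix(m))
  expect_true(all(m %in% c(0, 1)))
})
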
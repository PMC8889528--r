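test_that("generated truth obeys the CTC labeling rule and basic invariants", {
  out <- generate_image(test_sim_params(seed = 3))
  tr <- out$truth
  expect_equal(nrow(tr), 5)
  expect_equal(tr$true_label, ctc_rule(tr$cd45_positive, tr$spot_count))
  expect_true(all(tr$spot_count >= tr$spots_clipped))
  expect_true(all(tr$radius_major / tr$radius_minor <= 1.5 + 1e-9))
  for (ch in c("dapi", "cep8", "cd45")) {
    expect_true(all(out$image[[ch]] >= 0 & out$image[[ch]] <= 255))
    expect_identical(dim(out$image[[ch]]), c(192L, 192L))
  }
})

test_that("n_nuclei = 0 yields pure background and an empty truth list", {
  p <- test_sim_params(); p$n_nuclei <- 0L
  out <- generate_image(p)
  expect_equal(nrow(out$truth), 0)
  # background noise around the base level, no bright nuclei
  expect_lt(max(out$image$dapi), 100)
})

test_that("forced spot count 3 with no CD45 yields all-CTC truth", {
  w <- numeric(9); w[4] <- 1  # all mass on three spots
  p <- test_sim_params(seed = 9, spot_count_distribution = w,
                       cd45_positive_fraction = 0)
  out <- generate_image(p)
  expect_equal(out$truth$spot_count, rep(3L, 5))
  expect_equal(out$truth$true_label, rep("CTC", 5))
})

test_that("identical seed and params give bit-identical output", {
  p <- test_sim_params(seed = 11)
  a <- generate_image(p); b <- generate_image(p)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  ds1 <- generate_dataset(3, p, 0.2)
  ds2 <- generate_dataset(3, p, 0.2)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(ds1$images, ds2$images)
})

test_that("different seeds give different spot-count sequences", {
  ds1 <- generate_dataset(4, test_sim_params(seed = 1), 0.3)
  ds2 <- generate_dataset(4, test_sim_params(seed = 2), 0.3)
  expect_false(identical(ds1$manifest$spot_count, ds2$manifest$spot_count))
})

test_that("dataset manifest rows equal rendered cells and mix tracks prevalence", {
  p <- test_sim_params(seed = 5)
  ds <- generate_dataset(10, p, 0.05)
  expect_equal(nrow(ds$manifest), 10 * p$n_nuclei)
  expect_equal(length(ds$images), 10)

  # binomial oracle: realized CTC fraction within 3 SD of the prevalence
  prev <- 0.049
  n_cells <- 40 * p$n_nuclei
  ds2 <- generate_dataset(40, test_sim_params(seed = 6), prev)
  frac <- mean(ds2$manifest$true_label == "CTC")
  expect_lt(abs(frac - prev), 3 * sqrt(prev * (1 - prev) / n_cells))
})

test_that("over-dense placement fails with an informative error", {
  p <- sim_params(image_width = 64, image_height = 64, n_nuclei = 12,
                  nucleus_radius_range = c(14, 16), overlap_fraction = 0,
                  seed = 1)
  expect_error(generate_image(p), "over-dense")
})
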
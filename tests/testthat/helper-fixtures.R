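# deterministic constructed fixtures, built in code at test time

# a crop with a centered nucleus disk and k disjoint CEP8 spots on a grid
make_rule_crop <- function(k, cd45_positive = FALSE, size = 56,
                           nucleus_radius = 15, spot_radius = 2,
                           dapi_level = 180, cd45_level = 150,
                           cep8_level = 210) {
  stopifnot(k <= 12)
  ctr <- (size + 1) / 2
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  nucleus <- (rows - ctr)^2 + (cols - ctr)^2 <= nucleus_radius^2
  dapi <- matrix(15, size, size); dapi[nucleus] <- dapi_level
  cd45 <- matrix(15, size, size)
  if (cd45_positive) cd45[nucleus] <- cd45_level
  cep8 <- matrix(10, size, size)
  offs <- expand.grid(dr = c(-12, -6, 0, 6, 12), dc = c(-12, -6, 0, 6, 12))
  offs <- offs[offs$dr^2 + offs$dc^2 <= (nucleus_radius - spot_radius - 1)^2, ]
  offs <- offs[order(offs$dr^2 + offs$dc^2, offs$dr, offs$dc), ][seq_len(k), , drop = FALSE]
  for (i in seq_len(nrow(offs))) {
    spot <- (rows - (ctr + offs$dr[i]))^2 + (cols - (ctr + offs$dc[i]))^2 <= spot_radius^2
    cep8[spot] <- cep8_level
  }
  structure(list(dapi = dapi, cep8 = cep8, cd45 = cd45,
                 cell_ref = sprintf("fix_k%02d", k)),
            class = "cell_crop")
}

# binary matrix with a filled disk
disk_mask <- function(size, ctr_row, ctr_col, radius) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((rows - ctr_row)^2 + (cols - ctr_col)^2 <= radius^2) * 1
}

# small fast simulation defaults shared by tests
test_sim_params <- function(seed = 1L, ...) {
  sim_params(image_width = 192, image_height = 192, n_nuclei = 5,
             overlap_fraction = 0, seed = seed, ...)
}
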
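#' Simulation parameters for synthetic imFISH images
#'
#' Bundles the knobs of the synthetic imFISH image generator. The generator
#' emulates the phenomenology of three-channel micrographs: round-ish bright
#' nuclei on a dark background (DAPI), punctate CEP8 hybridization spots
#' (including spots clipped at the nucleus boundary), diffuse CD45 staining
#' over positive cells, occasional overlapping nuclei, and per-image
#' exposure/noise variation.
#'
#' @param image_width,image_height Image size in pixels.
#' @param n_nuclei Number of nuclei rendered per image.
#' @param nucleus_radius_range Length-2 vector, min/max semi-major axis in
#'   pixels. Nuclei are ellipses with axis ratio at most 1.5.
#' @param spot_count_distribution Numeric vector of probability weights over
#'   spot counts \code{0..(length-1)}; normalized to sum to one. The default
#'   puts most mass on two spots (the diploid centromere count) with a tail
#'   of aneuploid counts up to eight.
#' @param spot_radius Radius of a rendered CEP8 spot, pixels.
#' @param spot_clip_fraction Expected fraction of spots placed straddling the
#'   nucleus boundary, emulating centromeres not fully inside the nucleus.
#' @param cd45_positive_fraction Probability that a cell is CD45-positive
#'   (a leukocyte) under unconditional sampling.
#' @param overlap_fraction Probability that a nucleus is placed overlapping a
#'   previously placed one.
#' @param background_noise_sd Standard deviation of additive Gaussian noise,
#'   8-bit intensity units.
#' @param exposure_gain_range Length-2 vector; each image's intensities are
#'   scaled by a gain drawn uniformly from this range.
#' @param dapi_intensity,cep8_intensity,cd45_intensity Nominal foreground
#'   intensities (8-bit) for the nucleus fill, spot disks, and CD45 lift.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return An object of class \code{sim_params} (a validated list).
#' @export
sim_params <- function(image_width = 256, image_height = 256,
                       n_nuclei = 8,
                       nucleus_radius_range = c(11, 16),
                       spot_count_distribution = c(0.02, 0.08, 0.55, 0.15,
                                                   0.10, 0.05, 0.03, 0.01, 0.01),
                       spot_radius = 2,
                       spot_clip_fraction = 0.1,
                       cd45_positive_fraction = 0.6,
                       overlap_fraction = 0.05,
                       background_noise_sd = 6,
                       exposure_gain_range = c(0.9, 1.1),
                       dapi_intensity = 180,
                       cep8_intensity = 200,
                       cd45_intensity = 140,
                       seed = 1L) {
  p <- list(image_width = as.integer(image_width),
            image_height = as.integer(image_height),
            n_nuclei = as.integer(n_nuclei),
            nucleus_radius_range = as.numeric(nucleus_radius_range),
            spot_count_distribution = as.numeric(spot_count_distribution),
            spot_radius = as.numeric(spot_radius),
            spot_clip_fraction = as.numeric(spot_clip_fraction),
            cd45_positive_fraction = as.numeric(cd45_positive_fraction),
            overlap_fraction = as.numeric(overlap_fraction),
            background_noise_sd = as.numeric(background_noise_sd),
            exposure_gain_range = as.numeric(exposure_gain_range),
            dapi_intensity = as.numeric(dapi_intensity),
            cep8_intensity = as.numeric(cep8_intensity),
            cd45_intensity = as.numeric(cd45_intensity),
            seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  stopifnot(p$image_width >= 16, p$image_height >= 16, p$n_nuclei >= 0,
            length(p$nucleus_radius_range) == 2,
            p$nucleus_radius_range[1] <= p$nucleus_radius_range[2],
            p$nucleus_radius_range[1] > 0,
            length(p$spot_count_distribution) >= 1,
            all(p$spot_count_distribution >= 0),
            sum(p$spot_count_distribution) > 0,
            p$spot_radius > 0,
            p$spot_clip_fraction >= 0, p$spot_clip_fraction <= 1,
            p$cd45_positive_fraction >= 0, p$cd45_positive_fraction <= 1,
            p$overlap_fraction >= 0, p$overlap_fraction <= 1,
            p$background_noise_sd >= 0,
            length(p$exposure_gain_range) == 2,
            p$exposure_gain_range[1] <= p$exposure_gain_range[2],
            p$exposure_gain_range[1] > 0,
            length(p$seed) == 1, is.finite(p$seed))
  invisible(p)
}

#' The CTC calling rule applied to ground-truth attributes
#'
#' A cell is a CTC when it is CD45-negative and carries three or more CEP8
#' hybridization signals (the nucleus itself is DAPI-positive by
#' construction).
#'
#' @param cd45_positive Logical vector.
#' @param spot_count Integer vector of CEP8 signal counts.
#' @return Character vector, \code{"CTC"} or \code{"non-CTC"}.
#' @export
ctc_rule <- function(cd45_positive, spot_count) {
  ifelse(!cd45_positive & spot_count >= 3, "CTC", "non-CTC")
}

# pixel-center mask of an ellipse (center in 1-based pixel coordinates)
ellipse_mask <- function(h, w, cr, cc, a, b, theta) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dr <- rows - cr
  dc <- cols - cc
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

disk_stamp <- function(h, w, cr, cc, radius) {
  r0 <- max(1L, floor(cr - radius)); r1 <- min(h, ceiling(cr + radius))
  c0 <- max(1L, floor(cc - radius)); c1 <- min(w, ceiling(cc + radius))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- matrix(r0:r1, r1 - r0 + 1, c1 - c0 + 1)
  cols <- matrix(c0:c1, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
  keep <- (rows - cr)^2 + (cols - cc)^2 <= radius^2
  cbind(row = rows[keep], col = cols[keep])
}

# sample a point on the ellipse boundary (returns c(row, col))
ellipse_boundary_point <- function(cr, cc, a, b, theta) {
  t <- stats::runif(1, 0, 2 * pi)
  u <- a * cos(t); v <- b * sin(t)
  c(cr + u * sin(theta) + v * cos(theta),
    cc + u * cos(theta) - v * sin(theta))
}

sample_spot_count <- function(weights, min_count = 0L) {
  counts <- seq_along(weights) - 1L
  keep <- counts >= min_count
  if (!any(keep & weights > 0))
    stop("spot count distribution has no mass at or above ", min_count)
  w <- weights * keep
  sample(counts, 1L, prob = w / sum(w))
}

#' Generate one synthetic imFISH image with ground truth
#'
#' Renders nuclei as filled ellipses in the DAPI channel, CEP8 spots as small
#' bright disks (a configurable fraction straddling the nucleus boundary),
#' and a uniform CD45 intensity lift over CD45-positive nuclei, then applies
#' a per-image exposure gain and additive Gaussian noise and quantizes to
#' 8-bit. Output is deterministic for a fixed seed.
#'
#' @param params A \code{\link{sim_params}} object.
#' @param image_id Identifier stored with the image and its truth records.
#' @param force_labels Optional character vector of length \code{n_nuclei}
#'   with entries \code{"CTC"}/\code{"non-CTC"}; cell attributes (CD45
#'   status, spot count) are then sampled conditional on the requested label.
#' @return A list with elements \code{image} (a \code{multichannel_image}:
#'   list of \code{dapi}, \code{cep8}, \code{cd45} integer matrices in
#'   0..255 plus \code{image_id}) and \code{truth} (a data frame of
#'   ground-truth cell records).
#' @export
generate_image <- function(params, image_id = "img_001", force_labels = NULL) {
  validate_sim_params(params)
  if (!is.null(force_labels))
    stopifnot(length(force_labels) == params$n_nuclei,
              all(force_labels %in% c("CTC", "non-CTC")))
  set.seed(params$seed)
  h <- params$image_height; w <- params$image_width
  rr <- params$nucleus_radius_range

  centers <- matrix(numeric(0), 0, 2)
  amax <- numeric(0)
  cells <- vector("list", params$n_nuclei)
  overlaps <- logical(params$n_nuclei)
  n <- params$n_nuclei
  for (i in seq_len(n)) {
    a <- stats::runif(1, rr[1], rr[2])
    ratio <- stats::runif(1, 1, 1.5)
    b <- a / ratio
    theta <- stats::runif(1, 0, pi)
    want_overlap <- i > 1 && stats::runif(1) < params$overlap_fraction
    placed <- FALSE
    for (attempt in seq_len(500)) {
      cr <- stats::runif(1, a + 2, h - a - 2)
      cc <- stats::runif(1, a + 2, w - a - 2)
      if (nrow(centers) == 0) {
        if (!want_overlap) { placed <- TRUE; break }
        next
      }
      d <- sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2)
      if (want_overlap) {
        # overlap a neighbor but keep centers distinct
        if (any(d < (amax + a) * 0.8 & d > pmax(amax, a) * 0.5)) {
          overlaps[i] <- TRUE
          overlaps[which.min(d)] <- TRUE
          placed <- TRUE; break
        }
      } else if (all(d > amax + a + 20)) {
        # 20 px clearance keeps non-overlapping nuclei separable after the
        # segmenter's smoothing and dilation steps
        placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place nucleus ", i, " of ", n,
           " at the requested overlap fraction; parameters are over-dense")
    centers <- rbind(centers, c(cr, cc))
    amax <- c(amax, a)
    cells[[i]] <- list(cr = cr, cc = cc, a = a, b = b, theta = theta)
  }

  dapi <- matrix(20, h, w)
  cep8 <- matrix(15, h, w)
  cd45 <- matrix(15, h, w)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- cells[[i]]
    if (is.null(force_labels)) {
      cd45_pos <- stats::runif(1) < params$cd45_positive_fraction
      count <- sample_spot_count(params$spot_count_distribution)
    } else if (force_labels[i] == "CTC") {
      cd45_pos <- FALSE
      count <- sample_spot_count(params$spot_count_distribution, min_count = 3L)
    } else {
      repeat {
        cd45_pos <- stats::runif(1) < params$cd45_positive_fraction
        count <- sample_spot_count(params$spot_count_distribution)
        if (cd45_pos || count < 3) break
      }
    }

    mask <- ellipse_mask(h, w, ci$cr, ci$cc, ci$a, ci$b, ci$theta)
    dapi[mask] <- pmax(dapi[mask],
                       params$dapi_intensity * stats::runif(1, 0.9, 1.1))
    if (cd45_pos)
      cd45[mask] <- pmax(cd45[mask],
                         15 + params$cd45_intensity * stats::runif(1, 0.85, 1.15))

    # spot placement: clipped spots sit on the boundary, interior spots are
    # rejection-sampled fully inside; pairwise separation > 2 x spot radius
    # keeps the rendered disks disjoint. Greedy placement restarts from
    # scratch when it dead-ends.
    n_clip <- if (count > 0) stats::rbinom(1, count, params$spot_clip_fraction) else 0L
    sep <- 2 * params$spot_radius + 0.4
    spot_centers <- NULL
    for (restart in seq_len(60)) {
      centers_try <- matrix(numeric(0), 0, 2)
      failed <- FALSE
      for (s in seq_len(count)) {
        ok <- FALSE
        for (attempt in seq_len(200)) {
          if (s <= n_clip) {
            pt <- ellipse_boundary_point(ci$cr, ci$cc, ci$a, ci$b, ci$theta)
          } else {
            shrink <- params$spot_radius
            aa <- max(ci$a - shrink, 1); bb <- max(ci$b - shrink, 1)
            t2 <- stats::runif(1, 0, 2 * pi); r2 <- sqrt(stats::runif(1))
            u <- aa * r2 * cos(t2); v <- bb * r2 * sin(t2)
            pt <- c(ci$cr + u * sin(ci$theta) + v * cos(ci$theta),
                    ci$cc + u * cos(ci$theta) - v * sin(ci$theta))
          }
          if (pt[1] < 2 || pt[1] > h - 1 || pt[2] < 2 || pt[2] > w - 1) next
          if (nrow(centers_try) == 0 ||
              all((centers_try[, 1] - pt[1])^2 + (centers_try[, 2] - pt[2])^2 > sep^2)) {
            ok <- TRUE; break
          }
        }
        if (!ok) { failed <- TRUE; break }
        centers_try <- rbind(centers_try, pt)
      }
      if (!failed) { spot_centers <- centers_try; break }
    }
    if (is.null(spot_centers))
      stop("could not place ", count, " disjoint spots in nucleus ", i)
    for (s in seq_len(count)) {
      px <- disk_stamp(h, w, spot_centers[s, 1], spot_centers[s, 2],
                       params$spot_radius)
      if (!is.null(px)) {
        idx <- px[, 1] + (px[, 2] - 1) * h
        cep8[idx] <- pmax(cep8[idx],
                          params$cep8_intensity * stats::runif(1, 0.9, 1.1))
      }
    }

    truth[[i]] <- data.frame(
      image_id = image_id,
      cell_id = sprintf("%s_c%02d", image_id, i),
      center_row = ci$cr, center_col = ci$cc,
      radius_major = ci$a, radius_minor = ci$b, orientation = ci$theta,
      spot_count = as.integer(count), spots_clipped = as.integer(n_clip),
      cd45_positive = cd45_pos, overlaps_neighbor = NA,
      true_label = ctc_rule(cd45_pos, count),
      stringsAsFactors = FALSE)
  }

  gain <- stats::runif(1, params$exposure_gain_range[1], params$exposure_gain_range[2])
  quantize <- function(m) {
    m <- m * gain + matrix(stats::rnorm(h * w, 0, params$background_noise_sd), h, w)
    matrix(as.integer(round(pmin(pmax(m, 0), 255))), h, w)
  }
  img <- structure(list(dapi = quantize(dapi), cep8 = quantize(cep8),
                        cd45 = quantize(cd45), image_id = image_id),
                   class = "multichannel_image")
  truth <- if (n > 0) do.call(rbind, truth) else empty_truth()
  if (n > 0) truth$overlaps_neighbor <- overlaps
  list(image = img, truth = truth)
}

empty_truth <- function() {
  data.frame(image_id = character(0), cell_id = character(0),
             center_row = numeric(0), center_col = numeric(0),
             radius_major = numeric(0), radius_minor = numeric(0),
             orientation = numeric(0), spot_count = integer(0),
             spots_clipped = integer(0), cd45_positive = logical(0),
             overlaps_neighbor = logical(0), true_label = character(0),
             stringsAsFactors = FALSE)
}

#' Cut per-cell crops at ground-truth nucleus boxes
#'
#' Bypasses segmentation: crops each cell at the bounding box of its
#' ground-truth ellipse (plus a margin), which is useful for benchmarking
#' the classifier in isolation from the segmenter.
#'
#' @param images List of \code{multichannel_image} objects.
#' @param manifest Ground-truth data frame from
#'   \code{\link{generate_dataset}}.
#' @param margin Pixels added around the ellipse bounding box (clamped to
#'   the image).
#' @return List of \code{cell_crop} objects, aligned with the manifest rows.
#' @export
truth_crops <- function(images, manifest, margin = 4) {
  by_id <- stats::setNames(images, vapply(images, `[[`, "", "image_id"))
  lapply(seq_len(nrow(manifest)), function(i) {
    tr <- manifest[i, ]
    img <- by_id[[tr$image_id]]
    if (is.null(img)) stop("manifest references unknown image ", tr$image_id)
    h <- nrow(img$dapi); w <- ncol(img$dapi)
    a <- tr$radius_major; b <- tr$radius_minor; th <- tr$orientation
    er <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
    ec <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
    box <- data.frame(
      row_start = max(floor(tr$center_row - er - margin) - 1, 0),
      col_start = max(floor(tr$center_col - ec - margin) - 1, 0),
      row_stop = min(ceiling(tr$center_row + er + margin), h),
      col_stop = min(ceiling(tr$center_col + ec + margin), w),
      source_image_id = tr$image_id, stringsAsFactors = FALSE)
    box$area <- (box$row_stop - box$row_start) * (box$col_stop - box$col_start)
    structure(list(box = box,
                   dapi = crop_channel(img$dapi, box),
                   cep8 = crop_channel(img$cep8, box),
                   cd45 = crop_channel(img$cd45, box),
                   cell_ref = tr$cell_id),
              class = "cell_crop")
  })
}

#' Generate a dataset of synthetic imFISH images
#'
#' Draws a per-cell CTC indicator at the requested prevalence, renders
#' \code{n_images} images whose cells realize those labels, and returns (and
#' optionally writes) the images together with a ground-truth manifest. The
#' master seed in \code{params} expands into independent per-image substream
#' seeds, so each image is individually reproducible.
#'
#' @param n_images Number of images.
#' @param params A \code{\link{sim_params}} object; \code{params$seed} is the
#'   master seed.
#' @param ctc_prevalence Probability that a rendered cell is a CTC; must lie
#'   strictly between 0 and 1.
#' @param dir Optional output directory: each image is written as an RGB PNG
#'   (R=CD45, G=CEP8, B=DAPI) with a CSV manifest and YAML parameter sidecar.
#' @return Invisibly, a list with \code{images} (list of
#'   \code{multichannel_image}) and \code{manifest} (ground-truth data frame,
#'   one row per rendered cell).
#' @export
generate_dataset <- function(n_images, params, ctc_prevalence, dir = NULL) {
  stopifnot(n_images >= 1, ctc_prevalence > 0, ctc_prevalence < 1)
  validate_sim_params(params)
  set.seed(params$seed)
  image_seeds <- sample.int(.Machine$integer.max - 1L, n_images)
  labels <- matrix(stats::rbinom(n_images * params$n_nuclei, 1, ctc_prevalence),
                   n_images, params$n_nuclei)
  images <- vector("list", n_images)
  manifests <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    pi_ <- params
    pi_$seed <- image_seeds[i]
    out <- generate_image(pi_, image_id = sprintf("img_%04d", i),
                          force_labels = ifelse(labels[i, ] == 1, "CTC", "non-CTC"))
    images[[i]] <- out$image
    manifests[[i]] <- out$truth
  }
  manifest <- do.call(rbind, manifests)
  rownames(manifest) <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (img in images)
      write_image(img, file.path(dir, paste0(img$image_id, ".png")))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    sidecar <- unclass(params)
    sidecar$channel_map <- list(R = "cd45", G = "cep8", B = "dapi")
    sidecar$ctc_prevalence <- ctc_prevalence
    sidecar$n_images <- n_images
    yaml::write_yaml(sidecar, file.path(dir, "params.yaml"))
  }
  invisible(list(images = images, manifest = manifest))
}
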
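#' Segmentation parameters
#'
#' Parameters of the DAPI-channel nucleus localization pipeline: Gaussian
#' denoise, gradient extraction, binarization, averaging smooth, and four
#' rounds of erosion followed by four rounds of dilation before contour
#' boxing.
#'
#' @param gaussian_kernel Odd width of the Gaussian denoising kernel, pixels.
#' @param gradient_mode \code{"magnitude"} uses |dx| + |dy|;
#'   \code{"subtract"} keeps regions of high horizontal and low vertical
#'   gradient, max(|dx| - |dy|, 0). \code{"magnitude"} is the default:
#'   the subtractive construction favors elongated structures and can
#'   under-segment round nuclei.
#' @param gradient_clip Clip negative values of the subtractive gradient map
#'   to zero (only relevant for \code{gradient_mode = "subtract"}).
#' @param binarize_threshold Intensity threshold in \code{[0, 255]} applied
#'   to the (max-normalized) gradient map, or \code{"otsu"}.
#' @param smooth_kernel Odd width of the averaging (box) smoothing kernel.
#' @param binarize_order \code{"smooth_then_binarize"} (default) box-smooths
#'   the gradient map and binarizes once; \code{"binarize_then_smooth"}
#'   binarizes first, then box-smooths the binary image and re-binarizes by
#'   majority vote.
#' @param morph_kernel Width of the square morphological structuring element.
#' @param pre_dilate Number of dilations applied before the erosion rounds.
#'   The gradient step leaves a thin ring around each nucleus whose contour
#'   lacks detail; expanding it first (and filling, see \code{fill_holes})
#'   closes the ring so the erosion rounds do not fragment it.
#' @param morph_iterations Number of erosions, then the same number of
#'   dilations (default 4).
#' @param min_contour_area Components smaller than this many pixels are not
#'   boxed.
#' @param fill_holes Fill interior holes of the mask before the erosion
#'   rounds, so gradient rings become solid nucleus regions.
#' @param pad_px Padding added on each side of a bounding box (clamped to
#'   the image).
#' @return An object of class \code{segment_params}.
#' @export
segment_params <- function(gaussian_kernel = 5,
                           gradient_mode = c("magnitude", "subtract"),
                           gradient_clip = TRUE,
                           binarize_threshold = "otsu",
                           smooth_kernel = 9,
                           binarize_order = c("smooth_then_binarize",
                                              "binarize_then_smooth"),
                           morph_kernel = 3,
                           pre_dilate = 1,
                           morph_iterations = 4,
                           min_contour_area = 100,
                           fill_holes = TRUE,
                           pad_px = 0) {
  gradient_mode <- match.arg(gradient_mode)
  binarize_order <- match.arg(binarize_order)
  stopifnot(gaussian_kernel >= 1, gaussian_kernel %% 2 == 1,
            smooth_kernel >= 1, smooth_kernel %% 2 == 1,
            morph_kernel >= 1, pre_dilate >= 0,
            morph_iterations >= 0, min_contour_area >= 0,
            pad_px >= 0)
  if (!identical(binarize_threshold, "otsu"))
    stopifnot(is.numeric(binarize_threshold),
              binarize_threshold >= 0, binarize_threshold <= 255)
  structure(list(gaussian_kernel = as.integer(gaussian_kernel),
                 gradient_mode = gradient_mode,
                 gradient_clip = isTRUE(gradient_clip),
                 binarize_threshold = binarize_threshold,
                 smooth_kernel = as.integer(smooth_kernel),
                 binarize_order = binarize_order,
                 morph_kernel = as.integer(morph_kernel),
                 pre_dilate = as.integer(pre_dilate),
                 morph_iterations = as.integer(morph_iterations),
                 min_contour_area = as.numeric(min_contour_area),
                 fill_holes = isTRUE(fill_holes),
                 pad_px = as.integer(pad_px)),
            class = "segment_params")
}

gaussian_brush <- function(k) {
  if (k <= 1) return(matrix(1, 1, 1))
  EBImage::makeBrush(k, shape = "gaussian", sigma = k / 4)
}

sobel_gradients <- function(img) {
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dcol
  sy <- t(sx)                                          # d/drow
  list(gx = EBImage::filter2(img, sx, boundary = "replicate"),
       gy = EBImage::filter2(img, sy, boundary = "replicate"))
}

binarize <- function(img, threshold) {
  rng <- range(img)
  if (rng[2] <= rng[1]) return(matrix(0, nrow(img), ncol(img)))
  scaled <- (img - rng[1]) / (rng[2] - rng[1])
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  } else threshold / 255
  (scaled > thr) * 1
}

#' Locate candidate nucleus regions in a DAPI channel
#'
#' Applies, in order: Gaussian denoise, gradient extraction, a second
#' Gaussian denoise, binarization, averaging smooth, and
#' \code{morph_iterations} erosions followed by the same number of dilations
#' with a square structuring element. With \code{fill_holes = TRUE} the
#' gradient ring around each nucleus is filled into a solid region.
#'
#' @param dapi 2-D numeric matrix of DAPI intensities (0..255).
#' @param params A \code{\link{segment_params}} object.
#' @return Binary (0/1) matrix of candidate nucleus regions, same size as
#'   the input. Warns (does not fail) if the mask is empty.
#' @export
preprocess_dapi <- function(dapi, params = segment_params()) {
  if (!is.matrix(dapi) || !is.numeric(dapi[1]))
    stop("dapi must be a 2-D numeric matrix")
  if (length(dapi) == 0) stop("dapi raster is empty")
  img <- dapi / 255
  img <- EBImage::filter2(img, gaussian_brush(params$gaussian_kernel),
                          boundary = "replicate")
  g <- sobel_gradients(img)
  grad <- if (params$gradient_mode == "magnitude") {
    abs(g$gx) + abs(g$gy)
  } else {
    d <- abs(g$gx) - abs(g$gy)
    if (params$gradient_clip) pmax(d, 0) else d
  }
  grad <- EBImage::filter2(grad, gaussian_brush(params$gaussian_kernel),
                           boundary = "replicate")

  box <- matrix(1, params$smooth_kernel, params$smooth_kernel)
  box <- box / sum(box)
  if (params$binarize_order == "smooth_then_binarize") {
    grad <- EBImage::filter2(grad, box, boundary = "replicate")
    mask <- binarize(grad, params$binarize_threshold)
  } else {
    mask <- binarize(grad, params$binarize_threshold)
    sm <- EBImage::filter2(mask, box, boundary = "replicate")
    mask <- (sm > 0.5) * 1  # majority vote re-binarization
  }

  if (any(mask > 0)) {
    brush <- matrix(1L, params$morph_kernel, params$morph_kernel)
    m <- EBImage::Image(mask)
    for (i in seq_len(params$pre_dilate)) m <- EBImage::dilate(m, brush)
    if (params$fill_holes) m <- EBImage::fillHull(m)
    for (i in seq_len(params$morph_iterations)) m <- EBImage::erode(m, brush)
    for (i in seq_len(params$morph_iterations)) m <- EBImage::dilate(m, brush)
    mask <- EBImage::imageData(m)
  }
  mask <- (mask > 0) * 1
  if (!any(mask > 0)) warning("segmentation mask is empty")
  mask
}

#' Bounding boxes of connected mask components
#'
#' One minimal axis-aligned box per connected foreground component with area
#' at least \code{min_contour_area}. Coordinates are 0-based half-open pixel
#' index intervals; boxes are sorted by \code{(row_start, col_start)}.
#'
#' @param mask Binary matrix.
#' @param params A \code{\link{segment_params}} object.
#' @param image_id Identifier recorded in the output.
#' @return Data frame with columns \code{row_start}, \code{col_start},
#'   \code{row_stop}, \code{col_stop}, \code{area} (box area in pixels), and
#'   \code{source_image_id}.
#' @export
find_nucleus_boxes <- function(mask, params = segment_params(),
                               image_id = NA_character_) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1, FALSE, TRUE)))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((mask > 0) * 1)))
  n <- max(lab)
  out <- empty_boxes()
  if (n >= 1) {
    h <- nrow(mask); w <- ncol(mask)
    for (k in seq_len(n)) {
      idx <- which(lab == k)
      if (length(idx) < params$min_contour_area) next
      rows <- ((idx - 1) %% h) + 1
      cols <- ((idx - 1) %/% h) + 1
      rs <- max(min(rows) - 1 - params$pad_px, 0)
      cs <- max(min(cols) - 1 - params$pad_px, 0)
      re <- min(max(rows) + params$pad_px, h)
      ce <- min(max(cols) + params$pad_px, w)
      out <- rbind(out, data.frame(row_start = rs, col_start = cs,
                                   row_stop = re, col_stop = ce,
                                   area = (re - rs) * (ce - cs),
                                   source_image_id = image_id,
                                   stringsAsFactors = FALSE))
    }
    out <- out[order(out$row_start, out$col_start), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

empty_boxes <- function() {
  data.frame(row_start = integer(0), col_start = integer(0),
             row_stop = integer(0), col_stop = integer(0),
             area = numeric(0), source_image_id = character(0),
             stringsAsFactors = FALSE)
}

#' Cut a crop out of a channel at a box
#'
#' @param channel 2-D matrix.
#' @param box One row of a box data frame (0-based, half-open).
#' @return The sub-matrix.
#' @export
crop_channel <- function(channel, box) {
  channel[(box$row_start + 1):box$row_stop,
          (box$col_start + 1):box$col_stop, drop = FALSE]
}

#' Segment a multi-channel image into per-cell crops
#'
#' Runs \code{\link{preprocess_dapi}} and \code{\link{find_nucleus_boxes}}
#' on the DAPI channel and cuts crops at identical coordinates from all
#' three channels.
#'
#' @param image A \code{multichannel_image}.
#' @param params A \code{\link{segment_params}} object.
#' @return List of \code{cell_crop} objects, each with \code{box} and
#'   \code{dapi}, \code{cep8}, \code{cd45} crop matrices.
#' @export
segment_cells <- function(image, params = segment_params()) {
  stopifnot(inherits(image, "multichannel_image"))
  mask <- suppressWarnings(preprocess_dapi(image$dapi, params))
  boxes <- find_nucleus_boxes(mask, params, image_id = image$image_id)
  lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    structure(list(box = b,
                   dapi = crop_channel(image$dapi, b),
                   cep8 = crop_channel(image$cep8, b),
                   cd45 = crop_channel(image$cd45, b),
                   cell_ref = sprintf("%s_%03d", image$image_id, i)),
              class = "cell_crop")
  })
}

#' Match segmented boxes to ground-truth cell centers
#'
#' A truth cell is recalled when its center falls inside some box; each box
#' is assigned the label of the nearest contained center (ties broken by
#' distance to the box center).
#'
#' @param boxes Box data frame from \code{\link{find_nucleus_boxes}} (or the
#'   \code{box} rows of crops).
#' @param truth Ground-truth data frame from the simulator.
#' @return List with \code{recall} (fraction of truth centers inside a box),
#'   \code{box_label} (character vector per box, \code{NA} when no center is
#'   contained), and \code{box_cell_id}.
#' @export
match_boxes_to_truth <- function(boxes, truth) {
  nb <- nrow(boxes)
  box_label <- rep(NA_character_, nb)
  box_cell <- rep(NA_character_, nb)
  hit <- logical(nrow(truth))
  for (i in seq_len(nb)) {
    b <- boxes[i, ]
    inside <- which(truth$center_row > b$row_start & truth$center_row <= b$row_stop &
                    truth$center_col > b$col_start & truth$center_col <= b$col_stop &
                    (!("image_id" %in% names(truth)) |
                       is.na(b$source_image_id) |
                       truth$image_id == b$source_image_id))
    if (length(inside) == 0) next
    hit[inside] <- TRUE
    bc <- c((b$row_start + b$row_stop) / 2, (b$col_start + b$col_stop) / 2)
    d <- (truth$center_row[inside] - bc[1])^2 + (truth$center_col[inside] - bc[2])^2
    j <- inside[which.min(d)]
    box_label[i] <- truth$true_label[j]
    box_cell[i] <- truth$cell_id[j]
  }
  list(recall = if (nrow(truth)) mean(hit) else NA_real_,
       box_label = box_label, box_cell_id = box_cell)
}
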
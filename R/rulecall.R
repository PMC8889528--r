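#' Parameters of the rule-based CTC caller
#'
#' Operational thresholds behind the interpretation criteria: exclude
#' aggregated/superposed nuclei, require DAPI positivity, require CD45
#' negativity, and count CEP8 signal points (a cell is a CTC when the count
#' reaches three).
#'
#' @param cep8_spot_threshold Intensity threshold for CEP8 spot foreground
#'   (0..255) or \code{"otsu"}. The fixed default is robust to spot-free
#'   crops, where Otsu would split background noise.
#' @param min_spot_area,max_spot_area Connected components with pixel area
#'   outside this band are not counted as signal points.
#' @param mask_dilate_px The nucleus mask is dilated by this many pixels
#'   (about one spot radius) so border-clipped spots can be counted.
#' @param border_overlap_min Minimum fraction of a spot's area that must lie
#'   within the dilated nucleus mask for the spot to count.
#' @param cd45_mean_threshold Mean masked CD45 intensity at or above which a
#'   cell is CD45-positive.
#' @param dapi_mean_threshold Mean masked DAPI intensity at or above which a
#'   cell is DAPI-positive.
#' @param aggregate_solidity_min Masks whose largest component has solidity
#'   (area / convex hull area) below this are flagged as aggregates.
#' @param aggregate_area_max Masks whose largest component exceeds this area
#'   (pixels) are flagged as aggregates.
#' @return An object of class \code{call_params}.
#' @export
call_params <- function(cep8_spot_threshold = 100,
                        min_spot_area = 4, max_spot_area = 200,
                        mask_dilate_px = 3,
                        border_overlap_min = 0.5,
                        cd45_mean_threshold = 80,
                        dapi_mean_threshold = 60,
                        aggregate_solidity_min = 0.94,
                        aggregate_area_max = 1100) {
  stopifnot(min_spot_area <= max_spot_area, min_spot_area >= 0,
            mask_dilate_px >= 0,
            border_overlap_min >= 0, border_overlap_min <= 1,
            cd45_mean_threshold >= 0, cd45_mean_threshold <= 255,
            dapi_mean_threshold >= 0, dapi_mean_threshold <= 255,
            aggregate_solidity_min >= 0, aggregate_solidity_min <= 1,
            aggregate_area_max > 0)
  if (!identical(cep8_spot_threshold, "otsu"))
    stopifnot(is.numeric(cep8_spot_threshold),
              cep8_spot_threshold >= 0, cep8_spot_threshold <= 255)
  structure(list(cep8_spot_threshold = cep8_spot_threshold,
                 min_spot_area = min_spot_area, max_spot_area = max_spot_area,
                 mask_dilate_px = as.integer(mask_dilate_px),
                 border_overlap_min = border_overlap_min,
                 cd45_mean_threshold = cd45_mean_threshold,
                 dapi_mean_threshold = dapi_mean_threshold,
                 aggregate_solidity_min = aggregate_solidity_min,
                 aggregate_area_max = aggregate_area_max),
            class = "call_params")
}

#' Nucleus mask of a DAPI crop
#'
#' Otsu-thresholds the crop, fills holes, and keeps the largest connected
#' component.
#'
#' @param dapi_crop 2-D matrix (0..255).
#' @return Binary matrix of the same size (all zero when nothing exceeds
#'   threshold).
#' @export
nucleus_mask_from_dapi <- function(dapi_crop) {
  m <- binarize(dapi_crop, "otsu")
  if (!any(m > 0)) return(m)
  m <- EBImage::fillHull(EBImage::Image(m))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  if (max(lab) > 1) {
    areas <- tabulate(lab[lab > 0])
    m <- (lab == which.max(areas)) * 1
  } else m <- EBImage::imageData(m)
  (m > 0) * 1
}

#' Count CEP8 signal points in a crop
#'
#' Thresholds the CEP8 crop, labels connected components, and counts those
#' whose area lies in the configured band and whose overlap with the nucleus
#' mask (dilated by about one spot radius so border-clipped signals are
#' admitted) is at least \code{border_overlap_min}.
#'
#' @param cep8_crop 2-D matrix (0..255).
#' @param nucleus_mask Binary matrix of the same shape.
#' @param params A \code{\link{call_params}} object.
#' @return Integer spot count.
#' @export
count_cep8_spots <- function(cep8_crop, nucleus_mask, params = call_params()) {
  if (!all(dim(cep8_crop) == dim(nucleus_mask)))
    stop("cep8 crop and nucleus mask differ in shape")
  fg <- if (identical(params$cep8_spot_threshold, "otsu")) {
    binarize(cep8_crop, "otsu")
  } else (cep8_crop >= params$cep8_spot_threshold) * 1
  if (!any(fg > 0)) return(0L)
  dm <- nucleus_mask
  if (params$mask_dilate_px > 0 && any(dm > 0)) {
    brush <- EBImage::makeBrush(2L * params$mask_dilate_px + 1L, shape = "disc")
    dm <- EBImage::imageData(EBImage::dilate(EBImage::Image(dm), brush))
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg)))
  n <- 0L
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    a <- sum(comp)
    if (a < params$min_spot_area || a > params$max_spot_area) next
    if (sum(comp & dm > 0) / a >= params$border_overlap_min) n <- n + 1L
  }
  n
}

#' Mean-intensity positivity test
#'
#' A channel is called positive when the mean intensity over the nucleus
#' mask (or the whole crop when no mask is given) reaches the threshold.
#'
#' @param crop 2-D matrix (0..255).
#' @param threshold Intensity threshold.
#' @param mask Optional binary matrix; an empty mask falls back to the whole
#'   crop.
#' @return Logical.
#' @export
assess_positivity <- function(crop, threshold, mask = NULL) {
  stopifnot(length(crop) > 0)
  v <- if (is.null(mask) || !any(mask > 0)) crop else crop[mask > 0]
  mean(v) >= threshold
}

# convex hull area of a pixel set, Pick-style corrected so a convex digital
# region has solidity close to 1
hull_area_px <- function(rows, cols) {
  pts <- unique(cbind(rows, cols))
  if (nrow(pts) < 3) return(nrow(pts))
  h <- grDevices::chull(pts[, 2], pts[, 1])
  x <- pts[h, 2]; y <- pts[h, 1]
  n <- length(h)
  j <- c(n, seq_len(n - 1))
  interior <- abs(sum(x * y[j] - x[j] * y)) / 2
  perim <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  interior + perim / 2 + 1
}

#' Flag aggregated or superposed nuclei
#'
#' The largest mask component is an aggregate when its solidity (pixel area
#' over convex-hull area) falls below \code{aggregate_solidity_min} — fused
#' nuclei form concave dumbbells — or when its area exceeds
#' \code{aggregate_area_max}.
#'
#' @param nucleus_mask Binary matrix.
#' @param params A \code{\link{call_params}} object.
#' @return Logical; \code{FALSE} for an empty mask.
#' @export
detect_aggregate <- function(nucleus_mask, params = call_params()) {
  stopifnot(is.matrix(nucleus_mask))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((nucleus_mask > 0) * 1)))
  if (max(lab) == 0) return(FALSE)
  areas <- tabulate(lab[lab > 0])
  k <- which.max(areas)
  if (areas[k] > params$aggregate_area_max) return(TRUE)
  idx <- which(lab == k)
  h <- nrow(nucleus_mask)
  rows <- ((idx - 1) %% h) + 1
  cols <- ((idx - 1) %/% h) + 1
  solidity <- min(areas[k] / hull_area_px(rows, cols), 1)
  solidity < params$aggregate_solidity_min
}

#' Apply the CTC interpretation criteria to one cell crop
#'
#' Composes the four criteria: (1) aggregated/superposed nuclei are
#' excluded, (2) DAPI positivity, (3) CD45 negativity, (4) at least three
#' CEP8 signal points. Exclusion takes precedence: excluded cells are
#' labeled \code{"excluded"} regardless of the other checks.
#'
#' @param crop A \code{cell_crop} (list with \code{dapi}, \code{cep8},
#'   \code{cd45} matrices and optionally \code{cell_ref}).
#' @param params A \code{\link{call_params}} object.
#' @return One-row data frame: \code{cell_ref}, \code{dapi_positive},
#'   \code{cd45_positive}, \code{cep8_count}, \code{excluded}, \code{label}.
#' @export
call_cell <- function(crop, params = call_params()) {
  mask <- nucleus_mask_from_dapi(crop$dapi)
  dapi_pos <- assess_positivity(crop$dapi, params$dapi_mean_threshold, mask)
  cd45_pos <- assess_positivity(crop$cd45, params$cd45_mean_threshold, mask)
  count <- count_cep8_spots(crop$cep8, mask, params)
  excluded <- detect_aggregate(mask, params)
  label <- if (excluded) "excluded"
           else if (dapi_pos && !cd45_pos && count >= 3) "CTC"
           else "non-CTC"
  data.frame(cell_ref = if (!is.null(crop$cell_ref)) crop$cell_ref else NA_character_,
             dapi_positive = dapi_pos, cd45_positive = cd45_pos,
             cep8_count = as.integer(count), excluded = excluded,
             label = label, stringsAsFactors = FALSE)
}

#' Call a list of cell crops
#'
#' @param crops List of \code{cell_crop} objects.
#' @param params A \code{\link{call_params}} object.
#' @return Data frame with one \code{\link{call_cell}} row per crop.
#' @export
call_cells <- function(crops, params = call_params()) {
  if (length(crops) == 0)
    return(data.frame(cell_ref = character(0), dapi_positive = logical(0),
                      cd45_positive = logical(0), cep8_count = integer(0),
                      excluded = logical(0), label = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(crops, call_cell, params = params))
  rownames(out) <- NULL
  out
}
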
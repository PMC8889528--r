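#' Write a multi-channel image as an RGB PNG
#'
#' Channel mapping follows the display convention of imFISH micrographs:
#' R = CD45 (red immunofluorescence), G = CEP8 (orange probe, carried in the
#' green plane), B = DAPI (blue counterstain). The mapping is recorded in
#' the dataset's YAML sidecar by \code{\link{generate_dataset}}.
#'
#' @param image A \code{multichannel_image}.
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "multichannel_image"))
  h <- nrow(image$dapi); w <- ncol(image$dapi)
  arr <- array(0, dim = c(h, w, 3))
  arr[, , 1] <- image$cd45 / 255
  arr[, , 2] <- image$cep8 / 255
  arr[, , 3] <- image$dapi / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' Read a multi-channel image from an RGB PNG
#'
#' Inverse of \code{\link{write_image}}; 8-bit intensities round-trip
#' losslessly.
#'
#' @param path PNG path.
#' @param image_id Identifier; defaults to the file name without extension.
#' @return A \code{multichannel_image} with integer 0..255 channel matrices.
#' @export
read_image <- function(path, image_id = NULL) {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  arr <- tryCatch(png::readPNG(path),
                  error = function(e) stop("ill-formed PNG '", path, "': ",
                                           conditionMessage(e)))
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  to8 <- function(m) matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  structure(list(dapi = to8(arr[, , 3]), cep8 = to8(arr[, , 2]),
                 cd45 = to8(arr[, , 1]),
                 image_id = image_id %||% sub("\\.[^.]*$", "", basename(path))),
            class = "multichannel_image")
}

#' Write / read an evaluation report as JSON
#'
#' @param report An \code{eval_report} (or any list of numeric fields).
#' @param path JSON path.
#' @return \code{read_report} returns the restored list.
#' @export
write_report <- function(report, path) {
  obj <- unclass(report)
  if (!is.null(obj$roc_points)) obj$roc_points <- as.data.frame(obj$roc_points)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$roc_points)) obj$roc_points <- as.data.frame(obj$roc_points)
  obj
}

#' Write crops and a crop manifest to a directory
#'
#' Each crop is written as one PNG per channel named
#' \code{{image_id}_{index}_{channel}.png}; the manifest CSV records the box
#' coordinates (0-based, half-open).
#'
#' @param crops List of \code{cell_crop} objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_crops <- function(crops, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(crops), function(i) {
    cr <- crops[[i]]
    b <- cr$box
    for (ch in c("dapi", "cep8", "cd45")) {
      png::writePNG(cr[[ch]] / 255,
                    file.path(dir, sprintf("%s_%s.png", cr$cell_ref, ch)))
    }
    data.frame(cell_ref = cr$cell_ref, image_id = b$source_image_id,
               row_start = b$row_start, col_start = b$col_start,
               row_stop = b$row_stop, col_stop = b$col_stop,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "crops.csv"), row.names = FALSE)
  invisible(manifest)
}

simple_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
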
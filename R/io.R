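#' Write a speckle sequence as a multi-page 8-bit grayscale TIFF
#'
#' A sidecar JSON file (same path with extension `.json`) records the
#' simulation parameters and seed when the sequence carries them.
#'
#' @param seq A `speckle_sequence` with integer frames in
#'   `[0, bit_depth - 1]`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_speckle_tiff <- function(seq, path) {
  stopifnot(inherits(seq, "speckle_sequence"))
  g <- seq$bit_depth
  if (g > 256L) stop("only 8-bit (or fewer gray levels) stacks are written",
                     call. = FALSE)
  pages <- lapply(seq_len(dim(seq$frames)[3]), function(t)
    seq$frames[, , t] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  if (!is.null(seq$params)) {
    meta <- unclass(seq$params)
    jsonlite::write_json(meta, sub("\\.tiff?$", ".json", path,
                                   ignore.case = TRUE),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a speckle stack from a multi-page TIFF or a frame directory
#'
#' Frame directories are read in lexicographic filename order (zero-padded
#' names required for correct chronology); PNG and TIFF frames are
#' accepted. Only 8-bit grayscale inputs are supported.
#'
#' @param path A multi-page TIFF file or a directory of single-frame
#'   PNG/TIFF files.
#' @param frame_rate Acquisition rate in Hz; default 12.5.
#' @return A `speckle_sequence` with integer frames in `[0, 255]`.
#' @export
read_speckle_stack <- function(path, frame_rate = 12.5) {
  read_one <- function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
    else tiff::readTIFF(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L) stop("frame directory must contain >= 2 frames: ",
                                 path, call. = FALSE)
    pages <- lapply(files, read_one)
  } else {
    if (!file.exists(path)) stop("no such stack: ", path, call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1]
                    else p)
  }
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1))))
    stop("frames have inconsistent dimensions", call. = FALSE)
  frames <- array(0L, dim = c(d1[1], d1[2], length(pages)))
  for (t in seq_along(pages))
    frames[, , t] <- as.integer(round(pages[[t]] * 255))
  structure(list(frames = frames, frame_rate = frame_rate,
                 bit_depth = 256L, params = NULL),
            class = "speckle_sequence")
}

#' Write an RGB patch as an 8-bit PNG
#'
#' @param patch An `rgb_patch` with integer pixels in `[0, 255]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_patch_png <- function(patch, path) {
  stopifnot(inherits(patch, "rgb_patch"))
  png::writePNG(patch$pixels / 255, path)
  invisible(path)
}

#' Read an RGB patch (or a ROI of an image) from PNG/TIFF/JPEG
#'
#' @param path Image path (PNG or TIFF).
#' @param roi Optional `c(row, col, size)` (1-based top-left corner) to crop
#'   a square ROI.
#' @param label Class tag: `"SS"`, `"IS"` or `"unknown"`.
#' @return An `rgb_patch` with integer pixels in `[0, 255]`.
#' @export
read_patch <- function(path, roi = NULL, label = "unknown") {
  if (!file.exists(path)) stop("no such image: ", path, call. = FALSE)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
  else tiff::readTIFF(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3),
                                           dim = c(dim(img), 3))
  img <- img[, , 1:3, drop = FALSE]
  origin <- c(1L, 1L)
  if (!is.null(roi)) {
    r <- roi[1]; c0 <- roi[2]; s <- roi[3]
    if (r < 1 || c0 < 1 || r + s - 1 > dim(img)[1] || c0 + s - 1 > dim(img)[2])
      stop("ROI exceeds the image bounds", call. = FALSE)
    img <- img[r:(r + s - 1), c0:(c0 + s - 1), , drop = FALSE]
    origin <- c(as.integer(r), as.integer(c0))
  }
  .new_rgb_patch(array(as.integer(round(img * 255)), dim = dim(img)),
                 label = label, roi_origin = origin)
}
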
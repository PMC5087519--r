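#' Extract the time history of the speckle pattern (THSP)
#'
#' The THSP tracks one spatial column of the frame through time: column
#' `column_index` of frame t becomes column t of the THSP, so rows are
#' pixels and columns are time. Its width equals the number of frames used.
#'
#' @param seq A `speckle_sequence` (see [simulate_speckle_sequence()]) or an
#'   H x W x T integer array.
#' @param column_index 0-based column to track. The default, `"mid"`, uses
#'   `floor((width - 1) / 2)`; for 512-wide frames this is index 255, i.e.
#'   the 256th column in 1-based counting.
#' @param n_frames Optional prefix length: use only the first `n_frames`
#'   frames of the stack.
#' @return A `thsp` object: H x T integer matrix with attributes
#'   `column_index` and `frame_rate`.
#' @export
extract_thsp <- function(seq, column_index = "mid", n_frames = NULL) {
  frames <- if (inherits(seq, "speckle_sequence")) seq$frames else seq
  if (length(dim(frames)) != 3L)
    stop("'seq' must be an H x W x T array of frames", call. = FALSE)
  d <- dim(frames)
  if (!is.null(n_frames)) {
    if (n_frames > d[3]) stop("'n_frames' exceeds the stack length",
                              call. = FALSE)
    frames <- frames[, , seq_len(n_frames), drop = FALSE]
    d <- dim(frames)
  }
  if (d[3] < 2L) stop("at least 2 frames are required", call. = FALSE)
  if (identical(column_index, "mid")) column_index <- floor((d[2] - 1) / 2)
  if (column_index < 0 || column_index >= d[2])
    stop(sprintf("column_index %d out of range [0, %d]",
                 column_index, d[2] - 1L), call. = FALSE)
  thsp <- frames[, column_index + 1L, , drop = TRUE]
  dim(thsp) <- c(d[1], d[3])
  structure(thsp, class = c("thsp", class(thsp)),
            column_index = as.integer(column_index),
            frame_rate = if (inherits(seq, "speckle_sequence"))
              seq$frame_rate else NA_real_)
}

#' Build the intensity co-occurrence matrix of a THSP
#'
#' Counts, over all rows of the THSP, how often intensity i at time t is
#' followed immediately by intensity j at time t + 1:
#' \deqn{COM = [N_{ij}]}
#' Row-normalizing by the number of times gray level i occurred as the
#' first member of a pair gives
#' \deqn{M_{ij} = N_{ij} / \sum_j N_{ij},}
#' with rows of unvisited gray levels left at zero. The total count equals
#' H (T - 1).
#'
#' @param thsp An H x T integer matrix (a [extract_thsp()] result).
#' @param gray_levels Number of gray levels G; entries must lie in
#'   `[0, G - 1]`. Default 256.
#' @return A `com_matrix`: list with `counts` (G x G integer) and
#'   `normalized` (G x G double).
#' @export
build_com <- function(thsp, gray_levels = 256L) {
  g <- as.integer(gray_levels)
  tt <- ncol(thsp)
  if (tt < 2L) stop("THSP must have at least 2 columns", call. = FALSE)
  if (min(thsp) < 0 || max(thsp) > g - 1L)
    stop(sprintf("'gray_levels' = %d is smaller than observed range [%d, %d] + 1",
                 g, min(thsp), max(thsp)), call. = FALSE)
  from <- as.vector(thsp[, -tt, drop = FALSE])
  to <- as.vector(thsp[, -1L, drop = FALSE])
  counts <- matrix(tabulate(from * g + to + 1L, nbins = g * g),
                   nrow = g, ncol = g, byrow = TRUE)
  row_tot <- rowSums(counts)
  normalized <- counts / ifelse(row_tot > 0, row_tot, 1)
  structure(list(counts = counts, normalized = normalized, gray_levels = g),
            class = "com_matrix")
}

#' Inertia moment of a co-occurrence matrix
#'
#' The inertia moment is the second-order moment of the row-normalized
#' co-occurrence matrix about its principal diagonal,
#' \deqn{IM = \sum_{ij} M_{ij} (i - j)^2,}
#' and the biospeckle activity is defined as BA = IM. Diagonal entries
#' (unchanged intensity) contribute nothing; the more the intensity moves
#' between consecutive frames, the larger IM.
#'
#' @param com A `com_matrix` from [build_com()], or a row-normalized G x G
#'   matrix.
#' @return A `ba_result`: list with `ba`, `n_frames_used` (NA when unknown),
#'   `window_seconds` (NA), `column_index` (NA).
#' @export
inertia_moment <- function(com) {
  m <- if (inherits(com, "com_matrix")) com$normalized else com
  g <- nrow(m)
  idx <- seq_len(g) - 1L
  w <- outer(idx, idx, function(i, j) (i - j)^2)
  ba <- sum(m * w)
  structure(list(ba = ba, window_seconds = NA_real_,
                 n_frames_used = NA_integer_, column_index = NA_integer_),
            class = "ba_result")
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf("BA = %.4f (frames used: %s, window: %s s, column: %s)\n",
              x$ba, x$n_frames_used, x$window_seconds, x$column_index))
  invisible(x)
}

#' Biospeckle activity of a speckle sequence
#'
#' Convenience wrapper: THSP extraction, co-occurrence matrix and inertia
#' moment in one call.
#'
#' @inheritParams extract_thsp
#' @param gray_levels Number of gray levels; default 256.
#' @return A `ba_result`.
#' @export
biospeckle_activity <- function(seq, column_index = "mid", n_frames = NULL,
                                gray_levels = 256L) {
  thsp <- extract_thsp(seq, column_index, n_frames)
  res <- inertia_moment(build_com(thsp, gray_levels))
  res$n_frames_used <- ncol(thsp)
  res$column_index <- attr(thsp, "column_index")
  fr <- attr(thsp, "frame_rate")
  if (!is.na(fr)) res$window_seconds <- ncol(thsp) / fr
  res
}

#' Biospeckle activity over prefix time windows
#'
#' For each requested window length w (seconds), uses the prefix of
#' `floor(w * frame_rate)` frames of the recording and computes BA. This is
#' the time-span reduction analysis: a 10 s window of a 12.5 Hz recording
#' uses 125 of the 512 frames. The special window `"all"` uses every frame,
#' which reproduces the full 512-frame behaviour on a nominal 40 s
#' recording whose frame count exceeds `40 * frame_rate`.
#'
#' @param seq A `speckle_sequence`, or an array plus explicit `frame_rate`.
#' @param windows_seconds Numeric vector of window lengths in seconds, or
#'   the string `"all"` for the full stack; entries of the numeric vector
#'   may also be the string `"all"` in a list. Default `c(10, 20, 30, 40)`.
#' @param column_index Passed to [extract_thsp()].
#' @param gray_levels Passed to [build_com()].
#' @param frame_rate Required when `seq` is a bare array.
#' @return A data.frame with columns `window_s`, `n_frames`, `column`, `ba`.
#' @export
ba_over_windows <- function(seq, windows_seconds = c(10, 20, 30, 40),
                            column_index = "mid", gray_levels = 256L,
                            frame_rate = NULL) {
  if (inherits(seq, "speckle_sequence")) {
    frame_rate <- seq$frame_rate
    n_total <- dim(seq$frames)[3]
  } else {
    if (is.null(frame_rate)) stop("'frame_rate' required for array input",
                                  call. = FALSE)
    n_total <- dim(seq)[3]
  }
  rows <- lapply(as.list(windows_seconds), function(w) {
    if (identical(w, "all")) {
      n_use <- n_total
      w_s <- n_total / frame_rate
    } else {
      w <- as.numeric(w)
      n_use <- floor(w * frame_rate)
      if (n_use > n_total)
        stop(sprintf("window of %g s needs %d frames but the stack has %d",
                     w, n_use, n_total), call. = FALSE)
      if (n_use < 2L) stop("window too short: fewer than 2 frames",
                           call. = FALSE)
      w_s <- w
    }
    res <- biospeckle_activity(seq, column_index, n_frames = n_use,
                               gray_levels = gray_levels)
    data.frame(window_s = w_s, n_frames = n_use,
               column = res$column_index, ba = res$ba)
  })
  do.call(rbind, rows)
}

#' Correlation of windowed BA against a reference window
#'
#' Given a samples x windows table of BA values (one row per specimen, one
#' column per time span), computes the Pearson correlation of each window's
#' BA vector with the reference window's across samples. This mirrors the
#' consistency analysis that justifies replacing the full recording with a
#' 10 s prefix.
#'
#' @param ba_table Numeric matrix or data.frame, samples in rows, windows in
#'   columns (named).
#' @param reference_window Column name or index of the reference window.
#' @return Named numeric vector of correlations, one per window; the
#'   reference's self-correlation is exactly 1.
#' @export
window_correlation <- function(ba_table, reference_window = 1L) {
  m <- as.matrix(ba_table)
  if (nrow(m) < 3L) stop("at least 3 samples are required", call. = FALSE)
  ref <- m[, reference_window]
  if (stats::sd(ref) == 0)
    stop("reference window has zero variance; correlation undefined",
         call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("a window column has zero variance; correlation undefined",
         call. = FALSE)
  r <- drop(stats::cor(m, ref))
  names(r) <- colnames(m)
  ref_idx <- if (is.character(reference_window))
    match(reference_window, colnames(m)) else reference_window
  r[ref_idx] <- 1
  r
}
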
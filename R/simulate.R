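#' Simulation parameters for a dynamic speckle stack
#'
#' Bundles and validates the parameters of the synthetic dynamic-speckle
#' generator. The generator emulates fully developed speckle from a living
#' surface: a spatially smoothed complex circular-Gaussian field is evolved
#' in time as an order-1 autoregressive process and its squared modulus is
#' recorded, so that `rho` controls frame-to-frame temporal decorrelation
#' (the "activity" seen by the inertia-moment statistic).
#'
#' @param height,width Frame dimensions in pixels (>= 8). Defaults match a
#'   512 x 512 region of interest cropped from the speckle camera.
#' @param n_frames Number of frames in the stack (>= 2); default 512.
#' @param frame_rate Acquisition rate in Hz; default 12.5.
#' @param rho Temporal correlation coefficient in [0, 1] of the underlying
#'   complex field between consecutive frames. `rho = 1` gives a static
#'   stack; `rho = 0` gives independent frames. Lower `rho` means higher
#'   biospeckle activity.
#' @param grain_sigma Spatial Gaussian smoothing scale in pixels controlling
#'   the speckle grain size; default 1.
#' @param bit_depth Number of gray levels after quantization; default 256.
#' @param seed Integer RNG seed.
#' @return An object of class `speckle_sim_params`.
#' @export
speckle_sim_params <- function(height = 512L, width = 512L, n_frames = 512L,
                               frame_rate = 12.5, rho = 0.9,
                               grain_sigma = 1, bit_depth = 256L,
                               seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  n_frames <- as.integer(n_frames)
  if (is.na(height) || is.na(width) || height < 8L || width < 8L)
    stop("frame dimensions must be at least 8 x 8 pixels", call. = FALSE)
  if (is.na(n_frames) || n_frames < 2L)
    stop("'n_frames' must be at least 2", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
      rho < 0 || rho > 1)
    stop("'rho' must be a single value in [0, 1]", call. = FALSE)
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("'frame_rate' must be positive", call. = FALSE)
  if (!is.numeric(grain_sigma) || grain_sigma < 0)
    stop("'grain_sigma' must be non-negative", call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  if (is.na(bit_depth) || bit_depth < 2L)
    stop("'bit_depth' must be at least 2 gray levels", call. = FALSE)
  structure(list(height = height, width = width, n_frames = n_frames,
                 frame_rate = frame_rate, rho = rho,
                 grain_sigma = grain_sigma, bit_depth = bit_depth,
                 seed = as.integer(seed)),
            class = "speckle_sim_params")
}

# Gaussian low-pass transfer function for an H x W grid, applied in the
# Fourier domain; returns a real H x W matrix of filter gains.
.gaussian_transfer <- function(h, w, sigma) {
  if (sigma <= 0) return(matrix(1, h, w))
  fy <- c(0:(floor(h / 2)), -((ceiling(h / 2) - 1):1)) / h
  fx <- c(0:(floor(w / 2)), -((ceiling(w / 2) - 1):1)) / w
  gy <- exp(-2 * pi^2 * sigma^2 * fy^2)
  gx <- exp(-2 * pi^2 * sigma^2 * fx^2)
  outer(gy, gx)
}

# One spatially smoothed complex circular-Gaussian field with unit variance
# per pixel (in expectation); smoothing acts on the complex amplitude so the
# marginal intensity statistics stay negative-exponential.
.smoothed_field <- function(h, w, transfer, gain) {
  z <- matrix(complex(real = stats::rnorm(h * w), imaginary = stats::rnorm(h * w)),
              h, w) / sqrt(2)
  if (is.null(transfer)) return(z)
  fft(fft(z) * transfer, inverse = TRUE) / (h * w) / gain
}

#' Simulate a dynamic speckle sequence
#'
#' Generates `n_frames` frames as the squared modulus of a spatially smoothed
#' complex circular-Gaussian field evolved as an AR(1) process with
#' coefficient `rho`, then linearly rescales the whole stack to
#' `[0, bit_depth - 1]` and quantizes. Rescaling is per-stack, not per-frame,
#' so quantization injects no artificial frame-to-frame transitions.
#'
#' @param params A [speckle_sim_params()] object.
#' @param quantize If `FALSE`, return the raw (unscaled, double) intensity
#'   stack instead of the quantized 8-bit one; used for checking first-order
#'   speckle statistics.
#' @return A `speckle_sequence`: list with `frames` (H x W x T integer array,
#'   or double if `quantize = FALSE`), `frame_rate`, `bit_depth` and the
#'   generating parameters.
#' @examples
#' seq <- simulate_speckle_sequence(
#'   speckle_sim_params(height = 32, width = 32, n_frames = 16, rho = 0.8))
#' dim(seq$frames)
#' @export
simulate_speckle_sequence <- function(params, quantize = TRUE) {
  stopifnot(inherits(params, "speckle_sim_params"))
  h <- params$height; w <- params$width; tt <- params$n_frames
  rho <- params$rho
  set.seed(params$seed)
  transfer <- if (params$grain_sigma > 0)
    .gaussian_transfer(h, w, params$grain_sigma) else NULL
  # smoothing shrinks the per-pixel variance by mean(transfer^2); undo it so
  # the AR(1) recursion stays stationary with unit marginal variance
  gain <- if (is.null(transfer)) 1 else sqrt(mean(transfer^2))
  field <- .smoothed_field(h, w, transfer, gain)
  frames <- array(0, dim = c(h, w, tt))
  frames[, , 1] <- Mod(field)^2
  innov_scale <- sqrt(1 - rho^2)
  for (t in 2:tt) {
    if (innov_scale > 0) {
      field <- rho * field +
        innov_scale * .smoothed_field(h, w, transfer, gain)
    }
    frames[, , t] <- Mod(field)^2
  }
  out <- list(frames = frames, frame_rate = params$frame_rate,
              bit_depth = params$bit_depth, params = params)
  class(out) <- "speckle_sequence"
  if (!quantize) return(out)
  rng <- range(frames)
  g <- params$bit_depth
  scaled <- if (rng[2] > rng[1])
    (frames - rng[1]) / (rng[2] - rng[1]) * (g - 1) else frames * 0
  out$frames <- array(as.integer(round(scaled)), dim = dim(frames))
  out
}

#' @export
print.speckle_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("speckle_sequence: %d x %d pixels, %d frames @ %.3g Hz\n",
              d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}

#' Simulation parameters for a sound/injured RGB skin patch pair
#'
#' Parameters for generating matched sound-skin (SS) and injured-skin (IS)
#' patches whose grey-level contrast `Con = mean_gray(SS) - mean_gray(IS)`
#' is controlled. Injured patches may carry dark circular "lenticel" spots,
#' a minimal emulation of the dark spots scattered over injured areas.
#'
#' @param size Patch side length in pixels; default 65 (the ROI size used
#'   for visible imaging).
#' @param mean_rgb_ss Length-3 per-channel means of the sound patch on the
#'   0-255 scale; default `c(150, 115, 85)`, a matte skin tone.
#' @param con Target signed gray contrast (SS minus IS); `|con| <= 128`.
#'   Positive values darken the injured patch, negative brighten it (fresh
#'   injuries reflect more light).
#' @param channel_sd Per-channel pixel noise SD (length 1 or 3); default 8.
#' @param n_lenticels Number of dark disks rendered on the IS patch.
#' @param lenticel_radius Disk radius in pixels.
#' @param seed Integer RNG seed.
#' @return An object of class `patch_sim_params`.
#' @export
patch_sim_params <- function(size = 65L, mean_rgb_ss = c(150, 115, 85),
                             con = 30.943, channel_sd = 8,
                             n_lenticels = 5L, lenticel_radius = 2,
                             seed = 1L) {
  size <- as.integer(size)
  if (is.na(size) || size < 16L)
    stop("'size' must be at least 16 pixels", call. = FALSE)
  if (length(mean_rgb_ss) != 3L || any(mean_rgb_ss < 0 | mean_rgb_ss > 255))
    stop("'mean_rgb_ss' must be 3 values in [0, 255]", call. = FALSE)
  if (!is.numeric(con) || length(con) != 1L || abs(con) > 128)
    stop("'con' must be a single value with |con| <= 128", call. = FALSE)
  if (any(channel_sd < 0)) stop("'channel_sd' must be non-negative",
                                call. = FALSE)
  if (any(mean_rgb_ss - con < -1 | mean_rgb_ss - con > 256))
    stop("requested contrast pushes injured-patch channels outside [0, 255]",
         call. = FALSE)
  structure(list(size = size, mean_rgb_ss = as.numeric(mean_rgb_ss),
                 con = con, channel_sd = rep_len(channel_sd, 3L),
                 n_lenticels = as.integer(n_lenticels),
                 lenticel_radius = lenticel_radius,
                 seed = as.integer(seed)),
            class = "patch_sim_params")
}

.new_rgb_patch <- function(px, label = "unknown", roi_origin = c(1L, 1L)) {
  structure(list(pixels = px, label = label, roi_origin = roi_origin),
            class = "rgb_patch")
}

#' @export
print.rgb_patch <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("rgb_patch (%s): %d x %d pixels\n", x$label, d[1], d[2]))
  invisible(x)
}

#' Simulate a matched sound/injured skin patch pair
#'
#' Draws two noisy RGB patches. The injured patch has its per-channel means
#' shifted (and, optionally, dark lenticel disks stamped in) and is then
#' globally adjusted so that the realized gray contrast
#' `mean_gray(SS) - mean_gray(IS)` matches the requested `con` up to
#' 8-bit rounding.
#'
#' @param params A [patch_sim_params()] object.
#' @return List with elements `ss` and `is_` (both `rgb_patch`).
#' @examples
#' pair <- simulate_skin_patch_pair(patch_sim_params(con = 30, seed = 7))
#' contrast_con(pair$ss, pair$is_)
#' @export
simulate_skin_patch_pair <- function(params) {
  stopifnot(inherits(params, "patch_sim_params"))
  n <- params$size
  set.seed(params$seed)
  draw <- function(means) {
    px <- array(0, dim = c(n, n, 3))
    for (ch in 1:3)
      px[, , ch] <- means[ch] + stats::rnorm(n * n, sd = params$channel_sd[ch])
    px
  }
  ss <- draw(params$mean_rgb_ss)
  is_means <- params$mean_rgb_ss - params$con
  isp <- draw(is_means)
  if (params$n_lenticels > 0L && params$lenticel_radius > 0) {
    cx <- stats::runif(params$n_lenticels, 1, n)
    cy <- stats::runif(params$n_lenticels, 1, n)
    idx <- expand.grid(row = seq_len(n), col = seq_len(n))
    dark <- rep(FALSE, n * n)
    for (k in seq_len(params$n_lenticels)) {
      dark <- dark | ((idx$row - cy[k])^2 + (idx$col - cx[k])^2 <=
                        params$lenticel_radius^2)
    }
    # lenticels darken all channels by a fixed factor
    for (ch in 1:3) {
      plane <- isp[, , ch]
      plane[dark] <- plane[dark] * 0.45
      isp[, , ch] <- plane
    }
  }
  # recentre IS so the realized gray contrast hits the target exactly
  realized <- .gray_mean(ss) - .gray_mean(isp)
  isp <- isp + (realized - params$con)
  if (min(isp) < -0.5 || max(isp) > 255.5 || min(ss) < -0.5 || max(ss) > 255.5)
    stop("requested contrast/noise pushes channel values outside [0, 255]; ",
         "reduce |con|, channel_sd or lenticel count", call. = FALSE)
  clamp8 <- function(px) {
    px <- round(px); px[px < 0] <- 0; px[px > 255] <- 255
    array(as.integer(px), dim = dim(px))
  }
  list(ss = .new_rgb_patch(clamp8(ss), "SS"),
       is_ = .new_rgb_patch(clamp8(isp), "IS"))
}

# ITU-R BT.601 luminance of an H x W x 3 array
.gray_convert <- function(px) {
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}
.gray_mean <- function(px) mean(.gray_convert(px))

#' Generate a reproducible labeled synthetic dataset
#'
#' Produces `n_per_class` samples per class for either imaging channel.
#' In `"speckle"` mode each sample is a speckle stack whose class is set by
#' its temporal correlation `rho` (sound skin decorrelates slowly, injured
#' skin fast); in `"rgb"` mode each sample is one patch of a simulated
#' SS/IS pair. Per-sample seeds are derived deterministically from the
#' master seed, so the collection is byte-identical across calls.
#'
#' @param n_per_class Samples per class (>= 2).
#' @param mode `"speckle"` or `"rgb"`.
#' @param params For `"speckle"`: a [speckle_sim_params()] template (its
#'   `rho` and `seed` are overridden per sample). For `"rgb"`: a
#'   [patch_sim_params()] template (its `seed` is overridden).
#' @param class_rhos Length-2 rho values for (sound, injured) classes in
#'   speckle mode; default `c(0.95, 0.5)`.
#' @param seed Master seed.
#' @return List of samples; each has `label` (`"SS"`/`"IS"`), `seed`, and
#'   either `sequence` (speckle mode) or `patch` (rgb mode).
#' @export
generate_dataset <- function(n_per_class, mode = c("speckle", "rgb"),
                             params = NULL, class_rhos = c(0.95, 0.5),
                             seed = 1L) {
  mode <- match.arg(mode)
  n_per_class <- as.integer(n_per_class)
  if (is.na(n_per_class) || n_per_class < 2L)
    stop("'n_per_class' must be at least 2", call. = FALSE)
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_per_class)
  out <- vector("list", 2L * n_per_class)
  k <- 0L
  if (mode == "speckle") {
    if (is.null(params)) params <- speckle_sim_params(height = 64, width = 64,
                                                      n_frames = 125)
    stopifnot(inherits(params, "speckle_sim_params"),
              length(class_rhos) == 2L)
    for (cls in 1:2) {
      for (i in seq_len(n_per_class)) {
        k <- k + 1L
        p <- params
        p$rho <- class_rhos[cls]
        p$seed <- sample_seeds[k]
        out[[k]] <- list(label = c("SS", "IS")[cls], seed = p$seed,
                         sequence = simulate_speckle_sequence(p))
      }
    }
  } else {
    if (is.null(params)) params <- patch_sim_params()
    stopifnot(inherits(params, "patch_sim_params"))
    for (i in seq_len(n_per_class)) {
      p <- params
      p$seed <- sample_seeds[i]
      pair <- simulate_skin_patch_pair(p)
      out[[2L * i - 1L]] <- list(label = "SS", seed = p$seed, patch = pair$ss)
      out[[2L * i]] <- list(label = "IS", seed = p$seed, patch = pair$is_)
    }
  }
  out
}
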
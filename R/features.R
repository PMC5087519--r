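#' Color features of an RGB patch
#'
#' Mean and population standard deviation of each RGB channel over all
#' patch pixels, in the fixed order mean_R, mean_G, mean_B, sd_R, sd_G,
#' sd_B (6 features).
#'
#' @param patch An `rgb_patch` or an H x W x 3 array on the 0-255 scale.
#' @return Named numeric vector of length 6 with attribute
#'   `family = "color"`.
#' @export
color_features <- function(patch) {
  px <- .patch_pixels(patch)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  out <- c(mean_R = mean(px[, , 1]), mean_G = mean(px[, , 2]),
           mean_B = mean(px[, , 3]),
           sd_R = pop_sd(px[, , 1]), sd_G = pop_sd(px[, , 2]),
           sd_B = pop_sd(px[, , 3]))
  attr(out, "family") <- "color"
  out
}

.patch_pixels <- function(patch) {
  px <- if (inherits(patch, "rgb_patch")) patch$pixels else patch
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("patch must be an H x W x 3 RGB array", call. = FALSE)
  px
}

# quantize a gray image (0-255 scale) to `levels` bins, 0-based
.quantize_gray <- function(gray, levels) {
  q <- floor(gray / 256 * levels)
  q[q > levels - 1] <- levels - 1
  q[q < 0] <- 0
  matrix(as.integer(q), nrow(gray), ncol(gray))
}

# symmetric normalized gray-level co-occurrence matrix at distance 1 for one
# direction given as a (drow, dcol) offset
.glcm_one <- function(q, levels, drow, dcol) {
  h <- nrow(q); w <- ncol(q)
  r1 <- max(1, 1 - drow):min(h, h - drow)
  c1 <- max(1, 1 - dcol):min(w, w - dcol)
  a <- as.vector(q[r1, c1, drop = FALSE])
  b <- as.vector(q[r1 + drow, c1 + dcol, drop = FALSE])
  counts <- matrix(tabulate(a * levels + b + 1L, nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  counts <- counts + t(counts)  # symmetric: count each pair both ways
  counts / sum(counts)
}

# Haralick statistics of one normalized GLCM: ASM, entropy, inertia
# (contrast) and correlation; COR of a zero-variance image is defined as 0
.glcm_stats <- function(p) {
  g <- nrow(p)
  i <- matrix(rep(0:(g - 1), g), g, g)
  j <- t(i)
  asm <- sum(p^2)
  nz <- p > 0
  ent <- -sum(p[nz] * log(p[nz]))
  ine <- sum(p * (i - j)^2)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p)); sd_j <- sqrt(sum((j - mu_j)^2 * p))
  cor <- if (sd_i > 0 && sd_j > 0)
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j) else 0
  c(ASM = asm, ENT = ent, INE = ine, COR = cor)
}

#' GLCM texture features of an RGB patch
#'
#' Converts the patch to gray (BT.601 luminance), quantizes to `levels`
#' gray levels and builds symmetric normalized co-occurrence matrices at
#' distance 1 in the four directions 0, 45, 90 and 135 degrees. For each of
#' the four Haralick statistics - angular second moment (ASM), entropy
#' (ENT), inertia (INE) and correlation (COR) - the mean and the population
#' SD across the four directions are reported, giving 8 features in the
#' fixed order mean_ASM, mean_ENT, mean_INE, mean_COR, sd_ASM, sd_ENT,
#' sd_INE, sd_COR.
#'
#' @param patch An `rgb_patch` or H x W x 3 array (0-255).
#' @param levels Gray-level quantization; default 32.
#' @return Named numeric vector of length 8, attribute `family = "glcm"`.
#' @export
glcm_features <- function(patch, levels = 32L) {
  px <- .patch_pixels(patch)
  q <- .quantize_gray(.gray_convert(px), levels)
  # offsets for 0, 45, 90, 135 degrees in (drow, dcol) image convention
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  stats4 <- vapply(offsets, function(o)
    .glcm_stats(.glcm_one(q, as.integer(levels), o[1], o[2])),
    numeric(4))
  mu <- rowMeans(stats4)
  sdv <- sqrt(rowMeans((stats4 - mu)^2))
  out <- c(mean_ASM = mu[["ASM"]], mean_ENT = mu[["ENT"]],
           mean_INE = mu[["INE"]], mean_COR = mu[["COR"]],
           sd_ASM = sdv[["ASM"]], sd_ENT = sdv[["ENT"]],
           sd_INE = sdv[["INE"]], sd_COR = sdv[["COR"]])
  attr(out, "family") <- "glcm"
  out
}

# complex Gabor kernel; wavelength in px, theta in radians, 1-octave
# bandwidth (sigma = 0.56 lambda), aspect ratio 0.5
.gabor_kernel <- function(wavelength, theta, max_size) {
  sigma <- wavelength * (1 / pi) * sqrt(log(2) / 2) * 3  # (2^b+1)/(2^b-1)=3
  half <- min(ceiling(3 * sigma), floor((max_size - 1) / 2))
  u <- -half:half
  x <- outer(rep(1, length(u)), u)   # column coordinate
  y <- outer(u, rep(1, length(u)))   # row coordinate
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  env <- exp(-(xr^2 + (0.5 * yr)^2) / (2 * sigma^2))
  list(re = env * cos(2 * pi * xr / wavelength),
       im = env * sin(2 * pi * xr / wavelength))
}

#' Gabor texture features of an RGB patch
#'
#' A bank of 12 complex Gabor filters (3 wavelengths x 4 orientations
#' 0/45/90/135 degrees) is applied to the gray-converted patch. The patch
#' is partitioned into a 3 x 3 grid of blocks (as equal as integer division
#' allows) and the mean response magnitude over each block is one feature:
#' 12 filters x 9 blocks = 108 features, ordered by (scale, orientation,
#' block row, block column).
#'
#' @param patch An `rgb_patch` or H x W x 3 array (0-255); side >= 9.
#' @param wavelengths Filter wavelengths in pixels; default `c(4, 8, 16)`.
#' @param orientations Orientations in degrees; default `c(0, 45, 90, 135)`.
#' @return Named numeric vector of length 108, attribute `family = "gabor"`.
#' @export
gabor_features <- function(patch, wavelengths = c(4, 8, 16),
                           orientations = c(0, 45, 90, 135)) {
  px <- .patch_pixels(patch)
  gray <- .gray_convert(px)
  h <- nrow(gray); w <- ncol(gray)
  if (h < 9L || w < 9L)
    stop("patch must be at least 9 x 9 for the 3 x 3 block grid",
         call. = FALSE)
  rb <- .block_bounds(h, 3L); cb <- .block_bounds(w, 3L)
  feats <- numeric(0)
  for (lam in wavelengths) {
    for (ang in orientations) {
      k <- .gabor_kernel(lam, ang * pi / 180, min(h, w))
      re <- EBImage::filter2(gray, k$re, boundary = "replicate")
      im <- EBImage::filter2(gray, k$im, boundary = "replicate")
      mag <- sqrt(re^2 + im^2)
      for (br in 1:3) for (bc in 1:3) {
        v <- mean(mag[rb[[br]], cb[[bc]]])
        names(v) <- sprintf("gabor_w%g_o%g_b%d%d", lam, ang, br, bc)
        feats <- c(feats, v)
      }
    }
  }
  attr(feats, "family") <- "gabor"
  feats
}

.block_bounds <- function(n, k) {
  cuts <- floor(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) (cuts[i] + 1):cuts[i + 1])
}

# --- level-1 dual-tree complex wavelet transform -------------------------
# Odd-length biorthogonal analysis pair (LeGall 5/3): lowpass sums to 1,
# highpass sums to 0 so oriented subbands vanish on constant images.
.dtcwt_h0 <- c(-1, 2, 6, 2, -1) / 8
.dtcwt_h1 <- c(-1, 2, -1) / 2

# filter the columns of x with symmetric (whole-point) boundary extension
.colfilter <- function(x, h) {
  half <- (length(h) - 1) / 2
  n <- nrow(x)
  ext <- c(rev(seq_len(half) + 1L), seq_len(n), n - seq_len(half))
  xe <- x[ext, , drop = FALSE]
  out <- matrix(0, n, ncol(x))
  for (k in seq_along(h))
    out <- out + h[k] * xe[(k - 1) + seq_len(n), , drop = FALSE]
  out
}
.rowfilter <- function(x, h) t(.colfilter(t(x), h))

# quad-to-complex: interpret 2x2 quads of a real highpass image as two
# complex subband coefficients (the two trees of the dual tree)
.q2c <- function(y) {
  a <- y[seq(1, nrow(y), 2), seq(1, ncol(y), 2)]
  b <- y[seq(1, nrow(y), 2), seq(2, ncol(y), 2)]
  c_ <- y[seq(2, nrow(y), 2), seq(1, ncol(y), 2)]
  d <- y[seq(2, nrow(y), 2), seq(2, ncol(y), 2)]
  s <- sqrt(0.5)
  p <- (a + 1i * b) * s
  q <- (d - 1i * c_) * s
  list(z1 = p - q, z2 = p + q)
}

#' Level-1 dual-tree complex wavelet subbands of a gray image
#'
#' Computes the six complex oriented subbands (approximately +15, +45, +75,
#' -75, -45 and -15 degrees) of a one-level dual-tree complex wavelet
#' decomposition. The image is padded to even dimensions by symmetric
#' extension when needed.
#'
#' @param gray Numeric matrix (gray image).
#' @return Named list of six complex matrices, names `p15`, `p45`, `p75`,
#'   `m75`, `m45`, `m15`.
#' @export
dtcwt_level1 <- function(gray) {
  if (nrow(gray) %% 2 == 1) gray <- rbind(gray, gray[nrow(gray), ])
  if (ncol(gray) %% 2 == 1) gray <- cbind(gray, gray[, ncol(gray)])
  lo <- .colfilter(gray, .dtcwt_h0)
  hi <- .colfilter(gray, .dtcwt_h1)
  lohi <- .rowfilter(lo, .dtcwt_h1)   # horizontal-ish edges
  hilo <- .rowfilter(hi, .dtcwt_h0)   # vertical-ish edges
  hihi <- .rowfilter(hi, .dtcwt_h1)   # diagonal
  z_lh <- .q2c(lohi); z_hh <- .q2c(hihi); z_hl <- .q2c(hilo)
  list(p15 = z_lh$z1, p45 = z_hh$z1, p75 = z_hl$z1,
       m75 = z_hl$z2, m45 = z_hh$z2, m15 = z_lh$z2)
}

#' Dual-tree complex wavelet features of an RGB patch
#'
#' One-level dual-tree complex wavelet transform of the gray-converted
#' patch; for each of the six oriented subbands (about +/-15, +/-45 and
#' +/-75 degrees) the mean absolute value of the real part and of the
#' imaginary part are reported, giving 12 features in fixed
#' (orientation, real/imag) order.
#'
#' @param patch An `rgb_patch` or H x W x 3 array (0-255); side >= 16.
#' @return Named numeric vector of length 12, attribute `family = "dtcwt"`.
#' @export
dtcwt_features <- function(patch) {
  px <- .patch_pixels(patch)
  gray <- .gray_convert(px)
  if (nrow(gray) < 16L || ncol(gray) < 16L)
    stop("patch must be at least 16 x 16 for the wavelet decomposition",
         call. = FALSE)
  sb <- dtcwt_level1(gray)
  out <- unlist(lapply(names(sb), function(nm) {
    v <- c(mean(abs(Re(sb[[nm]]))), mean(abs(Im(sb[[nm]]))))
    names(v) <- paste0("dtcwt_", nm, c("_re", "_im"))
    v
  }))
  attr(out, "family") <- "dtcwt"
  out
}

#' Extract a named set of feature families from a patch
#'
#' @param patch An `rgb_patch` or H x W x 3 array.
#' @param families Character vector drawn from `"color"`, `"glcm"`,
#'   `"gabor"`, `"dtcwt"`.
#' @return Single named numeric vector, families concatenated in the given
#'   order; attribute `family = "combined"` when more than one.
#' @export
extract_features <- function(patch,
                             families = c("color", "glcm", "gabor", "dtcwt")) {
  families <- match.arg(families, several.ok = TRUE)
  fns <- list(color = color_features, glcm = glcm_features,
              gabor = gabor_features, dtcwt = dtcwt_features)
  out <- unlist(lapply(families, function(f) fns[[f]](patch)))
  attr(out, "family") <- if (length(families) == 1L) families else "combined"
  out
}

#' Signed gray contrast between sound and injured patches
#'
#' `Con = mean_gray(SS) - mean_gray(IS)` with gray the BT.601 luminance.
#' Positive when the injured patch is darker than sound skin; negative for
#' fresh injuries that reflect more light.
#'
#' @param ss,is_ `rgb_patch` objects or H x W x 3 arrays.
#' @return A single number.
#' @export
contrast_con <- function(ss, is_) {
  .gray_mean(.patch_pixels(ss)) - .gray_mean(.patch_pixels(is_))
}
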
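# smFISH spot detection and radial (10-bin) quantification between a
# central and a portal vein outline.

#' Detect diffraction-limited spots in a 2-D image
#'
#' Laplacian-of-Gaussian filtering at scale `psf_sigma`, local maxima of
#' the (negated) response above `threshold`, and sub-pixel refinement by a
#' separable quadratic fit around each maximum.
#'
#' @param image Numeric matrix, indexed `[row = y, col = x]`.
#' @param psf_sigma Spot scale in pixels (> 0).
#' @param threshold Minimum LoG response amplitude for a detection.
#' @return data.frame `x`, `y` (pixel-centre convention: a spot centred in
#'   pixel (i, j) has x = j - 0.5, y = i - 0.5) and `response`.
#' @export
detect_spots <- function(image, psf_sigma, threshold) {
  if (psf_sigma <= 0) stop("psf_sigma must be positive")
  stopifnot(is.matrix(image))
  resp <- -log_filter(image, psf_sigma) * psf_sigma^2  # scale-normalized
  h <- nrow(resp); w <- ncol(resp)
  if (h < 3 || w < 3) return(data.frame(x = numeric(0), y = numeric(0),
                                        response = numeric(0)))
  core <- resp[2:(h - 1), 2:(w - 1)]
  is_max <- core > threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- resp[(2 + dy):(h - 1 + dy), (2 + dx):(w - 1 + dx)]
    is_max <- is_max & core >= nb
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(data.frame(x = numeric(0), y = numeric(0),
                                        response = numeric(0)))
  iy <- idx[, 1] + 1L; ix <- idx[, 2] + 1L
  # quadratic sub-pixel offset from the 1-D three-point parabola
  off1d <- function(fm, f0, fp) {
    den <- fm - 2 * f0 + fp
    d <- ifelse(abs(den) > 0, 0.5 * (fm - fp) / den, 0)
    pmax(pmin(d, 0.5), -0.5)
  }
  dx <- off1d(resp[cbind(iy, ix - 1L)], resp[cbind(iy, ix)],
              resp[cbind(iy, ix + 1L)])
  dy <- off1d(resp[cbind(iy - 1L, ix)], resp[cbind(iy, ix)],
              resp[cbind(iy + 1L, ix)])
  data.frame(x = ix - 0.5 + dx, y = iy - 0.5 + dy,
             response = resp[cbind(iy, ix)])
}

# 2-D Laplacian-of-Gaussian convolution (zero-padded borders) by summing
# weighted shifts of the image; kernel truncated at 4 sigma.
log_filter <- function(image, sigma) {
  half <- max(2L, as.integer(ceiling(4 * sigma)))
  off <- -half:half
  g <- exp(-off^2 / (2 * sigma^2))
  g <- g / sum(g)
  # separable decomposition of the LoG: gxx (x) g + g (x) gyy
  d2 <- (off^2 - sigma^2) / sigma^4
  gxx <- d2 * g
  conv_sep(image, gxx, g) + conv_sep(image, g, gxx)
}

# separable convolution: kernel kx applied along x (columns), ky along y
conv_sep <- function(image, kx, ky) {
  half <- (length(kx) - 1L) %/% 2L
  h <- nrow(image); w <- ncol(image)
  pad <- matrix(0, h + 2 * half, w + 2 * half)
  pad[half + seq_len(h), half + seq_len(w)] <- image
  tmp <- matrix(0, h + 2 * half, w)
  for (i in seq_along(kx))
    tmp <- tmp + kx[i] * pad[, (i - 1) + seq_len(w)]
  out <- matrix(0, h, w)
  for (i in seq_along(ky))
    out <- out + ky[i] * tmp[(i - 1) + seq_len(h), ]
  out
}

# signed point-in-polygon (even-odd) via mgcv's in/out test
in_polygon <- function(x, y, poly) {
  bnd <- rbind(as.matrix(poly[, c("x", "y")]),
               as.matrix(poly[1, c("x", "y")]))
  mgcv::in.out(bnd, cbind(x, y))
}

# minimum Euclidean distance from points to a closed polygon's boundary
dist_to_polygon <- function(x, y, poly) {
  px <- poly$x; py <- poly$y
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  best <- rep(Inf, length(x))
  for (s in seq_along(px)) {
    ex <- qx[s] - px[s]; ey <- qy[s] - py[s]
    len2 <- ex^2 + ey^2
    t <- if (len2 > 0) ((x - px[s]) * ex + (y - py[s]) * ey) / len2 else 0
    t <- pmax(0, pmin(1, t))
    d2 <- (x - (px[s] + t * ex))^2 + (y - (py[s] + t * ey))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# relative radial coordinate r = d_CV / (d_CV + d_PV)
relative_radius <- function(x, y, cv, pv) {
  dcv <- dist_to_polygon(x, y, cv)
  dpv <- dist_to_polygon(x, y, pv)
  tot <- dcv + dpv
  if (any(tot == 0)) stop("point equidistant at zero from both veins")
  dcv / tot
}

#' Assign spots to radial bins between the central and portal veins
#'
#' For each spot, `r = d_CV / (d_CV + d_PV)` with distances to the nearest
#' point of each vein outline; bin = `floor(n_bins * r)` (0-based), with
#' `r = 1` clamped into the last bin. Spots inside either vein lumen are
#' masked (`NA`) with a warning.
#'
#' @param spots data.frame with `x`, `y`.
#' @param cv,pv Central and portal vein outlines (data.frame `x`, `y`).
#' @param n_bins Number of radial bins (default 10).
#' @return Integer bin per spot (0 .. n_bins - 1; `NA` for masked spots).
#' @export
assign_bins <- function(spots, cv, pv, n_bins = 10) {
  inside <- in_polygon(spots$x, spots$y, cv) |
    in_polygon(spots$x, spots$y, pv)
  if (any(inside))
    warning(sum(inside), " spot(s) inside vein lumens masked")
  r <- rep(NA_real_, nrow(spots))
  if (any(!inside))
    r[!inside] <- relative_radius(spots$x[!inside], spots$y[!inside],
                                  cv, pv)
  as.integer(pmin(floor(r * n_bins), n_bins - 1))
}

#' Area-normalized radial profile of spot counts
#'
#' Per-bin spot counts are normalized by the bin's tissue area in pixels
#' (computed by evaluating `r` at every pixel centre, excluding vein
#' interiors and any additional mask), and the percentage of the total
#' normalized density in each bin is reported.
#'
#' @param spots data.frame with `x`, `y` and optionally `image`, `mouse`.
#' @param cv,pv Vein outlines.
#' @param width,height Image extent in pixels.
#' @param n_bins Number of radial bins (default 10).
#' @param mask Optional logical matrix (`height` x `width`), `TRUE` for
#'   pixels to exclude (e.g. red blood cells in lumens).
#' @return data.frame per bin: `bin` (0-based), `count`, `area`,
#'   `density`, `percent`; percentages sum to 100 when any spot falls in
#'   tissue. Carries `image`/`mouse` columns when present in `spots`.
#' @export
radial_profile <- function(spots, cv, pv, width, height, n_bins = 10,
                           mask = NULL) {
  bins <- assign_bins(spots, cv, pv, n_bins)
  counts <- tabulate(bins + 1L, n_bins)

  px <- pixel_grid(width, height)
  tissue <- !in_polygon(px$x, px$y, cv) & !in_polygon(px$x, px$y, pv)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), nrow(mask) == height, ncol(mask) == width)
    tissue <- tissue & !as.vector(t(mask))
  }
  r_px <- relative_radius(px$x[tissue], px$y[tissue], cv, pv)
  pix_bin <- pmin(as.integer(floor(r_px * n_bins)), n_bins - 1L)
  area <- tabulate(pix_bin + 1L, n_bins)
  if (any(counts > 0 & area == 0))
    stop("bin with spots but zero tissue area")
  density <- ifelse(area > 0, counts / area, 0)
  percent <- if (sum(density) > 0) 100 * density / sum(density) else
    rep(0, n_bins)
  out <- data.frame(bin = 0:(n_bins - 1), count = counts, area = area,
                    density = density, percent = percent)
  for (col in c("image", "mouse"))
    if (!is.null(spots[[col]]) && length(unique(spots[[col]])) == 1)
      out[[col]] <- spots[[col]][1]
  out
}

#' Average radial profiles within each mouse
#'
#' Unweighted arithmetic mean of the per-image percentage vectors for each
#' mouse.
#'
#' @param profiles data.frame with `mouse`, `bin`, `percent` (stacked
#'   [radial_profile()] outputs).
#' @return data.frame `mouse`, `bin`, `percent`.
#' @export
average_by_mouse <- function(profiles) {
  stopifnot(all(c("mouse", "bin", "percent") %in% names(profiles)))
  agg <- stats::aggregate(percent ~ mouse + bin, data = profiles,
                          FUN = mean)
  agg[order(agg$mouse, agg$bin), c("mouse", "bin", "percent")]
}
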
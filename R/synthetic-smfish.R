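# Synthetic smFISH spot fields around a central and a portal vein.

#' Configuration for the synthetic smFISH field generator
#'
#' A field of transcript spots is placed by an inhomogeneous Poisson process
#' whose per-pixel rate depends on the relative radial coordinate
#' \eqn{r = d_{CV} / (d_{CV} + d_{PV})}, the distance to the central vein
#' boundary as a fraction of the summed distances to both vein boundaries.
#' Veins are disks (regular polygons) that must be disjoint and inside the
#' image.
#'
#' @param width,height Image extent in pixels.
#' @param cv_center,cv_radius,pv_center,pv_radius Central and portal vein
#'   disk geometry (pixels).
#' @param lambda_intercept,lambda_slope Per-pixel Poisson rate
#'   \eqn{\lambda(r) = a + b r}; must be non-negative on \eqn{[0,1]}.
#' @param psf_sigma Point-spread sigma (pixels) used when rendering images.
#' @param background_sd Gaussian background noise of rendered images.
#' @param n_images,n_mice Number of images, split evenly across mice.
#' @param gene Channel label attached to every spot.
#' @param seed Integer seed.
#' @return An `smfish_sim_config` list.
#' @export
smfish_sim_config <- function(width = 200, height = 200,
                              cv_center = c(50, 100), cv_radius = 15,
                              pv_center = c(160, 100), pv_radius = 12,
                              lambda_intercept = 0.02, lambda_slope = 0,
                              psf_sigma = 1.5, background_sd = 0.02,
                              n_images = 1, n_mice = 1,
                              gene = "Glul", seed = 1L) {
  stopifnot(width > 0, height > 0, cv_radius > 0, pv_radius > 0,
            psf_sigma > 0, background_sd >= 0, n_images >= 1, n_mice >= 1)
  if (min(lambda_intercept, lambda_intercept + lambda_slope) < 0)
    stop("lambda(r) must be non-negative on [0, 1]")
  gap <- sqrt(sum((cv_center - pv_center)^2)) - cv_radius - pv_radius
  if (gap <= 0) stop("vein polygons overlap")
  inside <- function(c, r) all(c - r >= 0) && c[1] + r <= width &&
    c[2] + r <= height
  if (!inside(cv_center, cv_radius) || !inside(pv_center, pv_radius))
    stop("vein polygons must lie inside the image")
  structure(list(width = width, height = height,
                 cv_center = cv_center, cv_radius = cv_radius,
                 pv_center = pv_center, pv_radius = pv_radius,
                 lambda_intercept = lambda_intercept,
                 lambda_slope = lambda_slope,
                 psf_sigma = psf_sigma, background_sd = background_sd,
                 n_images = as.integer(n_images),
                 n_mice = as.integer(n_mice),
                 gene = gene, seed = as.integer(seed)),
            class = "smfish_sim_config")
}

# Disk as a closed regular polygon (64 vertices), the package-wide vein
# outline representation: data.frame(x, y, type).
vein_polygon <- function(center, radius, type, n_vertices = 64) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  data.frame(x = center[1] + radius * cos(th),
             y = center[2] + radius * sin(th),
             type = type, stringsAsFactors = FALSE)
}

#' Simulate smFISH spot fields with a known radial intensity profile
#'
#' Spots are drawn per image by an inhomogeneous Poisson process with rate
#' \eqn{\lambda(r)} per tissue pixel (vein interiors excluded), with uniform
#' sub-pixel jitter. Optionally renders each image by stamping a Gaussian of
#' `psf_sigma` per spot plus background noise.
#'
#' @param config An [smfish_sim_config()].
#' @param render If `TRUE`, also return rendered intensity images.
#' @return List with `spots` (data.frame `x`, `y`, `gene`, `image`,
#'   `mouse`), `cv` and `pv` vein outlines, `lambda` (the true rate
#'   function of `r`), and `images` (list of matrices, `NULL` unless
#'   `render`).
#' @export
simulate_smfish <- function(config, render = FALSE) {
  stopifnot(inherits(config, "smfish_sim_config"))
  set.seed(config$seed)
  cv <- vein_polygon(config$cv_center, config$cv_radius, "central")
  pv <- vein_polygon(config$pv_center, config$pv_radius, "portal")
  lambda <- function(r) config$lambda_intercept + config$lambda_slope * r

  # pixel-centre grid; r and tissue mask are identical across images
  px <- pixel_grid(config$width, config$height)
  tissue <- !in_polygon(px$x, px$y, cv) & !in_polygon(px$x, px$y, pv)
  r <- relative_radius(px$x[tissue], px$y[tissue], cv, pv)
  rate <- lambda(r)

  mouse_of <- rep(seq_len(config$n_mice), length.out = config$n_images)
  spots <- vector("list", config$n_images)
  images <- if (render) vector("list", config$n_images) else NULL
  for (img in seq_len(config$n_images)) {
    n_spots <- stats::rpois(1, sum(rate))
    idx <- sample.int(length(rate), n_spots, replace = TRUE, prob = rate)
    x <- px$x[tissue][idx] + stats::runif(n_spots, -0.5, 0.5)
    y <- px$y[tissue][idx] + stats::runif(n_spots, -0.5, 0.5)
    # sub-pixel jitter may push a boundary-pixel spot into a lumen;
    # re-jitter those so all spots stay in tissue
    for (round in 1:20) {
      bad <- in_polygon(x, y, cv) | in_polygon(x, y, pv)
      if (!any(bad)) break
      x[bad] <- px$x[tissue][idx[bad]] + stats::runif(sum(bad), -0.5, 0.5)
      y[bad] <- px$y[tissue][idx[bad]] + stats::runif(sum(bad), -0.5, 0.5)
    }
    spots[[img]] <- data.frame(x = x, y = y, gene = config$gene,
                               image = sprintf("IMG%02d", img),
                               mouse = sprintf("M%02d", mouse_of[img]),
                               stringsAsFactors = FALSE)
    if (render)
      images[[img]] <- render_spot_image(x, y, config$width, config$height,
                                         config$psf_sigma,
                                         config$background_sd)
  }
  list(spots = do.call(rbind, spots), cv = cv, pv = pv,
       lambda = lambda, images = images)
}

pixel_grid <- function(width, height) {
  list(x = rep(seq_len(width) - 0.5, times = height),
       y = rep(seq_len(height) - 0.5, each = width))
}

# Stamp unit-amplitude Gaussians at (x, y) onto a height x width matrix
# indexed [row = y, col = x], then add N(0, sd) background.
render_spot_image <- function(x, y, width, height, sigma, background_sd) {
  img <- matrix(0, height, width)
  half <- ceiling(4 * sigma)
  off <- -half:half
  for (s in seq_along(x)) {
    cx <- x[s] + 0.5; cy <- y[s] + 0.5   # pixel-centre convention
    ix <- round(cx) + off; iy <- round(cy) + off
    keep_x <- ix >= 1 & ix <= width; keep_y <- iy >= 1 & iy <= height
    gx <- exp(-((ix - cx)^2) / (2 * sigma^2))
    gy <- exp(-((iy - cy)^2) / (2 * sigma^2))
    img[iy[keep_y], ix[keep_x]] <- img[iy[keep_y], ix[keep_x]] +
      outer(gy[keep_y], gx[keep_x])
  }
  img + matrix(stats::rnorm(length(img), 0, background_sd), height, width)
}
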
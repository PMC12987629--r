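#' Generate a synthetic fiber image with known crossings
#'
#' Draws `n_fibers` random smooth curves (unit-speed random walks with small
#' angular diffusion) of fixed intensity on a dark background, blurs with a
#' Gaussian point-spread function and adds Poisson-like shot noise. The exact
#' polyline of every fiber is recorded in `truth`, so grid-crossing counts
#' can be computed exactly by [true_crossings()].
#'
#' @param n_fibers number of fibers (>= 0).
#' @param size_px image side, pixels.
#' @param um_per_px spatial calibration.
#' @param psf_sigma_px PSF standard deviation, pixels.
#' @param noise_level relative shot-noise SD at unit intensity; 0 disables
#'   noise.
#' @param rng an [make_rng()] stream.
#' @param intensity fiber line intensity before blurring.
#' @param background background intensity.
#' @param fibers optional list of polyline data frames (`x`, `y`) to draw
#'   instead of random curves (used to construct images with known geometry).
#' @return A [fiber_image()] with `truth$fibers`.
#' @export
gen_fiber_image <- function(n_fibers, size_px = 256, um_per_px = 0.5,
                            psf_sigma_px = 1.2, noise_level = 0.05,
                            rng = make_rng(1, "fibers"),
                            intensity = 4, background = 0.2,
                            fibers = NULL) {
  stopifnot(n_fibers >= 0)
  rng_draw(rng, {
    if (is.null(fibers)) {
      fibers <- lapply(seq_len(n_fibers), function(i)
        random_fiber(size_px))
    }
    img <- matrix(0, size_px, size_px)
    for (f in fibers) img <- rasterize_polyline(img, f, intensity)
    img <- blur_gaussian(img, psf_sigma_px) + background
    if (noise_level > 0) {
      kappa <- 1 / noise_level^2
      img <- matrix(stats::rpois(length(img), img * kappa) / kappa,
                    nrow(img), ncol(img))
    }
    fiber_image(img, um_per_px = um_per_px,
                truth = list(fibers = fibers, n_fibers = length(fibers),
                             psf_sigma_px = psf_sigma_px,
                             noise_level = noise_level))
  })
}

# A smooth random curve crossing the field: random entry point and heading,
# unit-pixel steps with angular diffusion, clipped at the image border.
random_fiber <- function(size_px) {
  x <- stats::runif(1, 1, size_px)
  y <- stats::runif(1, 1, size_px)
  th <- stats::runif(1, 0, 2 * pi)
  nstep <- round(1.5 * size_px)
  xs <- numeric(nstep); ys <- numeric(nstep)
  for (i in seq_len(nstep)) {
    xs[i] <- x; ys[i] <- y
    th <- th + stats::rnorm(1, 0, 0.08)
    x <- x + cos(th); y <- y + sin(th)
    if (x < 1 || x > size_px || y < 1 || y > size_px) break
  }
  k <- max(which(xs != 0 | ys != 0))
  data.frame(x = xs[seq_len(k)], y = ys[seq_len(k)])
}

# Draw a polyline by marking every pixel the segments pass through.
rasterize_polyline <- function(img, f, intensity) {
  nr <- nrow(img); nc <- ncol(img)
  for (k in seq_len(nrow(f) - 1)) {
    len <- max(abs(f$x[k + 1] - f$x[k]), abs(f$y[k + 1] - f$y[k]), 1e-9)
    np <- max(2L, ceiling(len * 2))
    xs <- seq(f$x[k], f$x[k + 1], length.out = np)
    ys <- seq(f$y[k], f$y[k + 1], length.out = np)
    r <- pmin(pmax(round(ys), 1L), nr)
    c <- pmin(pmax(round(xs), 1L), nc)
    img[unique(cbind(r, c))] <- intensity
  }
  img
}

# Separable Gaussian blur (replicate-padded), preserving total flux away
# from the border.
blur_gaussian <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  for (i in seq_len(nrow(m))) m[i, ] <- gaussian_smooth(m[i, ], 1, sigma_px)
  for (j in seq_len(ncol(m))) m[, j] <- gaussian_smooth(m[, j], 1, sigma_px)
  m
}
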
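## Synthetic pulsating-region phantom videos with analytic ground truth.
##
## The phantom emulates the recorded organ: a bright ellipse on a darker
## textured background whose semi-axes pulse sinusoidally, so the projected
## area (and hence the pixel-fraction "size" of the region) oscillates with
## a known amplitude. Every downstream stage can be validated against the
## rasterized truth masks and the closed-form intensity.

#' Specify a pulsating-ellipse phantom video
#'
#' Defines a synthetic video in which a bright elliptical region pulses on a
#' darker, smoothly textured background. Both semi-axes are scaled by
#' \eqn{s(t) = 1 + A\sin(2\pi\,\mathrm{cycles}\,t/n)}, so the projected area
#' scales as \eqn{s(t)^2} and the relative size change between full
#' relaxation and full contraction has the closed form
#' [analytic_intensity()].
#'
#' @param width,height Frame size in pixels.
#' @param n_frames Number of frames in the video.
#' @param center `(row, col)` of the ellipse centre, 1-based; defaults to the
#'   frame centre.
#' @param base_axes `(a0, b0)` baseline semi-axes in pixels: `a0` along rows,
#'   `b0` along columns.
#' @param amplitude Pulsation amplitude `A` in `[0, 1)`.
#' @param cycles Number of full contraction cycles over the video.
#' @param fg_level,bg_level Foreground / background intensity in `[0, 1]`.
#' @param noise_sigma Standard deviation of per-pixel Gaussian noise.
#' @param texture_scale Correlation length (pixels) of the smooth additive
#'   texture field shared by both regions.
#' @param texture_amp Peak amplitude of the texture field (intensity units).
#' @param seed Integer seed; all randomness in the generator flows from it.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 160L, height = 160L, n_frames = 48L,
                         center = NULL, base_axes = c(55, 55),
                         amplitude = 0.10, cycles = 3L,
                         fg_level = 0.75, bg_level = 0.35,
                         noise_sigma = 0.03, texture_scale = 16,
                         texture_amp = 0.08, seed = 1L) {
  if (is.null(center)) center <- c((height + 1) / 2, (width + 1) / 2)
  spec <- structure(
    list(width = as.integer(width), height = as.integer(height),
         n_frames = as.integer(n_frames), center = as.numeric(center),
         base_axes = as.numeric(base_axes), amplitude = amplitude,
         cycles = as.integer(cycles), fg_level = fg_level,
         bg_level = bg_level, noise_sigma = noise_sigma,
         texture_scale = texture_scale, texture_amp = texture_amp,
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  A <- spec$amplitude
  if (A < 0 || A >= 1)
    stop_pulseroi("amplitude must satisfy 0 <= A < 1 (got ", A, ")")
  a0 <- spec$base_axes[1]; b0 <- spec$base_axes[2]
  if ((1 + A) * a0 >= spec$height / 2)
    stop_pulseroi("(1 + amplitude) * a0 = ", (1 + A) * a0,
                  " must be < height/2 = ", spec$height / 2,
                  " (region would touch the frame border)")
  if ((1 + A) * b0 >= spec$width / 2)
    stop_pulseroi("(1 + amplitude) * b0 = ", (1 + A) * b0,
                  " must be < width/2 = ", spec$width / 2,
                  " (region would touch the frame border)")
  if (spec$fg_level == spec$bg_level)
    stop_pulseroi("fg_level must differ from bg_level")
  if (spec$noise_sigma < 0) stop_pulseroi("noise_sigma must be >= 0")
  if (spec$n_frames < 1L) stop_pulseroi("n_frames must be >= 1")
  invisible(spec)
}

## Rasterize the ellipse with semi-axes (a, b) as a logical mask.
rasterize_ellipse <- function(height, width, center, a, b) {
  rr <- ((seq_len(height) - center[1]) / a)^2
  cc <- ((seq_len(width) - center[2]) / b)^2
  outer(rr, cc, "+") <= 1
}

## Smooth low-frequency texture: coarse white noise, bilinearly upsampled.
## Defeats global thresholding so the graph cut is genuinely exercised.
smooth_texture <- function(height, width, scale, amp) {
  gh <- max(2L, ceiling(height / scale) + 1L)
  gw <- max(2L, ceiling(width / scale) + 1L)
  coarse <- matrix(stats::runif(gh * gw, -amp, amp), gh, gw)
  ry <- seq(1, gh, length.out = height)
  rx <- seq(1, gw, length.out = width)
  y0 <- pmin(floor(ry), gh - 1L); x0 <- pmin(floor(rx), gw - 1L)
  fy <- ry - y0; fx <- rx - x0
  t00 <- coarse[cbind(rep(y0, width), rep(x0, each = height))]
  t10 <- coarse[cbind(rep(y0 + 1L, width), rep(x0, each = height))]
  t01 <- coarse[cbind(rep(y0, width), rep(x0 + 1L, each = height))]
  t11 <- coarse[cbind(rep(y0 + 1L, width), rep(x0 + 1L, each = height))]
  wy <- rep(fy, width); wx <- rep(fx, each = height)
  v <- (1 - wy) * (1 - wx) * t00 + wy * (1 - wx) * t10 +
    (1 - wy) * wx * t01 + wy * wx * t11
  matrix(v, height, width)
}

#' Generate a pulsating-ellipse phantom video with ground truth
#'
#' Renders the video described by a [phantom_spec()] and its exact ground
#' truth: noise-free rasterized masks, the true pixel-fraction size series,
#' the analytic relaxation/contraction frame indices, and the closed-form
#' contraction intensity.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{frames}{List of `height x width` intensity matrices in `[0,1]`.}
#'     \item{truth}{List with `masks` (logical matrices), `size_series`
#'       (percent of frame area per frame), `relax_frames` /
#'       `contract_frames` (1-based indices of maximal / minimal size;
#'       empty when `amplitude = 0`), and `true_intensity`
#'       (percent, [analytic_intensity()]).}
#'   }
#' @export
generate_pulsating_video <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  n <- spec$n_frames
  A <- spec$amplitude
  s <- 1 + A * sin(2 * pi * spec$cycles * (seq_len(n) - 1L) / n)
  masks <- lapply(s, function(sc)
    rasterize_ellipse(spec$height, spec$width, spec$center,
                      spec$base_axes[1] * sc, spec$base_axes[2] * sc))
  size_series <- vapply(masks, function(m) 100 * sum(m) / length(m), 0)

  frames <- withr::with_seed(spec$seed, {
    tex <- smooth_texture(spec$height, spec$width,
                          spec$texture_scale, spec$texture_amp)
    lapply(masks, function(m) {
      img <- spec$bg_level + (spec$fg_level - spec$bg_level) * m + tex
      if (spec$noise_sigma > 0)
        img <- img + matrix(stats::rnorm(length(m), 0, spec$noise_sigma),
                            nrow(m), ncol(m))
      pmin(pmax(img, 0), 1)
    })
  })

  if (A > 0 && spec$cycles >= 1L) {
    k <- seq_len(spec$cycles) - 1L
    relax <- round(n / (4 * spec$cycles) + k * n / spec$cycles) + 1L
    contract <- round(3 * n / (4 * spec$cycles) + k * n / spec$cycles) + 1L
    relax <- relax[relax >= 1L & relax <= n]
    contract <- contract[contract >= 1L & contract <= n]
  } else {
    relax <- integer(0)
    contract <- integer(0)
  }

  list(frames = frames,
       truth = list(masks = masks, size_series = size_series,
                    relax_frames = relax, contract_frames = contract,
                    true_intensity = analytic_intensity(A)))
}

#' Closed-form contraction intensity of the phantom
#'
#' For a pulsation amplitude `A`, the region area scales between
#' \eqn{(1+A)^2} (full relaxation) and \eqn{(1-A)^2} (full contraction), so
#' the relative size change is
#' \deqn{100\,\frac{(1+A)^2 - (1-A)^2}{(1+A)^2} = \frac{400A}{(1+A)^2}.}
#'
#' @param A Pulsation amplitude in `[0, 1)`.
#' @return Intensity in percent, in `[0, 100)`.
#' @export
analytic_intensity <- function(A) {
  if (!is.numeric(A) || any(A < 0) || any(A >= 1))
    stop_pulseroi("amplitude A must lie in [0, 1)")
  400 * A / (1 + A)^2
}

#' Sample scribble seeds from a ground-truth mask
#'
#' Emulates an operator's foreground/background scribbles: foreground seeds
#' are drawn from the mask eroded by `fg_margin`, background seeds from the
#' complement of the mask dilated by `bg_margin`, keeping both seed sets
#' safely away from the true boundary.
#'
#' @param mask Logical ground-truth mask.
#' @param fg_margin,bg_margin Margin radii in pixels.
#' @param n_points Number of seeds per class.
#' @param seed Integer seed.
#' @return A [scribble_set()] with `n_points` seeds per class.
#' @export
scribbles_from_truth <- function(mask, fg_margin = 3L, bg_margin = 3L,
                                 n_points = 50L, seed = 1L) {
  mask <- check_mask(mask)
  fg_region <- if (fg_margin > 0)
    as_mask(EBImage::erode(mask * 1L, disc_kernel(fg_margin))) else mask
  bg_region <- if (bg_margin > 0)
    !as_mask(EBImage::dilate(mask * 1L, disc_kernel(bg_margin))) else !mask
  if (!any(fg_region))
    stop_pulseroi("eroding the mask by fg_margin = ", fg_margin,
                  " leaves no foreground to seed")
  if (!any(bg_region))
    stop_pulseroi("dilating the mask by bg_margin = ", bg_margin,
                  " leaves no background to seed")
  withr::with_seed(seed, {
    fg_idx <- which(fg_region)
    bg_idx <- which(bg_region)
    fg <- sample(fg_idx, min(n_points, length(fg_idx)))
    bg <- sample(bg_idx, min(n_points, length(bg_idx)))
    scribble_set(
      foreground = cbind(row = (fg - 1L) %% nrow(mask) + 1L,
                         col = (fg - 1L) %/% nrow(mask) + 1L),
      background = cbind(row = (bg - 1L) %% nrow(mask) + 1L,
                         col = (bg - 1L) %/% nrow(mask) + 1L))
  })
}
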
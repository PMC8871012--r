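#' Configuration for synthetic spine phantoms
#'
#' A phantom is a single-arch scoliotic spine with a sinusoidal centerline
#' `x(y) = x0 + A * sin(pi * (y - y0) / L)` for y inside the arch and a
#' straight centerline elsewhere. Vertebra centers are equally spaced in y
#' across the arch; each box's endplates are perpendicular to the local
#' centerline tangent, so the phantom's Cobb angle is known analytically
#' from the tangent slopes (see [true_cobb()]).
#'
#' @param n_vertebrae number of vertebrae (5..17; default 17).
#' @param amplitude lateral arch amplitude A in pixels.
#' @param arch_top y of the arch start (pixels, default 80).
#' @param arch_len arch length L in pixels (default 864; with the default
#'   1024-px image height the arch spans the whole spine).
#' @param vertebra_width per-vertebra widths in pixels; length-2 values are
#'   linearly tapered superior to inferior (default `c(64, 96)`, emulating
#'   the wider lumbar bodies).
#' @param vertebra_height per-vertebra heights in pixels (default 32).
#' @param corner_noise_sigma standard deviation of i.i.d. Gaussian jitter
#'   added to every corner coordinate, in pixels (default 1, a minimal
#'   stand-in for landmark-detection error; 0 = noise-free).
#' @param score_range range of uniform per-box detection scores
#'   (default `c(0.85, 1)`).
#' @param image_width,image_height phantom image size in pixels
#'   (default 512 x 1024).
#' @param seed integer RNG seed; the generator is fully deterministic
#'   under a fixed seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_vertebrae = 17, amplitude = 50,
                           arch_top = 80, arch_len = 864,
                           vertebra_width = c(64, 96), vertebra_height = 32,
                           corner_noise_sigma = 1, score_range = c(0.85, 1),
                           image_width = 512, image_height = 1024,
                           seed = 1L) {
  stopifnot(n_vertebrae >= 5, n_vertebrae <= 17, arch_len > 0,
            corner_noise_sigma >= 0, amplitude >= 0,
            length(score_range) == 2L, score_range[1] <= score_range[2])
  if (arch_top < 0 || arch_top + arch_len > image_height)
    stop("arch [", arch_top, ", ", arch_top + arch_len,
         "] lies outside the image height ", image_height)
  structure(list(n_vertebrae = as.integer(n_vertebrae), amplitude = amplitude,
                 arch_top = arch_top, arch_len = arch_len,
                 vertebra_width = vertebra_width,
                 vertebra_height = vertebra_height,
                 corner_noise_sigma = corner_noise_sigma,
                 score_range = score_range,
                 image_width = image_width, image_height = image_height,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# centerline slope dx/dy at height y
phantom_slope <- function(cfg, y) {
  inside <- y >= cfg$arch_top & y <= cfg$arch_top + cfg$arch_len
  s <- numeric(length(y))
  s[inside] <- cfg$amplitude * pi / cfg$arch_len *
    cos(pi * (y[inside] - cfg$arch_top) / cfg$arch_len)
  s
}

phantom_center_y <- function(cfg) {
  seq(cfg$arch_top, cfg$arch_top + cfg$arch_len, length.out = cfg$n_vertebrae)
}

#' Analytic Cobb angle of a phantom configuration
#'
#' The centerline tangent makes angle `theta(y) = atan(dx/dy)` with the
#' vertical; because each phantom endplate is perpendicular to the tangent,
#' the Cobb angle that an ideal measurement should recover is the range of
#' `theta` over the vertebra center positions, ignoring corner noise.
#'
#' @param cfg a [phantom_config()].
#' @return Cobb angle in degrees (>= 0).
#' @export
true_cobb <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  th <- atan(phantom_slope(cfg, phantom_center_y(cfg))) * 180 / pi
  max(th) - min(th)
}

#' Solve for the arch amplitude that yields a target Cobb angle
#'
#' Inverts [true_cobb()] by bisection: the analytic angle is strictly
#' increasing in the amplitude, so the amplitude producing any requested
#' angle is found to 0.1 degrees.
#'
#' @param target_deg requested Cobb angle in degrees (0..170).
#' @param cfg a [phantom_config()]; its amplitude entry is ignored.
#' @param tol_deg bisection tolerance in degrees (default 0.1).
#' @return Amplitude in pixels.
#' @export
amplitude_for_cobb <- function(target_deg, cfg = phantom_config(),
                               tol_deg = 0.1) {
  stopifnot(target_deg >= 0, target_deg < 170)
  if (target_deg == 0) return(0)
  f <- function(a) {
    c2 <- cfg; c2$amplitude <- a
    true_cobb(c2)
  }
  lo <- 0; hi <- cfg$arch_len  # ample upper bound (slope ~ pi at A = L)
  while (f(hi) < target_deg) hi <- hi * 2
  repeat {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v - target_deg) <= tol_deg) return(mid)
    if (v < target_deg) lo <- mid else hi <- mid
  }
}

#' Generate a synthetic spine phantom
#'
#' Places `n_vertebrae` boxes along the sinusoidal centerline of `cfg`:
#' centers equally spaced in y, endplate edges perpendicular to the local
#' tangent, widths/heights from the configured (optionally tapered)
#' profiles, i.i.d. Gaussian corner jitter, and uniform detection scores.
#' Fully deterministic under the configured seed.
#'
#' @param cfg a [phantom_config()].
#' @return An object of class `phantom`: list with `seq` (the
#'   [spine_sequence()]), `true_cobb_deg`, `true_apex_index`, and `config`.
#' @examples
#' ph <- generate_phantom(phantom_config(amplitude = 80, seed = 7))
#' ph$true_cobb_deg
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  n <- cfg$n_vertebrae
  cy <- phantom_center_y(cfg)
  x0 <- cfg$image_width / 2
  cx <- x0 + ifelse(
    cy >= cfg$arch_top & cy <= cfg$arch_top + cfg$arch_len,
    cfg$amplitude * sin(pi * (cy - cfg$arch_top) / cfg$arch_len), 0)
  s <- phantom_slope(cfg, cy)
  # endplate tilt: perpendicular to the tangent (t = (s, 1)/|.|) means the
  # edge direction is u = (1, -s)/|.|, i.e. tilt angle -atan(s)
  t_ang <- -atan(s)

  widths <- if (length(cfg$vertebra_width) == 2L)
    seq(cfg$vertebra_width[1], cfg$vertebra_width[2], length.out = n)
  else rep_len(cfg$vertebra_width, n)
  heights <- rep_len(cfg$vertebra_height, n)

  corners <- matrix(NA_real_, n, 8, dimnames = list(NULL, .corner_cols))
  for (i in seq_len(n)) {
    u <- c(cos(t_ang[i]), sin(t_ang[i]))
    v <- c(-sin(t_ang[i]), cos(t_ang[i]))
    c0 <- c(cx[i], cy[i])
    hw <- widths[i] / 2; hh <- heights[i] / 2
    corners[i, ] <- c(c0 - hh * v - hw * u, c0 - hh * v + hw * u,
                      c0 + hh * v - hw * u, c0 + hh * v + hw * u)
  }

  with_seed(cfg$seed, {
    if (cfg$corner_noise_sigma > 0)
      corners <- corners + stats::rnorm(length(corners),
                                        sd = cfg$corner_noise_sigma)
    scores <- stats::runif(n, cfg$score_range[1], cfg$score_range[2])
  })

  seq <- spine_sequence(corners, scores = scores,
                        image_width = cfg$image_width,
                        image_height = cfg$image_height)
  structure(list(seq = seq,
                 true_cobb_deg = true_cobb(cfg),
                 true_apex_index = which.min(abs(cy - (cfg$arch_top + cfg$arch_len / 2))),
                 config = cfg),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d vertebrae, true Cobb %.1f deg, apex at box %d\n",
              nrow(x$seq), x$true_cobb_deg, x$true_apex_index))
  invisible(x)
}

#' Rasterize a phantom into a pseudo-radiograph
#'
#' Renders bright filled vertebra quadrilaterals on a torso-shaped mid-gray
#' background over a darker surround, with additive Gaussian pixel noise —
#' a deliberately simple stand-in for a radiograph, sufficient to exercise
#' texture features and window classification. Deterministic under `seed`.
#'
#' @param ph a [generate_phantom()] result.
#' @param width,height output size in pixels (default: the phantom's image
#'   size).
#' @param contrast vertebra brightness relative to the torso background
#'   (default 1: vertebrae at gray level 220 vs torso 110).
#' @param noise standard deviation of additive Gaussian noise in gray
#'   levels on the 0..255 scale (default 8).
#' @param seed RNG seed for the pixel noise (default: the phantom's seed).
#' @return Numeric matrix `height x width` with values clipped to
#'   `[0, 255]` (row = y, column = x).
#' @export
render_image <- function(ph, width = NULL, height = NULL, contrast = 1,
                         noise = 8, seed = NULL) {
  stopifnot(inherits(ph, "phantom"))
  cfg <- ph$config
  if (is.null(width)) width <- cfg$image_width
  if (is.null(height)) height <- cfg$image_height
  if (is.null(seed)) seed <- cfg$seed
  img <- matrix(40, nrow = height, ncol = width)

  # torso: rectangle around the spine with a margin
  cen <- vertebra_centers(ph$seq)
  tx <- pmax(1, floor(width * 0.2)):pmin(width, ceiling(width * 0.8))
  ty <- pmax(1, floor(min(cen$y) - 40)):pmin(height, ceiling(max(cen$y) + 40))
  img[ty, tx] <- 110

  lvl <- min(255, 110 + 110 * contrast)
  sq <- ph$seq
  for (i in seq_len(nrow(sq))) {
    poly_x <- c(sq$tl_x[i], sq$tr_x[i], sq$br_x[i], sq$bl_x[i])
    poly_y <- c(sq$tl_y[i], sq$tr_y[i], sq$br_y[i], sq$bl_y[i])
    xr <- pmax(1, floor(min(poly_x))):pmin(width, ceiling(max(poly_x)))
    yr <- pmax(1, floor(min(poly_y))):pmin(height, ceiling(max(poly_y)))
    if (length(xr) == 0L || length(yr) == 0L) next
    gx <- rep(xr, each = length(yr)); gy <- rep(yr, times = length(xr))
    img[cbind(gy, gx)[in_convex_quad(gx, gy, poly_x, poly_y), , drop = FALSE]] <- lvl
  }

  if (noise > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img), sd = noise),
                                        nrow = height))
  img[img < 0] <- 0; img[img > 255] <- 255
  img
}

# vectorized point-in-convex-quadrilateral test (vertices in order)
in_convex_quad <- function(px, py, qx, qy) {
  inside <- rep(TRUE, length(px))
  sgn <- NULL
  for (k in 1:4) {
    k2 <- if (k == 4) 1L else k + 1L
    cr <- (qx[k2] - qx[k]) * (py - qy[k]) - (qy[k2] - qy[k]) * (px - qx[k])
    if (is.null(sgn)) sgn <- sign(sum(cr))  # orientation of the quad
    inside <- inside & (cr * sgn >= 0)
  }
  inside
}

# evaluate expr with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
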
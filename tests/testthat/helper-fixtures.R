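# Shared builders for geometry tests: hand-constructed sequences and
# rigid-transform utilities. All independent of the package's own
# box-construction code paths where they serve as oracles.

# sequence with prescribed endplate tilts (deg, applied to both edges) and
# center x positions; centers equally spaced vertically
tilted_sequence <- function(tilts_deg, xs, y0 = 50, spacing = 40,
                            width = 40, height = 24, score = 1) {
  stopifnot(length(tilts_deg) == length(xs))
  n <- length(xs)
  corners <- matrix(NA_real_, n, 8)
  for (i in seq_len(n)) {
    t <- tilts_deg[i] * pi / 180
    u <- c(cos(t), sin(t))          # endplate direction
    v <- c(-sin(t), cos(t))         # axis direction (down)
    c0 <- c(xs[i], y0 + spacing * (i - 1))
    hw <- width / 2; hh <- height / 2
    corners[i, ] <- c(c0 - hh * v - hw * u, c0 - hh * v + hw * u,
                      c0 + hh * v - hw * u, c0 + hh * v + hw * u)
  }
  spine_sequence(corners, scores = score,
                 image_width = 2 * max(xs), image_height = y0 + spacing * n)
}

seq_corner_matrix <- function(seq)
  as.matrix(as.data.frame(seq)[, c("tl_x", "tl_y", "tr_x", "tr_y",
                                   "bl_x", "bl_y", "br_x", "br_y")])

rebuild_sequence <- function(seq, corners)
  spine_sequence(corners, scores = seq$score,
                 image_width = attr(seq, "image_width"),
                 image_height = attr(seq, "image_height"))

# rigid rotation of all landmarks about `center` by `deg` (y-down screen
# convention; small angles keep box roles valid)
rotate_seq <- function(seq, deg, center = c(0, 0)) {
  a <- deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  m <- seq_corner_matrix(seq)
  for (k in c(1, 3, 5, 7)) {
    p <- t(R %*% (t(m[, k:(k + 1)]) - center) + center)
    m[, k:(k + 1)] <- p
  }
  rebuild_sequence(seq, m)
}

translate_seq <- function(seq, dx, dy) {
  m <- seq_corner_matrix(seq)
  m[, c(1, 3, 5, 7)] <- m[, c(1, 3, 5, 7)] + dx
  m[, c(2, 4, 6, 8)] <- m[, c(2, 4, 6, 8)] + dy
  rebuild_sequence(seq, m)
}

# left-right reflection about the vertical line x = axis_x; corner roles
# swap left for right
mirror_seq <- function(seq, axis_x = NULL) {
  m <- seq_corner_matrix(seq)
  if (is.null(axis_x)) axis_x <- mean(m[, c(1, 3, 5, 7)])
  m[, c(1, 3, 5, 7)] <- 2 * axis_x - m[, c(1, 3, 5, 7)]
  m2 <- m
  m2[, 1:2] <- m[, 3:4]; m2[, 3:4] <- m[, 1:2]   # tl <-> tr
  m2[, 5:6] <- m[, 7:8]; m2[, 7:8] <- m[, 5:6]   # bl <-> br
  rebuild_sequence(seq, m2)
}

scale_seq <- function(seq, f) rebuild_sequence(seq, seq_corner_matrix(seq) * f)

# independent apex oracle: exhaustive perpendicular-distance scan
brute_apex <- function(seq) {
  cen <- vertebra_centers(seq)
  n <- nrow(cen)
  a <- c(cen$x[1], cen$y[1]); b <- c(cen$x[n], cen$y[n])
  len <- sqrt(sum((b - a)^2))
  d <- numeric(n)
  for (i in seq_len(n))
    d[i] <- abs((cen$x[i] - a[1]) * (b[2] - a[2]) -
                  (cen$y[i] - a[2]) * (b[1] - a[1])) / len
  which.max(d)
}

# independent end-vertebra oracle: explicit loops with the tie rules
brute_ends <- function(seq, apex) {
  top <- abs(edge_tilt(seq, "top")); bot <- abs(edge_tilt(seq, "bottom"))
  sup <- 1L
  for (i in seq_len(apex)) if (top[i] > top[sup]) sup <- i
  inf <- nrow(seq)
  for (i in rev(apex:nrow(seq))) if (bot[i] > bot[inf]) inf <- i
  list(superior_index = sup, inferior_index = inf)
}

# noise-free phantom with a requested analytic angle
phantom_for_angle <- function(angle, seed = 1, noise = 0, n = 17) {
  cfg <- phantom_config(n_vertebrae = n, corner_noise_sigma = noise,
                        seed = seed)
  cfg$amplitude <- amplitude_for_cobb(angle, cfg)
  generate_phantom(cfg)
}
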
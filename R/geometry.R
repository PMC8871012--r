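#' Filter vertebra boxes by detection score
#'
#' Keeps only boxes whose detection score strictly exceeds the threshold
#' (default 0.5), preserving the superior-to-inferior order. Fewer than five
#' surviving boxes make a Cobb measurement infeasible and raise an error of
#' class `cobb_infeasible`.
#'
#' @param seq a [spine_sequence()].
#' @param threshold score cutoff in `[0, 1]`; a box survives iff
#'   `score > threshold`.
#' @return The filtered [spine_sequence()].
#' @export
filter_by_score <- function(seq, threshold = 0.5) {
  stopifnot(inherits(seq, "spine_sequence"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  keep <- which(seq$score > threshold)
  if (length(keep) < 5L)
    stop(infeasible_error(sprintf(
      "only %d box(es) exceed score threshold %g; at least 5 are required",
      length(keep), threshold)))
  subset_sequence(seq, keep)
}

#' Detect laterally displaced outlier boxes
#'
#' A detected box is rejected as an outlier when its x-center lies more than
#' half the box width from the x-center of its two closest neighbours
#' (mean of the nearest usable boxes above and below). The first and last
#' vertebrae, which are flanked on one side only, are compared against the
#' linear extrapolation from the two nearest boxes on that side.
#'
#' Rejection is greedy and iterative: in each pass the box with the largest
#' excess deviation is flagged, and subsequent passes recompute every
#' reference from the nearest boxes not yet flagged. A single grossly
#' displaced box therefore does not drag its well-placed neighbours (whose
#' raw references it contaminates) into rejection.
#'
#' @param seq a [spine_sequence()] with at least 3 boxes.
#' @return Integer vector of outlier row indices, in increasing order
#'   (possibly empty).
#' @export
detect_outliers <- function(seq) {
  stopifnot(inherits(seq, "spine_sequence"))
  n <- nrow(seq)
  if (n < 3L) stop("outlier detection needs at least 3 boxes; got ", n)
  xc <- vertebra_centers(seq)$x
  w <- vertebra_dims(seq)$width
  bad <- logical(n)
  repeat {
    ok <- which(!bad)
    if (length(ok) < 3L) break
    excess <- rep(-Inf, n)
    for (i in ok) {
      above <- ok[ok < i]; below <- ok[ok > i]
      # an end box has no flanking pair; its reference is the linear
      # extrapolation from the two nearest boxes on its one side, so a
      # uniformly tilted spine (which shifts x by slope * spacing between
      # neighbours) is not mistaken for displacement
      ref <- if (length(above) && length(below)) {
        (xc[max(above)] + xc[min(below)]) / 2
      } else if (length(below) >= 2L) {
        b <- sort(below)[1:2]
        2 * xc[b[1L]] - xc[b[2L]]
      } else if (length(above) >= 2L) {
        a <- sort(above, decreasing = TRUE)[1:2]
        2 * xc[a[1L]] - xc[a[2L]]
      } else if (length(below)) xc[min(below)] else xc[max(above)]
      excess[i] <- abs(xc[i] - ref) - w[i] / 2
    }
    worst <- which.max(excess)
    if (excess[worst] <= 0) break
    bad[worst] <- TRUE
  }
  which(bad)
}

#' Reconstruct rejected or missed vertebra boxes by curve fitting
#'
#' Replaces up to two unusable boxes: the center x-coordinate is taken from
#' a cubic least-squares polynomial of center x as a function of center y
#' fitted over the good boxes nearest in y to the box being rebuilt (a
#' windowed fit of the 8 closest; a single global cubic cannot follow a
#' full scoliotic arch to sub-pixel accuracy); width, height and endplate
#' tilt are linearly interpolated in y from the good boxes. The replaced
#' boxes keep their original center y and are flagged `imputed`.
#'
#' @param seq a [spine_sequence()].
#' @param bad integer indices of boxes to reconstruct (at most 2).
#' @return A [spine_sequence()] of the same length with the bad boxes
#'   replaced.
#' @export
impute_boxes <- function(seq, bad) {
  stopifnot(inherits(seq, "spine_sequence"))
  bad <- sort(unique(as.integer(bad)))
  if (length(bad) == 0L) return(seq)
  if (length(bad) > 2L)
    stop(infeasible_error(sprintf(
      "%d boxes need reconstruction; at most 2 are supported", length(bad))))
  n <- nrow(seq)
  if (any(bad < 1L | bad > n)) stop("bad indices out of range")
  good <- setdiff(seq_len(n), bad)
  if (length(good) < 5L)
    stop(infeasible_error(sprintf(
      "only %d good boxes remain; at least 5 are required", length(good))))

  cen <- vertebra_centers(seq)
  dims <- vertebra_dims(seq)
  tilt <- (edge_tilt(seq, "top") + edge_tilt(seq, "bottom")) / 2

  gy <- cen$y[good]
  new_cx <- vapply(cen$y[bad], function(y0) {
    win <- good[order(abs(gy - y0))][seq_len(min(8L, length(good)))]
    d <- data.frame(x = cen$x[win], y = cen$y[win])
    fit <- if (length(unique(d$y)) >= 4L) {
      stats::lm(x ~ stats::poly(y, 3), data = d)
    } else {
      message("centerline fit under-determined; falling back to a linear fit")
      stats::lm(x ~ y, data = d)
    }
    as.numeric(stats::predict(fit, newdata = data.frame(y = y0)))
  }, numeric(1))
  interp <- function(v) stats::approx(gy, v, xout = cen$y[bad], rule = 2)$y
  new_w <- interp(dims$width[good])
  new_h <- interp(dims$height[good])
  new_t <- interp(tilt[good]) * pi / 180

  out <- as.data.frame(seq)
  for (k in seq_along(bad)) {
    i <- bad[k]
    c0 <- c(new_cx[k], cen$y[i])
    u <- c(cos(new_t[k]), sin(new_t[k]))    # endplate direction (left->right)
    v <- c(-sin(new_t[k]), cos(new_t[k]))   # spine-axis direction (downward)
    hw <- new_w[k] / 2; hh <- new_h[k] / 2
    out[i, c("tl_x", "tl_y")] <- c0 - hh * v - hw * u
    out[i, c("tr_x", "tr_y")] <- c0 - hh * v + hw * u
    out[i, c("bl_x", "bl_y")] <- c0 + hh * v - hw * u
    out[i, c("br_x", "br_y")] <- c0 + hh * v + hw * u
    out[i, "imputed"] <- TRUE
  }
  spine_sequence(as.matrix(out[, .corner_cols]), scores = out$score,
                 image_width = attr(seq, "image_width"),
                 image_height = attr(seq, "image_height"),
                 imputed = out$imputed)
}

#' Endplate tilt of vertebra edges
#'
#' Inclination of the top or bottom edge relative to the horizontal,
#' measured from the left corner to the right corner, in degrees in
#' (-90, 90]. With image y growing downward, a positive tilt means the
#' right corner sits lower than the left (clockwise on screen).
#'
#' @param seq a [spine_sequence()].
#' @param edge `"top"` (top-left to top-right) or `"bottom"` (bottom-left to
#'   bottom-right).
#' @return Numeric vector of signed tilts in degrees, one per vertebra.
#' @export
edge_tilt <- function(seq, edge = c("top", "bottom")) {
  stopifnot(inherits(seq, "spine_sequence"))
  edge <- match.arg(edge)
  if (edge == "top") {
    dx <- seq$tr_x - seq$tl_x; dy <- seq$tr_y - seq$tl_y
  } else {
    dx <- seq$br_x - seq$bl_x; dy <- seq$br_y - seq$bl_y
  }
  if (any(dx == 0 & dy == 0))
    stop("degenerate box: coincident ", edge, " corners at row(s) ",
         paste(which(dx == 0 & dy == 0), collapse = ", "))
  ang <- atan2(dy, dx) * 180 / pi
  # fold into (-90, 90]: the edge is an undirected line
  ang[ang > 90] <- ang[ang > 90] - 180
  ang[ang <= -90] <- ang[ang <= -90] + 180
  ang
}

#' Left/right inter-vertebral gap profile
#'
#' Curvature quantification: for each adjacent pair of boxes, the left gap
#' is the Euclidean distance from the bottom-left corner of the upper box to
#' the top-left corner of the lower box, and the right gap the distance
#' between the corresponding right corners. On a curved spine the gaps open
#' on the convex side and close on the concave side.
#'
#' @param seq a [spine_sequence()] with at least 2 boxes.
#' @return An object of class `gap_profile`: list with numeric vectors
#'   `left` and `right`, each of length `nrow(seq) - 1`.
#' @export
gap_profile <- function(seq) {
  stopifnot(inherits(seq, "spine_sequence"))
  n <- nrow(seq)
  if (n < 2L) stop("gap profile needs at least 2 boxes")
  up <- seq_len(n - 1L); lo <- up + 1L
  left <- sqrt((seq$bl_x[up] - seq$tl_x[lo])^2 + (seq$bl_y[up] - seq$tl_y[lo])^2)
  right <- sqrt((seq$br_x[up] - seq$tr_x[lo])^2 + (seq$br_y[up] - seq$tr_y[lo])^2)
  structure(list(left = left, right = right), class = "gap_profile")
}

#' @export
print.gap_profile <- function(x, ...) {
  cat(sprintf("<gap_profile> %d adjacent pairs; sum left %.1f px, sum right %.1f px\n",
              length(x$left), sum(x$left), sum(x$right)))
  invisible(x)
}

#' Locate the apex of the scoliotic curve
#'
#' The apex is the most laterally placed vertebra: the box whose center has
#' the maximum perpendicular distance from the chord joining the first and
#' last box centers (ties broken toward the most superior candidate). The
#' convex side of the curve is the side with the larger summed gap profile.
#' When all centers are collinear within 1 px the spine is treated as
#' straight: the middle box is returned with `zero_curve = TRUE`.
#'
#' @param seq a [spine_sequence()] with at least 5 boxes.
#' @return List with `apex_index`, `direction` (`"left-convex"` or
#'   `"right-convex"`), `zero_curve` flag and `apex_offset_px` (the maximal
#'   perpendicular distance).
#' @export
find_apex <- function(seq) {
  stopifnot(inherits(seq, "spine_sequence"))
  n <- nrow(seq)
  if (n < 5L) stop("apex detection needs at least 5 boxes; got ", n)
  cen <- vertebra_centers(seq)
  a <- c(cen$x[1L], cen$y[1L]); b <- c(cen$x[n], cen$y[n])
  chord <- b - a
  len <- sqrt(sum(chord^2))
  if (len == 0) stop("first and last centers coincide")
  # signed cross product: positive when the center lies to one fixed side
  d <- ((cen$x - a[1L]) * chord[2L] - (cen$y - a[2L]) * chord[1L]) / len

  gp <- gap_profile(seq)
  direction <- if (sum(gp$right) >= sum(gp$left)) "right-convex" else "left-convex"

  if (max(abs(d)) < 1) {
    return(list(apex_index = (n + 1L) %/% 2L, direction = direction,
                zero_curve = TRUE, apex_offset_px = max(abs(d))))
  }
  apex <- which.max(abs(d))  # which.max takes the first (most superior) tie
  list(apex_index = apex, direction = direction, zero_curve = FALSE,
       apex_offset_px = abs(d[apex]))
}

#' Select the superior and inferior end vertebrae
#'
#' The superior end vertebra is the most tilted vertebra at or above the
#' apex, judged by the absolute tilt of its top edge; the inferior end
#' vertebra is the most tilted vertebra at or below the apex, judged by its
#' bottom edge. The apex itself is an eligible candidate on both sides.
#' Ties are broken toward the vertebra farther from the apex.
#'
#' @param seq a [spine_sequence()].
#' @param apex_index apex row index from [find_apex()].
#' @return List with `superior_index` and `inferior_index`.
#' @export
select_end_vertebrae <- function(seq, apex_index) {
  stopifnot(inherits(seq, "spine_sequence"))
  n <- nrow(seq)
  if (apex_index < 1L || apex_index > n) stop("apex index out of range")
  top <- abs(edge_tilt(seq, "top"))
  bot <- abs(edge_tilt(seq, "bottom"))
  # above: first maximum = most superior = farthest from apex
  sup <- which.max(top[seq_len(apex_index)])
  # below: last maximum = most inferior = farthest from apex
  below <- bot[apex_index:n]
  inf <- apex_index + (length(below) + 1L - which.max(rev(below))) - 1L
  list(superior_index = sup, inferior_index = inf)
}

#' Measure the Cobb angle of a scored landmark sequence
#'
#' Full measurement pipeline: score filtering ([filter_by_score()]),
#' lateral-outlier rejection ([detect_outliers()]), curve-fit
#' reconstruction of rejected boxes ([impute_boxes()]), apex location
#' ([find_apex()]) and end-vertebra selection ([select_end_vertebrae()]).
#' The Cobb angle is the absolute difference between the top-edge tilt of
#' the superior end vertebra and the bottom-edge tilt of the inferior end
#' vertebra — the angle at which the two endplate lines intersect.
#'
#' @param seq a [spine_sequence()] with raw detection scores.
#' @param score_threshold detection-score cutoff (default 0.5).
#' @param impute reconstruct outlier boxes instead of measuring without
#'   them (default `TRUE`).
#' @return An object of class `cobb_result`: list with `angle_deg`,
#'   `angle_deg_rounded` (half-away-from-zero integer), `apex_index`,
#'   `superior_index`, `inferior_index` (1-based, into the post-imputation
#'   sequence returned as `sequence`), `direction`, `tilt_sup_deg`,
#'   `tilt_inf_deg`, `zero_curve`, and a character `log` of per-stage
#'   events.
#' @examples
#' ph <- generate_phantom(phantom_config(amplitude = 100,
#'                                       corner_noise_sigma = 0, seed = 1))
#' res <- measure_cobb(ph$seq)
#' res$angle_deg_rounded
#' @export
measure_cobb <- function(seq, score_threshold = 0.5, impute = TRUE) {
  stopifnot(inherits(seq, "spine_sequence"))
  log <- sprintf("input: %d boxes", nrow(seq))

  kept <- filter_by_score(seq, score_threshold)
  log <- c(log, sprintf("score filter (> %g): %d of %d boxes retained",
                        score_threshold, nrow(kept), nrow(seq)))

  out <- detect_outliers(kept)
  if (length(out) > 0L) {
    log <- c(log, sprintf("outlier rejection: box(es) %s displaced laterally",
                          paste(out, collapse = ", ")))
    if (impute) {
      kept <- impute_boxes(kept, out)
      log <- c(log, sprintf("imputation: box(es) %s reconstructed by curve fit",
                            paste(out, collapse = ", ")))
    } else {
      kept <- subset_sequence(kept, setdiff(seq_len(nrow(kept)), out))
      log <- c(log, sprintf("outlier box(es) dropped; %d remain", nrow(kept)))
      if (nrow(kept) < 5L)
        stop(infeasible_error(sprintf(
          "only %d boxes remain after outlier removal; at least 5 required",
          nrow(kept))))
    }
  } else {
    log <- c(log, "outlier rejection: none flagged")
  }

  apex <- find_apex(kept)
  if (apex$zero_curve) {
    log <- c(log, sprintf(
      "apex: centers collinear within 1 px; straight spine, apex = middle box %d",
      apex$apex_index))
    res <- list(angle_deg = 0, angle_deg_rounded = 0L,
                apex_index = apex$apex_index,
                superior_index = apex$apex_index,
                inferior_index = apex$apex_index,
                direction = apex$direction,
                tilt_sup_deg = 0, tilt_inf_deg = 0,
                zero_curve = TRUE, log = log, sequence = kept)
    class(res) <- "cobb_result"
    return(res)
  }
  log <- c(log, sprintf("apex: box %d (%s, lateral offset %.1f px)",
                        apex$apex_index, apex$direction, apex$apex_offset_px))

  ends <- select_end_vertebrae(kept, apex$apex_index)
  ts <- edge_tilt(kept, "top")[ends$superior_index]
  ti <- edge_tilt(kept, "bottom")[ends$inferior_index]
  angle <- abs(ts - ti)
  log <- c(log, sprintf(
    "end vertebrae: superior %d (top tilt %+.2f deg), inferior %d (bottom tilt %+.2f deg)",
    ends$superior_index, ts, ends$inferior_index, ti),
    sprintf("Cobb angle: %.2f deg", angle))

  res <- list(angle_deg = angle,
              angle_deg_rounded = round_half_away(angle),
              apex_index = apex$apex_index,
              superior_index = ends$superior_index,
              inferior_index = ends$inferior_index,
              direction = apex$direction,
              tilt_sup_deg = ts, tilt_inf_deg = ti,
              zero_curve = FALSE, log = log, sequence = kept)
  class(res) <- "cobb_result"
  res
}

# round to nearest integer, halves away from zero (0.5 -> 1, -0.5 -> -1)
round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' @export
print.cobb_result <- function(x, ...) {
  cat(sprintf("<cobb_result> Cobb angle %.1f deg (rounded %d)\n",
              x$angle_deg, x$angle_deg_rounded))
  cat(sprintf("  apex %d, superior end %d, inferior end %d, %s\n",
              x$apex_index, x$superior_index, x$inferior_index, x$direction))
  if (x$zero_curve) cat("  (straight spine: no measurable curve)\n")
  invisible(x)
}
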
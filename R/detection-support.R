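#' Focal loss for keypoint heatmaps
#'
#' Penalized focal loss used to train center/corner heatmaps of keypoint
#' detectors: cells where the ground truth equals 1 contribute
#' `(1 - p)^2 * log(p)`; every other cell contributes
#' `(1 - t)^4 * p^2 * log(1 - p)`, down-weighting negatives near a peak
#' through the `(1 - t)^4` factor. The total is negated and averaged over
#' all cells. Predictions are clamped to `[1e-7, 1 - 1e-7]` so the
#' logarithms stay finite.
#'
#' @param prediction numeric matrix/array of predicted probabilities.
#' @param truth numeric matrix/array of the same shape with values in
#'   `[0, 1]`; peaks are exactly 1.
#' @param clamp numeric guard for the prediction (default `1e-7`).
#' @return Non-negative scalar loss.
#' @export
focal_loss <- function(prediction, truth, clamp = 1e-7) {
  if (!identical(dim(prediction), dim(truth)) ||
      length(prediction) != length(truth))
    stop("prediction and truth must have identical shapes")
  p <- pmin(pmax(prediction, clamp), 1 - clamp)
  pos <- truth == 1
  contrib <- numeric(length(p))
  contrib[pos] <- (1 - p[pos])^2 * log(p[pos])
  contrib[!pos] <- (1 - truth[!pos])^4 * p[!pos]^2 * log(1 - p[!pos])
  -sum(contrib) / length(p)
}

#' Mean landmark localization error
#'
#' Mean Euclidean distance between index-aligned detected and ground-truth
#' landmark sets.
#'
#' @param detected,truth numeric matrices with columns `x`, `y` (or two
#'   unnamed columns), equal row counts.
#' @return Mean distance in pixels.
#' @export
landmark_error <- function(detected, truth) {
  detected <- as.matrix(detected); truth <- as.matrix(truth)
  if (nrow(detected) != nrow(truth))
    stop("landmark sets differ in size: ", nrow(detected), " vs ", nrow(truth))
  if (nrow(detected) == 0L) stop("landmark sets are empty")
  mean(sqrt(rowSums((detected[, 1:2, drop = FALSE] -
                       truth[, 1:2, drop = FALSE])^2)))
}

#' Encode a spine sequence into center/corner offset maps
#'
#' Builds the training-target representation that [decode_boxes()] inverts:
#' a downsampled center heatmap with a Gaussian splat (sd `sigma` grid
#' cells) around each vertebra center and an exact 1 at the peak cell; a
#' 2-channel center-offset map holding the sub-cell remainder of the center
#' position (pixels) at each peak; and an 8-channel corner-offset map
#' holding each corner's displacement from the center (pixels, channel
#' order tl,tr,bl,br x then y).
#'
#' Grid cell `(r, c)` (1-based) covers pixels
#' `[(c-1)*stride, c*stride) x [(r-1)*stride, r*stride)`.
#'
#' @param seq a [spine_sequence()].
#' @param stride downsampling factor (>= 1, default 4).
#' @param sigma Gaussian splat standard deviation in grid cells (default 2).
#' @return An `offset_maps` list with `center` (matrix), `coff`
#'   (rows x cols x 2 array), `korner` (rows x cols x 8 array) and
#'   `stride`.
#' @export
encode_offset_maps <- function(seq, stride = 4, sigma = 2) {
  stopifnot(inherits(seq, "spine_sequence"), stride >= 1)
  w <- attr(seq, "image_width"); h <- attr(seq, "image_height")
  ncell_r <- as.integer(ceiling(h / stride))
  ncell_c <- as.integer(ceiling(w / stride))
  center <- matrix(0, ncell_r, ncell_c)
  coff <- array(0, c(ncell_r, ncell_c, 2))
  korner <- array(0, c(ncell_r, ncell_c, 8))

  cen <- vertebra_centers(seq)
  rows <- matrix(seq_len(ncell_r), ncell_r, ncell_c)
  cols <- matrix(seq_len(ncell_c), ncell_r, ncell_c, byrow = TRUE)
  for (i in seq_len(nrow(seq))) {
    pc <- pmin(pmax(floor(cen$x[i] / stride) + 1L, 1L), ncell_c)
    pr <- pmin(pmax(floor(cen$y[i] / stride) + 1L, 1L), ncell_r)
    d2 <- (rows - pr)^2 + (cols - pc)^2
    center <- pmax(center, exp(-d2 / (2 * sigma^2)))
    center[pr, pc] <- 1
    coff[pr, pc, ] <- c(cen$x[i] - (pc - 1L) * stride,
                        cen$y[i] - (pr - 1L) * stride)
    korner[pr, pc, ] <- c(seq$tl_x[i] - cen$x[i], seq$tl_y[i] - cen$y[i],
                          seq$tr_x[i] - cen$x[i], seq$tr_y[i] - cen$y[i],
                          seq$bl_x[i] - cen$x[i], seq$bl_y[i] - cen$y[i],
                          seq$br_x[i] - cen$x[i], seq$br_y[i] - cen$y[i])
  }
  structure(list(center = center, coff = coff, korner = korner,
                 stride = stride,
                 image_width = w, image_height = h),
            class = "offset_maps")
}

#' Decode center/corner offset maps into a spine sequence
#'
#' Finds the top-`k` local maxima of the center heatmap under 3x3
#' non-maximum suppression (a cell survives when it is at least as large
#' as all 8 neighbours), converts each peak to a center position
#' (`(cell - 1) * stride + center offset`), places the four corners at
#' `center + corner offset`, and orders the boxes by center y. The
#' heatmap value at the peak becomes the detection score.
#'
#' @param maps an `offset_maps` object (see [encode_offset_maps()]).
#' @param k maximum number of boxes to decode (default 17).
#' @return A [spine_sequence()]; when fewer than `k` peaks exist, all that
#'   were found are returned with a warning.
#' @export
decode_boxes <- function(maps, k = 17) {
  stopifnot(inherits(maps, "offset_maps"), k >= 1)
  hm <- maps$center
  nr <- nrow(hm); nc <- ncol(hm)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- hm
  is_peak <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc), drop = FALSE]
    is_peak <- is_peak & (hm >= nb)
  }
  is_peak <- is_peak & hm > 0
  peaks <- which(is_peak, arr.ind = TRUE)
  if (nrow(peaks) == 0L) stop("no peaks found in the center heatmap")
  vals <- hm[peaks]
  ord <- order(-vals, peaks[, 1L], peaks[, 2L])
  if (nrow(peaks) < k)
    warning("only ", nrow(peaks), " peak(s) found; ", k, " requested")
  take <- ord[seq_len(min(k, nrow(peaks)))]
  pr <- peaks[take, 1L]; pc <- peaks[take, 2L]

  cx <- (pc - 1L) * maps$stride + maps$coff[cbind(pr, pc, 1L)]
  cy <- (pr - 1L) * maps$stride + maps$coff[cbind(pr, pc, 2L)]
  off <- sapply(1:8, function(ch) maps$korner[cbind(pr, pc, ch)])
  off <- matrix(off, ncol = 8)
  corners <- cbind(cx + off[, 1L], cy + off[, 2L],
                   cx + off[, 3L], cy + off[, 4L],
                   cx + off[, 5L], cy + off[, 6L],
                   cx + off[, 7L], cy + off[, 8L])
  spine_sequence(corners, scores = pmin(hm[cbind(pr, pc)], 1),
                 image_width = maps$image_width,
                 image_height = maps$image_height)
}
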
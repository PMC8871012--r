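#' Local binary pattern configuration
#'
#' @param n_points number of circular sampling points (only 8 is supported
#'   by the fast 3x3 implementation).
#' @param radius neighbourhood radius in pixels (only 1 is supported).
#' @return An `lbp_config` list.
#' @export
lbp_config <- function(n_points = 8, radius = 1) {
  stopifnot(n_points >= 4, radius >= 1)
  if (n_points != 8 || radius != 1)
    stop("only the 8-point, radius-1 neighbourhood is implemented")
  structure(list(n_points = as.integer(n_points), radius = as.integer(radius)),
            class = "lbp_config")
}

# 8-neighbour offsets (row, col), clockwise starting at the top-left
# neighbour; neighbour k carries weight 2^(k-1)
.lbp_offsets <- cbind(
  dr = c(-1, -1, -1, 0, 1, 1, 1, 0),
  dc = c(-1, 0, 1, 1, 1, 0, -1, -1)
)

#' Local binary pattern code of a 3x3 patch
#'
#' Each of the eight neighbours is thresholded against the center:
#' `g(z) = 1` when `z = neighbour - center >= 0` (ties count as 1) and 0
#' otherwise, and the bits are packed with weights `2^k`, k = 0..7,
#' enumerating neighbours clockwise from the top-left. A uniform patch
#' therefore codes to 255.
#'
#' @param patch numeric 3x3 matrix of gray values (row = y, column = x).
#' @param cfg an [lbp_config()].
#' @return Integer code in 0..255.
#' @export
lbp_code <- function(patch, cfg = lbp_config()) {
  stopifnot(is.matrix(patch), all(dim(patch) == c(3L, 3L)))
  center <- patch[2L, 2L]
  bits <- vapply(1:8, function(k) {
    patch[2L + .lbp_offsets[k, 1L], 2L + .lbp_offsets[k, 2L]] >= center
  }, logical(1))
  as.integer(sum(2^(0:7) * bits))
}

# LBP codes for every pixel with a full 3x3 neighbourhood inside `img`;
# returns an (nrow-2) x (ncol-2) matrix aligned to img[2:(n-1), 2:(m-1)]
lbp_code_matrix <- function(img) {
  n <- nrow(img); m <- ncol(img)
  if (n < 3L || m < 3L) return(matrix(integer(0), 0, 0))
  center <- img[2:(n - 1), 2:(m - 1), drop = FALSE]
  codes <- matrix(0L, n - 2L, m - 2L)
  for (k in 1:8) {
    dr <- .lbp_offsets[k, 1L]; dc <- .lbp_offsets[k, 2L]
    nb <- img[(2 + dr):(n - 1 + dr), (2 + dc):(m - 1 + dc), drop = FALSE]
    codes <- codes + as.integer(2^(k - 1)) * (nb >= center)
  }
  codes
}

#' Detection window
#'
#' A rectangular sliding-window position, in pixel coordinates with the
#' top-left pixel of the image at `(1, 1)`.
#'
#' @param x,y column and row of the window's top-left pixel.
#' @param w,h window width and height in pixels.
#' @return A `detection_window` list.
#' @export
detection_window <- function(x, y, w, h) {
  stopifnot(w >= 3, h >= 3, x >= 1, y >= 1)
  structure(list(x = x, y = y, w = w, h = h), class = "detection_window")
}

#' Normalized LBP histogram of an image window
#'
#' Histogram (256 bins, L1-normalized) of [lbp_code()] over the interior
#' pixels of the window — pixels whose full 3x3 neighbourhood lies inside
#' both the window and the image. No padding is applied: when the window
#' touches the image border, the affected pixels are simply skipped.
#'
#' @param img numeric matrix (gray image, row = y).
#' @param window a [detection_window()] (or a list with `x, y, w, h`).
#' @param cfg an [lbp_config()].
#' @return Numeric vector of length 256 summing to 1.
#' @export
lbp_histogram <- function(img, window, cfg = lbp_config()) {
  stopifnot(is.matrix(img))
  rows <- max(1L, window$y):min(nrow(img), window$y + window$h - 1L)
  cols <- max(1L, window$x):min(ncol(img), window$x + window$w - 1L)
  if (length(rows) < 3L || length(cols) < 3L)
    stop("window too small after clipping: need at least 3x3 pixels")
  codes <- lbp_code_matrix(img[rows, cols, drop = FALSE])
  counts <- tabulate(codes + 1L, nbins = 256L)
  counts / sum(counts)
}

#' Boosted decision-stump classifier over LBP histograms
#'
#' A strong classifier is an ordered list of decision stumps; each stump
#' votes on a single histogram bin (`feature_index`), comparing it against
#' `threshold` with a `polarity`, and carries a weight `log(1/beta)` where
#' `beta` in (0, 1) derives from its weighted training error.
#'
#' @param weak data frame with columns `feature_index`, `threshold`,
#'   `polarity` (+1/-1) and `beta`.
#' @return A `strong_classifier` object.
#' @export
strong_classifier <- function(weak) {
  weak <- as.data.frame(weak)
  stopifnot(all(c("feature_index", "threshold", "polarity", "beta") %in%
                  names(weak)),
            nrow(weak) >= 1L,
            all(weak$beta > 0 & weak$beta < 1),
            all(weak$polarity %in% c(-1, 1)))
  structure(list(weak = weak), class = "strong_classifier")
}

#' @export
print.strong_classifier <- function(x, ...) {
  cat(sprintf("<strong_classifier> %d weak stump(s)\n", nrow(x$weak)))
  invisible(x)
}

# vote of each stump on one feature vector: 1 iff polarity * f >= polarity * thr
stump_votes <- function(features, weak) {
  f <- features[weak$feature_index]
  as.integer(weak$polarity * f >= weak$polarity * weak$threshold)
}

#' Strong-classifier decision
#'
#' Weighted-majority vote: the window is labeled positive (1) when the sum
#' of `log(1/beta)` weights of stumps voting 1 reaches half the total
#' weight, and 0 otherwise. The decision is invariant to rescaling all
#' weights by a positive constant.
#'
#' @param features numeric length-256 histogram, or a matrix with one
#'   histogram per row.
#' @param clf a [strong_classifier()] or a cascade (list of them), in
#'   which case every stage must accept.
#' @return Integer 0/1 label (vector when `features` is a matrix).
#' @export
strong_classify <- function(features, clf) {
  if (is.matrix(features))
    return(vapply(seq_len(nrow(features)),
                  function(i) strong_classify(features[i, ], clf), integer(1)))
  if (is.list(clf) && !inherits(clf, "strong_classifier")) {  # cascade
    for (stage in clf)
      if (strong_classify(features, stage) == 0L) return(0L)
    return(1L)
  }
  stopifnot(inherits(clf, "strong_classifier"))
  w <- log(1 / clf$weak$beta)
  as.integer(sum(stump_votes(features, clf$weak) * w) >= sum(w) / 2)
}

#' Train a boosted stump classifier (discrete AdaBoost)
#'
#' Each round selects the decision stump (histogram bin, threshold,
#' polarity) with minimal weighted 0/1 error over the sample, sets
#' `beta = eps / (1 - eps)` with the error clamped to
#' `[1e-10, 0.5 - 1e-10]`, multiplies the weights of correctly classified
#' samples by `beta`, and renormalizes.
#'
#' @param samples numeric matrix, one length-256 histogram per row.
#' @param labels integer 0/1 vector, one per row.
#' @param n_rounds number of boosting rounds (>= 1).
#' @return A [strong_classifier()].
#' @export
train_adaboost <- function(samples, labels, n_rounds = 10) {
  samples <- as.matrix(samples)
  labels <- as.integer(labels)
  stopifnot(nrow(samples) == length(labels), n_rounds >= 1,
            all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2L)
    stop("training needs both positive and negative samples")
  n <- nrow(samples)
  w <- rep(1 / n, n)
  weak <- vector("list", n_rounds)

  for (round in seq_len(n_rounds)) {
    best <- list(err = Inf)
    for (j in seq_len(ncol(samples))) {
      f <- samples[, j]
      ord <- order(f)
      fs <- f[ord]; ys <- labels[ord]; ws <- w[ord]
      cum1 <- cumsum(ws * ys)          # weight of positives at or below i
      cum0 <- cumsum(ws * (1 - ys))
      W1 <- cum1[n]; W0 <- cum0[n]
      # threshold after sorted position i (i = 0..n): stump with polarity +1
      # predicts 1 for f >= thr, so the first i samples are predicted 0
      pre1 <- c(0, cum1); pre0 <- c(0, cum0)
      err_p <- pre1 + (W0 - pre0)      # polarity +1 error at each cut
      valid <- c(TRUE, fs[-n] != fs[-1], TRUE)  # cuts between distinct values
      err_m <- (W1 + W0) - err_p       # polarity -1 mirrors the prediction
      cand <- pmin(err_p, err_m)
      cand[!valid] <- Inf
      i <- which.min(cand)
      if (cand[i] < best$err) {
        thr <- if (i == 1L) fs[1L] - 1 else if (i == n + 1L) fs[n] + 1
               else (fs[i - 1L] + fs[i]) / 2
        best <- list(err = cand[i], feature_index = j, threshold = thr,
                     polarity = if (err_p[i] <= err_m[i]) 1 else -1)
      }
    }
    eps <- min(max(best$err, 1e-10), 0.5 - 1e-10)
    beta <- eps / (1 - eps)
    stump <- data.frame(feature_index = best$feature_index,
                        threshold = best$threshold,
                        polarity = best$polarity, beta = beta)
    weak[[round]] <- stump
    votes <- as.integer(stump$polarity * samples[, stump$feature_index] >=
                          stump$polarity * stump$threshold)
    correct <- votes == labels
    w[correct] <- w[correct] * beta
    w <- w / sum(w)
  }
  strong_classifier(do.call(rbind, weak))
}

#' Train a rejection cascade of boosted classifiers
#'
#' Stages are trained sequentially; each later stage sees only the samples
#' that every earlier stage accepted (classic attentional cascade: cheap
#' early stages discard most negatives). Stages that run out of negatives
#' to reject end the cascade early.
#'
#' @param samples,labels as in [train_adaboost()].
#' @param n_stages number of cascade stages (default 3).
#' @param rounds_per_stage boosting rounds per stage (default 10).
#' @return List of [strong_classifier()] stages (class `cascade_classifier`).
#' @export
train_cascade <- function(samples, labels, n_stages = 3, rounds_per_stage = 10) {
  samples <- as.matrix(samples)
  labels <- as.integer(labels)
  stages <- list()
  active <- rep(TRUE, length(labels))
  for (s in seq_len(n_stages)) {
    if (length(unique(labels[active])) < 2L) break
    clf <- train_adaboost(samples[active, , drop = FALSE], labels[active],
                          rounds_per_stage)
    stages[[length(stages) + 1L]] <- clf
    pass <- strong_classify(samples[active, , drop = FALSE], clf) == 1L
    active[active] <- pass
  }
  structure(stages, class = "cascade_classifier")
}

#' Detect body windows by sliding a classifier over an image
#'
#' Scans the image with windows of the base size scaled by each entry of
#' `scales` (coarse to fine, in the given order), stepping `step` pixels in
#' row-major order (rows outer, columns inner), and classifies each
#' window's LBP histogram. Windows not fully inside the image are skipped.
#'
#' @param img numeric gray matrix.
#' @param clf a [strong_classifier()] or cascade.
#' @param window_size base window `c(width, height)` in pixels.
#' @param step stride in pixels (default 8).
#' @param scales numeric vector of window scale factors
#'   (default `c(1, 0.75, 0.5)`).
#' @return Data frame of positive windows (`x, y, w, h, scale`), possibly
#'   empty; empty with a warning when the image is smaller than the
#'   smallest window.
#' @export
sliding_window_detect <- function(img, clf, window_size, step = 8,
                                  scales = c(1, 0.75, 0.5)) {
  stopifnot(is.matrix(img), length(window_size) == 2L, step >= 1)
  codes <- lbp_code_matrix(img)  # computed once; windows histogram subsets
  hits <- list()
  any_fit <- FALSE
  for (sc in scales) {
    w <- round(window_size[1] * sc); h <- round(window_size[2] * sc)
    if (w > ncol(img) || h > nrow(img) || w < 3 || h < 3) next
    any_fit <- TRUE
    for (y in seq(1L, nrow(img) - h + 1L, by = step)) {
      for (x in seq(1L, ncol(img) - w + 1L, by = step)) {
        # interior pixels of the window in code-matrix coordinates
        rr <- max(1L, y):min(nrow(codes), y + h - 3L)
        cc <- max(1L, x):min(ncol(codes), x + w - 3L)
        counts <- tabulate(codes[rr, cc] + 1L, nbins = 256L)
        hist <- counts / sum(counts)
        if (strong_classify(hist, clf) == 1L)
          hits[[length(hits) + 1L]] <- data.frame(x = x, y = y, w = w, h = h,
                                                  scale = sc)
      }
    }
  }
  if (!any_fit)
    warning("image smaller than the minimum detection window; no scan possible")
  if (length(hits) == 0L)
    return(data.frame(x = integer(), y = integer(), w = integer(),
                      h = integer(), scale = numeric()))
  do.call(rbind, hits)
}

#' Crop the body region from detections
#'
#' Returns the union bounding box of all positive detection windows,
#' clipped to the image, together with the cropped image.
#'
#' @param img numeric gray matrix.
#' @param detections data frame from [sliding_window_detect()].
#' @return List with `image` (the cropped matrix) and `box`
#'   (`c(x, y, w, h)`).
#' @export
crop_body <- function(img, detections) {
  stopifnot(is.matrix(img))
  if (is.null(detections) || nrow(detections) == 0L)
    stop(structure(class = c("crop_failed", "error", "condition"),
                   list(message = paste("no body region detected;",
                                        "supply a manual crop region"),
                        call = sys.call())))
  x1 <- max(1L, min(detections$x))
  y1 <- max(1L, min(detections$y))
  x2 <- min(ncol(img), max(detections$x + detections$w - 1L))
  y2 <- min(nrow(img), max(detections$y + detections$h - 1L))
  list(image = img[y1:y2, x1:x2, drop = FALSE],
       box = c(x = x1, y = y1, w = x2 - x1 + 1L, h = y2 - y1 + 1L))
}
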
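#' @title Spine sequences of vertebral bounding boxes
#'
#' @description A `spine_sequence` holds the per-vertebra corner landmarks of
#' one radiograph: up to 17 vertebrae, each located by four corner points
#' (top-left, top-right, bottom-left, bottom-right) plus a detection score.
#'
#' Coordinate convention (used everywhere in this package): image pixels,
#' origin at the top-left corner, x increasing rightward, y increasing
#' downward. Vertebrae are ordered superior to inferior, i.e. by strictly
#' increasing center y. Indices are 1-based, as is usual in R.
#'
#' @details Internally the sequence is a data frame with one row per
#' vertebra and columns `tl_x, tl_y, tr_x, tr_y, bl_x, bl_y, br_x, br_y,
#' score, imputed`, carrying `image_width`/`image_height` attributes.
#' Rows are sorted by center y on construction.
#'
#' @param corners numeric matrix with 8 columns
#'   (`tl_x, tl_y, tr_x, tr_y, bl_x, bl_y, br_x, br_y`), one row per
#'   vertebra, in pixels.
#' @param scores numeric vector of per-box detection scores in `[0, 1]`;
#'   recycled from a scalar; defaults to 1.
#' @param image_width,image_height image dimensions in pixels (optional;
#'   inferred from the landmark extent when missing).
#' @param imputed logical vector flagging boxes reconstructed by
#'   [impute_boxes()] rather than detected; defaults to `FALSE`.
#' @return An object of class `spine_sequence`.
#' @seealso [measure_cobb()], [read_landmarks()], [generate_phantom()]
#' @examples
#' seq <- spine_sequence(straight_column(n = 6))
#' nrow(seq)
#' vertebra_centers(seq)
#' @export
spine_sequence <- function(corners, scores = 1, image_width = NULL,
                           image_height = NULL, imputed = FALSE) {
  corners <- as.matrix(corners)
  if (ncol(corners) != 8L)
    stop("`corners` must have 8 columns (tl_x..br_y); got ", ncol(corners))
  n <- nrow(corners)
  if (n > 17L)
    stop("a spine sequence holds at most 17 vertebrae; got ", n)
  if (!all(is.finite(corners)))
    stop("landmark coordinates must be finite")
  scores <- rep_len(as.numeric(scores), n)
  if (any(scores < 0 | scores > 1))
    stop("detection scores must lie in [0, 1]")
  imputed <- rep_len(as.logical(imputed), n)

  colnames(corners) <- .corner_cols
  df <- data.frame(corners, score = scores, imputed = imputed)

  # top edge must lie above the bottom edge (y grows downward)
  top_y <- (df$tl_y + df$tr_y) / 2
  bot_y <- (df$bl_y + df$br_y) / 2
  if (any(top_y >= bot_y))
    stop("invalid vertebra box: top edge not above bottom edge at row(s) ",
         paste(which(top_y >= bot_y), collapse = ", "))

  cy <- rowMeans(corners[, c("tl_y", "tr_y", "bl_y", "br_y"), drop = FALSE])
  df <- df[order(cy), , drop = FALSE]
  rownames(df) <- NULL

  if (is.null(image_width))  image_width  <- ceiling(max(corners[, c(1, 3, 5, 7)]))
  if (is.null(image_height)) image_height <- ceiling(max(corners[, c(2, 4, 6, 8)]))
  structure(df,
            image_width = image_width, image_height = image_height,
            class = c("spine_sequence", "data.frame"))
}

.corner_cols <- c("tl_x", "tl_y", "tr_x", "tr_y",
                  "bl_x", "bl_y", "br_x", "br_y")

#' Vertebra centers of a spine sequence
#'
#' The center of each box is the mean of its four corners.
#'
#' @param seq a [spine_sequence()].
#' @return data frame with columns `x`, `y` (pixels), one row per vertebra.
#' @export
vertebra_centers <- function(seq) {
  stopifnot(inherits(seq, "spine_sequence"))
  data.frame(
    x = rowMeans(cbind(seq$tl_x, seq$tr_x, seq$bl_x, seq$br_x)),
    y = rowMeans(cbind(seq$tl_y, seq$tr_y, seq$bl_y, seq$br_y))
  )
}

#' Vertebra widths and heights
#'
#' Width is the mean of the top and bottom edge lengths; height the mean of
#' the left and right edge lengths.
#'
#' @param seq a [spine_sequence()].
#' @return data frame with columns `width`, `height` in pixels.
#' @export
vertebra_dims <- function(seq) {
  stopifnot(inherits(seq, "spine_sequence"))
  top <- sqrt((seq$tr_x - seq$tl_x)^2 + (seq$tr_y - seq$tl_y)^2)
  bot <- sqrt((seq$br_x - seq$bl_x)^2 + (seq$br_y - seq$bl_y)^2)
  lft <- sqrt((seq$bl_x - seq$tl_x)^2 + (seq$bl_y - seq$tl_y)^2)
  rgt <- sqrt((seq$br_x - seq$tr_x)^2 + (seq$br_y - seq$tr_y)^2)
  data.frame(width = (top + bot) / 2, height = (lft + rgt) / 2)
}

# subset rows, keeping class and image-dimension attributes
subset_sequence <- function(seq, idx) {
  out <- as.data.frame(seq)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            image_width = attr(seq, "image_width"),
            image_height = attr(seq, "image_height"),
            class = c("spine_sequence", "data.frame"))
}

#' @export
print.spine_sequence <- function(x, ...) {
  cen <- vertebra_centers(x)
  cat(sprintf("<spine_sequence> %d vertebrae, image %s x %s px\n",
              nrow(x), attr(x, "image_width"), attr(x, "image_height")))
  cat(sprintf("  center y: %.1f .. %.1f; scores %.2f .. %.2f; %d imputed\n",
              min(cen$y), max(cen$y), min(x$score), max(x$score),
              sum(x$imputed)))
  invisible(x)
}

#' Axis-aligned straight test column of vertebrae
#'
#' Convenience constructor for a perfectly straight, vertical column of
#' identical axis-aligned boxes, useful in examples and tests.
#'
#' @param n number of vertebrae.
#' @param width,height box dimensions in pixels.
#' @param spacing vertical center-to-center distance in pixels.
#' @param x0,y0 center of the first (most superior) box.
#' @param score detection score applied to every box.
#' @return A [spine_sequence()].
#' @export
straight_column <- function(n = 17, width = 40, height = 24, spacing = 34,
                            x0 = 100, y0 = 50, score = 1) {
  cy <- y0 + spacing * (seq_len(n) - 1)
  cbindv <- function(...) cbind(...)
  corners <- cbindv(
    tl_x = x0 - width / 2, tl_y = cy - height / 2,
    tr_x = x0 + width / 2, tr_y = cy - height / 2,
    bl_x = x0 - width / 2, bl_y = cy + height / 2,
    br_x = x0 + width / 2, br_y = cy + height / 2
  )
  spine_sequence(corners, scores = score,
                 image_width = 2 * x0, image_height = max(cy) + height)
}

# error constructor for "not enough usable vertebrae" conditions
infeasible_error <- function(msg) {
  structure(class = c("cobb_infeasible", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
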
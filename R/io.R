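#' Read vertebral landmarks from JSON or CSV
#'
#' JSON schema: `{"image": name, "width": int, "height": int, "vertebrae":
#' [{"score": float, "corners": {"tl": [x,y], "tr": [x,y], "bl": [x,y],
#' "br": [x,y]}}, ...]}`, vertebrae listed superior to inferior. CSV
#' dialect: header `vertebra,corner,x,y,score`, one row per corner with
#' `corner` in tl/tr/bl/br; lines starting with `#` are comments. Boxes
#' are re-sorted by center y regardless of file order; a missing score
#' defaults to 1.
#'
#' @param path file path ending in `.json` or `.csv`.
#' @return A [spine_sequence()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = read_landmarks_json(path),
         csv = read_landmarks_csv(path),
         stop("unsupported landmark format '.", ext, "' (use .json or .csv)"))
}

read_landmarks_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(doc$vertebrae) || length(doc$vertebrae) == 0L)
    stop("landmark JSON has no 'vertebrae' field: ", path)
  corners <- matrix(NA_real_, length(doc$vertebrae), 8,
                    dimnames = list(NULL, .corner_cols))
  scores <- numeric(length(doc$vertebrae))
  for (i in seq_along(doc$vertebrae)) {
    v <- doc$vertebrae[[i]]
    for (nm in c("tl", "tr", "bl", "br")) {
      pt <- v$corners[[nm]]
      if (is.null(pt) || length(pt) != 2L)
        stop("vertebra ", i, ": corner '", nm, "' missing or not [x, y]")
      corners[i, paste0(nm, c("_x", "_y"))] <- as.numeric(pt)
    }
    scores[i] <- if (is.null(v$score)) 1 else as.numeric(v$score)
  }
  spine_sequence(corners, scores = scores,
                 image_width = if (is.null(doc$width)) NULL else doc$width,
                 image_height = if (is.null(doc$height)) NULL else doc$height)
}

read_landmarks_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop("malformed CSV in ", path, ": ",
                             conditionMessage(e)))
  need <- c("vertebra", "corner", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("landmark CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (!"score" %in% names(df)) df$score <- 1
  if (!all(df$corner %in% c("tl", "tr", "bl", "br")))
    stop("corner labels must be tl/tr/bl/br; offending row(s): ",
         paste(utils::head(which(!df$corner %in% c("tl", "tr", "bl", "br"))),
               collapse = ", "))
  if (any(duplicated(df[c("vertebra", "corner")])))
    stop("duplicated vertebra/corner rows in ", path)
  ids <- sort(unique(df$vertebra))
  corners <- matrix(NA_real_, length(ids), 8,
                    dimnames = list(NULL, .corner_cols))
  scores <- numeric(length(ids))
  for (i in seq_along(ids)) {
    sub <- df[df$vertebra == ids[i], ]
    if (nrow(sub) != 4L)
      stop("vertebra ", ids[i], " has ", nrow(sub), " corner rows; expected 4")
    for (nm in c("tl", "tr", "bl", "br")) {
      row <- sub[sub$corner == nm, ]
      corners[i, paste0(nm, c("_x", "_y"))] <- c(row$x, row$y)
    }
    scores[i] <- sub$score[1L]
  }
  spine_sequence(corners, scores = scores)
}

.convention <- paste("pixels, origin top-left, x rightward, y downward,",
                     "1-based indices, vertebrae superior to inferior")

#' Write vertebral landmarks to JSON or CSV
#'
#' Inverse of [read_landmarks()]. Every output carries a header declaring
#' the coordinate convention so files are self-describing.
#'
#' @param seq a [spine_sequence()].
#' @param path output path ending in `.json` or `.csv`.
#' @param image image name recorded in the JSON form.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(seq, path, image = basename(path)) {
  stopifnot(inherits(seq, "spine_sequence"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    vert <- lapply(seq_len(nrow(seq)), function(i) list(
      score = seq$score[i],
      corners = list(tl = c(seq$tl_x[i], seq$tl_y[i]),
                     tr = c(seq$tr_x[i], seq$tr_y[i]),
                     bl = c(seq$bl_x[i], seq$bl_y[i]),
                     br = c(seq$br_x[i], seq$br_y[i]))))
    jsonlite::write_json(
      list(image = image, convention = .convention,
           width = attr(seq, "image_width"),
           height = attr(seq, "image_height"), vertebrae = vert),
      path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    rows <- do.call(rbind, lapply(seq_len(nrow(seq)), function(i) {
      data.frame(vertebra = i, corner = c("tl", "tr", "bl", "br"),
                 x = c(seq$tl_x[i], seq$tr_x[i], seq$bl_x[i], seq$br_x[i]),
                 y = c(seq$tl_y[i], seq$tr_y[i], seq$bl_y[i], seq$br_y[i]),
                 score = seq$score[i])
    }))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("# coordinates:", .convention), con)
    utils::write.csv(rows, con, row.names = FALSE)
  } else stop("unsupported landmark format '.", ext, "'")
  invisible(path)
}

#' Run configuration for the measurement pipeline
#'
#' @param score_threshold detection-score cutoff (default 0.5).
#' @param tolerance_deg observer-agreement band in degrees (default 5).
#' @param imputation_max maximum boxes reconstructed by curve fitting
#'   (0..2; the reconstruction claim covers one or two failed vertebrae).
#' @param seed integer seed routed to every stochastic component.
#' @param verbosity 0 = quiet, 1 = stage log.
#' @return A `run_config` list.
#' @export
run_config <- function(score_threshold = 0.5, tolerance_deg = 5,
                       imputation_max = 2, seed = 1L, verbosity = 1L) {
  stopifnot(score_threshold >= 0, score_threshold <= 1,
            imputation_max >= 0, imputation_max <= 2, tolerance_deg > 0)
  structure(list(score_threshold = score_threshold,
                 tolerance_deg = tolerance_deg,
                 imputation_max = as.integer(imputation_max),
                 seed = as.integer(seed), verbosity = as.integer(verbosity)),
            class = "run_config")
}

#' Measure a landmark file and build a serializable report
#'
#' @param input path to a landmark JSON/CSV file, or a [spine_sequence()].
#' @param config a [run_config()].
#' @param name input name recorded in the report (defaults to the path).
#' @return A `measurement_report` list: input name, the Cobb result fields
#'   (angle to one decimal plus the rounded integer), the per-stage log,
#'   the configuration echo, and the package version.
#' @export
measure_report <- function(input, config = run_config(), name = NULL) {
  seq <- if (inherits(input, "spine_sequence")) input else read_landmarks(input)
  if (is.null(name))
    name <- if (is.character(input)) basename(input) else "<in-memory>"
  res <- measure_cobb(seq, score_threshold = config$score_threshold)
  structure(list(
    input = name,
    convention = .convention,
    angle_deg = round(res$angle_deg, 1),
    angle_deg_rounded = res$angle_deg_rounded,
    apex_index = res$apex_index,
    superior_index = res$superior_index,
    inferior_index = res$inferior_index,
    direction = res$direction,
    tilt_sup_deg = round(res$tilt_sup_deg, 1),
    tilt_inf_deg = round(res$tilt_inf_deg, 1),
    zero_curve = res$zero_curve,
    log = res$log,
    config = unclass(config),
    version = as.character(utils::packageVersion("cobbangle"))),
    class = "measurement_report")
}

#' Serialize a measurement report to JSON
#'
#' @param report a [measure_report()] result.
#' @param path output path, or `NULL` to return the JSON string.
#' @return The path (invisibly) or the JSON string.
#' @export
write_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "measurement_report"))
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' Save / load a trained classifier as JSON
#'
#' Serializes a [strong_classifier()] or a cascade (list of them) as a
#' JSON array of stages, each an array of stumps with
#' `feature_index/threshold/polarity/beta`.
#'
#' @param clf classifier to save.
#' @param path JSON file path.
#' @return `write_classifier`: the path, invisibly. `read_classifier`: the
#'   classifier (a `cascade_classifier` list; single-stage files load as a
#'   one-stage cascade).
#' @export
write_classifier <- function(clf, path) {
  stages <- if (inherits(clf, "strong_classifier")) list(clf) else clf
  jsonlite::write_json(lapply(stages, function(s) s$weak), path,
                       dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(doc)) doc <- list(doc)
  structure(lapply(doc, strong_classifier), class = "cascade_classifier")
}

#' Read / write 8-bit grayscale images
#'
#' PNG images are read with the png package and converted to a gray
#' matrix on the 0..255 scale (color inputs by the Rec. 601 luminance).
#'
#' @param path PNG file path.
#' @param img numeric matrix on the 0..255 scale.
#' @return `read_gray_image`: numeric matrix (row = y). `write_gray_image`:
#'   the path, invisibly.
#' @export
read_gray_image <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L)
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    else arr <- arr[, , 1]
  }
  arr * 255
}

#' @rdname read_gray_image
#' @export
write_gray_image <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}
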
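#' Percentage accuracy of a Cobb measurement against a reference
#'
#' `100 - 100 * |ref - test| / ref`: 100 for perfect agreement, decreasing
#' by the relative absolute error; not clipped, so it goes negative when
#' the discrepancy exceeds the reference itself.
#'
#' @param ref reference measurement(s) in degrees (> 0).
#' @param test comparison measurement(s) in degrees.
#' @return Numeric vector of percentages.
#' @examples
#' percentage_accuracy(9, 11)  # 77.8 to one decimal
#' @export
percentage_accuracy <- function(ref, test) {
  if (any(ref == 0))
    stop("percentage accuracy is undefined for a zero reference angle")
  100 - 100 * abs(ref - test) / ref
}

#' Load the packaged 70-image observer-agreement fixture
#'
#' Seventy anterior-posterior radiographs measured independently by two
#' clinical observers (Observer 1, a scoliosis specialist, is the
#' reference) and by the automated method ("acamm", automated Cobb angle
#' measurement method), stratified by reference severity. Only the raw
#' integer Cobb angles are stored; accuracies, differences and
#' within-tolerance flags are always recomputed.
#'
#' @param path CSV path; defaults to the copy shipped in `extdata`.
#' @return Data frame of class `measurement_records` with columns
#'   `image_id`, `obs1`, `obs2`, `acamm`, `stratum`
#'   (`"<10"`, `"10-25"`, `">25-40"`, `">40"` degrees).
#' @export
load_fixture_records <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tables_1_4.csv", package = "cobbangle",
                        mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "obs1", "obs2", "acamm", "stratum")
  if (!all(need %in% names(df)))
    stop("fixture is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[order(df$image_id), need]
  # packaging integrity: row count, per-stratum counts and column checksums
  ok <- nrow(df) == 70L &&
    identical(as.integer(table(factor(df$stratum,
                                      c("<10", "10-25", ">25-40", ">40")))),
              c(6L, 19L, 15L, 30L)) &&
    sum(df$obs1) == 2519L && sum(df$obs2) == 2222L && sum(df$acamm) == 2495L
  if (!ok) stop("fixture checksum mismatch: tables_1_4.csv is corrupted")
  lo <- c("<10" = 0, "10-25" = 10, ">25-40" = 25, ">40" = 40)
  hi <- c("<10" = 10, "10-25" = 25, ">25-40" = 40, ">40" = Inf)
  bad <- df$obs1 <= lo[df$stratum] - 1e-9 | df$obs1 < lo[df$stratum] |
    df$obs1 > hi[df$stratum] |
    (df$stratum == "<10" & df$obs1 >= 10) |
    (df$stratum == ">25-40" & df$obs1 <= 25)
  if (any(bad))
    stop("stratum inconsistent with the reference angle at image_id ",
         paste(df$image_id[bad], collapse = ", "))
  structure(df, class = c("measurement_records", "data.frame"))
}

#' Summarize agreement of a comparator against Observer 1
#'
#' Per-record percentage accuracy ([percentage_accuracy()]) and signed
#' difference (comparator minus Observer 1), reduced to the median and
#' interquartile range (quartiles by linear interpolation between order
#' statistics) plus the count of records within the +/- tolerance.
#'
#' @param records a [load_fixture_records()]-style data frame.
#' @param comparator `"acamm"` (the automated method) or `"obs2"`.
#' @param tolerance agreement band in degrees (default 5).
#' @return An `agreement_summary` list with `median_accuracy`,
#'   `accuracy_iqr` (length 2), `median_diff`, `diff_iqr`, `n_within`,
#'   `n_total`, `comparator`.
#' @export
summarize_agreement <- function(records, comparator = c("acamm", "obs2"),
                                tolerance = 5) {
  comparator <- match.arg(comparator)
  if (nrow(records) == 0L) stop("no records to summarize")
  test <- records[[comparator]]
  acc <- percentage_accuracy(records$obs1, test)
  diff <- test - records$obs1
  structure(list(
    median_accuracy = stats::median(acc),
    accuracy_iqr = unname(stats::quantile(acc, c(0.25, 0.75))),
    median_diff = stats::median(diff),
    diff_iqr = unname(stats::quantile(diff, c(0.25, 0.75))),
    n_within = sum(abs(diff) <= tolerance),
    n_total = nrow(records),
    comparator = comparator, tolerance = tolerance),
    class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> %s vs obs1 (n = %d)\n", x$comparator,
              x$n_total))
  cat(sprintf("  median accuracy %.1f%% (IQR %.1f to %.1f)\n",
              x$median_accuracy, x$accuracy_iqr[1], x$accuracy_iqr[2]))
  cat(sprintf("  median difference %+.1f deg (IQR %+.1f to %+.1f)\n",
              x$median_diff, x$diff_iqr[1], x$diff_iqr[2]))
  cat(sprintf("  within +/-%g deg: %d/%d (%.1f%%)\n", x$tolerance,
              x$n_within, x$n_total, 100 * x$n_within / x$n_total))
  invisible(x)
}

#' Full agreement table (overall and per severity stratum)
#'
#' @param records a [load_fixture_records()]-style data frame.
#' @param tolerance agreement band in degrees (default 5).
#' @return Data frame with one row per (block, comparator): median
#'   accuracy/IQR, median difference/IQR and within-tolerance counts.
#' @export
agreement_table <- function(records, tolerance = 5) {
  blocks <- c("overall", "<10", "10-25", ">25-40", ">40")
  rows <- list()
  for (b in blocks) {
    sub <- if (b == "overall") records else records[records$stratum == b, ]
    for (comp in c("acamm", "obs2")) {
      s <- summarize_agreement(sub, comp, tolerance)
      rows[[length(rows) + 1L]] <- data.frame(
        block = b, comparator = comp,
        median_accuracy = s$median_accuracy,
        acc_q1 = s$accuracy_iqr[1], acc_q3 = s$accuracy_iqr[2],
        median_diff = s$median_diff,
        diff_q1 = s$diff_iqr[1], diff_q3 = s$diff_iqr[2],
        n_within = s$n_within, n_total = s$n_total)
    }
  }
  do.call(rbind, rows)
}

#' Intraclass correlation coefficient (two-way random, absolute agreement)
#'
#' Computed from the two-way ANOVA mean squares of the n x 2 rating
#' matrix. The default single-measures form ICC(2,1) rates the reliability
#' of one rating; the average-measures form ICC(2,k) rates the mean of the
#' k ratings and is what several statistics packages print by default.
#'
#' @param a,b numeric rating vectors of equal length (>= 3), e.g. two
#'   observers' Cobb angles over the same images.
#' @param type `"single"` for ICC(2,1) (default) or `"average"` for
#'   ICC(2,k).
#' @return ICC estimate in `(-1, 1]`.
#' @export
icc <- function(a, b, type = c("single", "average")) {
  type <- match.arg(type)
  stopifnot(length(a) == length(b), length(a) >= 3)
  X <- cbind(as.numeric(a), as.numeric(b))
  if (stats::var(X[, 1]) == 0 && stats::var(X[, 2]) == 0)
    stop("ICC undefined: both ratings have zero variance")
  n <- nrow(X); k <- ncol(X)
  gm <- mean(X)
  row_m <- rowMeans(X); col_m <- colMeans(X)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sse <- sum((X - gm)^2) - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  if (type == "single")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (msc - mse) / n)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] with the degenerate-input checks the
#' agreement pipeline needs; the two-sided test p-value from
#' [stats::cor.test()] is attached as attribute `p_value`.
#'
#' @param a,b numeric vectors of equal length (>= 3), nonzero variance.
#' @return Correlation coefficient with attribute `p_value`.
#' @export
pearson <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("correlation undefined for zero-variance input")
  r <- stats::cor(a, b)
  attr(r, "p_value") <- stats::cor.test(a, b)$p.value
  r
}

#' Reliability table across all observer pairs
#'
#' @param records a [load_fixture_records()]-style data frame.
#' @return Data frame with one row per pair: ICC(2,1), ICC(2,k) and
#'   Pearson r with its p-value.
#' @export
reliability_table <- function(records) {
  pairs <- list(c("obs1", "obs2"), c("obs1", "acamm"), c("obs2", "acamm"))
  do.call(rbind, lapply(pairs, function(p) {
    a <- records[[p[1]]]; b <- records[[p[2]]]
    r <- pearson(a, b)
    data.frame(pair = paste(p, collapse = "-"),
               icc_single = icc(a, b, "single"),
               icc_average = icc(a, b, "average"),
               pcc = as.numeric(r), pcc_p = attr(r, "p_value"))
  }))
}

#' Two-group comparison tests
#'
#' Two-sided Mann-Whitney U (normal approximation with tie correction, no
#' continuity correction) for non-normally distributed measurements, or a
#' chi-square test of independence on a 2x2 count table (no Yates
#' correction).
#'
#' @param x,y for `"mann_whitney"`: the two samples. For `"chi_square"`:
#'   `x` is a 2x2 count matrix/table and `y` is ignored.
#' @param kind `"mann_whitney"` or `"chi_square"`.
#' @return List with `statistic` and `p_value`.
#' @export
compare_groups <- function(x, y = NULL, kind = c("mann_whitney", "chi_square")) {
  kind <- match.arg(kind)
  if (kind == "mann_whitney") {
    ht <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    tab <- as.matrix(x)
    if (!all(dim(tab) == c(2L, 2L))) stop("chi-square expects a 2x2 table")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop("degenerate table: zero row or column margin")
    ht <- stats::chisq.test(tab, correct = FALSE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value)
  }
}
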
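test_that("LBP codes follow the clockwise-from-top-left bit packing", {
  expect_equal(lbp_code(matrix(7, 3, 3)), 255L)  # ties count as 1
  hi_center <- matrix(1, 3, 3); hi_center[2, 2] <- 9
  expect_equal(lbp_code(hi_center), 0L)

  # oracle: explicit 8-term sum with its own neighbour list
  oracle <- function(p) {
    nb <- c(p[1, 1], p[1, 2], p[1, 3], p[2, 3],
            p[3, 3], p[3, 2], p[3, 1], p[2, 1])
    sum(2^(0:7) * (nb >= p[2, 2]))
  }
  p <- matrix(c(10, 40, 70, 20, 25, 80, 30, 60, 90), 3, 3)  # column-major
  expect_equal(lbp_code(p), oracle(p))

  set.seed(1)
  for (i in 1:1000) {
    p <- matrix(sample(0:255, 9, replace = TRUE), 3, 3)
    expect_identical(lbp_code(p), as.integer(oracle(p)))
  }
})

test_that("window histograms are normalized and match a brute-force loop", {
  const <- matrix(128, 12, 12)
  h <- lbp_histogram(const, detection_window(1, 1, 12, 12))
  expect_equal(h[256], 1)  # all codes 255 -> last bin
  expect_equal(sum(h), 1, tolerance = 1e-9)

  set.seed(7)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  win <- detection_window(3, 2, 15, 17)
  h <- lbp_histogram(img, win)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  # oracle: naive double loop over the window's interior pixels
  counts <- numeric(256)
  for (r in (win$y + 1):(win$y + win$h - 2))
    for (c in (win$x + 1):(win$x + win$w - 2)) {
      code <- lbp_code(img[(r - 1):(r + 1), (c - 1):(c + 1)])
      counts[code + 1] <- counts[code + 1] + 1
    }
  expect_equal(h, counts / sum(counts))

  # codes depend only on the sign of differences: strictly monotone
  # gray-level relabeling leaves every histogram unchanged
  img2 <- (img + 1)^2 / 4
  expect_equal(lbp_histogram(img2, win), h)
})

test_that("the strong classifier applies the weighted-majority rule", {
  one <- strong_classifier(data.frame(feature_index = 1, threshold = 0.3,
                                      polarity = 1, beta = 0.2))
  f <- numeric(256)
  f[1] <- 0.5
  expect_equal(strong_classify(f, one), 1L)   # single stump voting 1
  f[1] <- 0.1
  expect_equal(strong_classify(f, one), 0L)   # all stumps voting 0

  # three stumps, beta (0.1, 0.3, 0.5), votes (1, 0, 1):
  # weights log(10), log(10/3), log(2); 2.303 + 0.693 >= 2.100 -> 1
  clf <- strong_classifier(data.frame(feature_index = 1:3,
                                      threshold = c(0.4, 0.2, 0.4),
                                      polarity = 1, beta = c(0.1, 0.3, 0.5)))
  f <- numeric(256); f[1:3] <- c(0.5, 0.1, 0.5)
  w <- log(1 / c(0.1, 0.3, 0.5))
  expect_equal(sum(w[c(1, 3)]) >= sum(w) / 2, TRUE)
  expect_equal(strong_classify(f, clf), 1L)
  # votes (0, 1, 0): 1.204 < 2.100 -> 0
  f[1:3] <- c(0.1, 0.5, 0.1)
  expect_equal(strong_classify(f, clf), 0L)

  # decision invariant to rescaling all log(1/beta) weights: beta^c scales
  # every weight by c
  clf2 <- strong_classifier(transform(clf$weak, beta = beta^1.7))
  set.seed(5)
  for (i in 1:50) {
    f <- numeric(256); f[1:3] <- runif(3)
    expect_identical(strong_classify(f, clf), strong_classify(f, clf2))
  }
})

test_that("boosting drives training error down and fits separable data", {
  set.seed(11)
  n <- 60
  labels <- rep(0:1, each = n / 2)
  samples <- matrix(runif(n * 256, 0, 0.002), n, 256)
  samples[, 10] <- ifelse(labels == 1, runif(n, 0.6, 1), runif(n, 0, 0.4))
  clf <- train_adaboost(samples, labels, n_rounds = 1)
  expect_equal(strong_classify(samples, clf), labels)  # perfect stump

  # training error trends down over rounds on this fixed sample, and the
  # exponential bound prod 2*sqrt(eps(1-eps)) shrinks every round
  set.seed(21)
  hard <- matrix(runif(n * 256), n, 256)
  hard[, 5] <- hard[, 5] + 0.35 * labels   # weak signal
  clf <- train_adaboost(hard, labels, n_rounds = 8)
  errs <- vapply(1:8, function(k) {
    partial <- strong_classifier(clf$weak[1:k, ])
    mean(strong_classify(hard, partial) != labels)
  }, numeric(1))
  expect_lte(errs[8], errs[1])
  expect_lte(errs[8], 0.05)
  eps <- clf$weak$beta / (1 + clf$weak$beta)
  expect_true(all(eps < 0.5))
  expect_true(all(diff(cumprod(2 * sqrt(eps * (1 - eps)))) < 0))

  # labels independent of the features: stumps cannot memorize much
  set.seed(31)
  noise <- matrix(runif(200 * 256), 200, 256)
  rand_labels <- sample(0:1, 200, replace = TRUE)
  clf <- train_adaboost(noise, rand_labels, n_rounds = 5)
  expect_lte(mean(strong_classify(noise, clf) == rand_labels), 0.75)

  expect_error(train_adaboost(noise, rep(1L, 200), 3), "both positive")
})

# shared scene for the detection tests: a textured torso band (vertebra
# quads rendered by the phantom generator) pasted into a wider noisy
# background canvas, leaving true background room on both sides
make_scene <- function(seed = 1, shift_x = 0) {
  ph <- generate_phantom(phantom_config(
    amplitude = 20, corner_noise_sigma = 0, image_width = 300,
    image_height = 400, arch_top = 60, arch_len = 300,
    vertebra_width = c(40, 52), vertebra_height = 14, seed = seed))
  patch <- render_image(ph, width = 300, height = 400, noise = 4, seed = seed)
  set.seed(seed + 5000)
  canvas <- matrix(40, 400, 600) + matrix(rnorm(400 * 600, sd = 4), 400, 600)
  canvas[, (151 + shift_x):(450 + shift_x)] <- patch
  canvas
}

# the painted torso region inside the default canvas (paste offset 150)
torso_box <- c(x = 210, y = 20, w = 181, h = 381)

window_samples <- function(img, n_pos = 12, n_neg = 12, seed = 2,
                           noise_canvas = NULL) {
  set.seed(seed)
  w <- 180; h <- 380
  pos <- t(replicate(n_pos, c(torso_box[["x"]] + sample(-8:8, 1),
                              max(1, torso_box[["y"]] + sample(-12:0, 1)))))
  neg <- t(replicate(n_neg, c(sample(c(1:25, 400:420), 1), sample(1:20, 1))))
  feats <- rbind(
    t(apply(rbind(pos, neg), 1, function(p)
      lbp_histogram(img, detection_window(p[1], p[2], w, h)))))
  labels <- rep(1:0, c(n_pos, n_neg))
  if (!is.null(noise_canvas)) {  # plain-background negatives
    nn <- t(replicate(n_neg, c(sample(1:420, 1), sample(1:20, 1))))
    feats <- rbind(feats, t(apply(nn, 1, function(p)
      lbp_histogram(noise_canvas, detection_window(p[1], p[2], w, h)))))
    labels <- c(labels, rep(0L, n_neg))
  }
  list(features = feats, labels = labels)
}

test_that("a trained cascade finds the torso and supports cropping", {
  img <- make_scene(seed = 1)
  set.seed(777)
  noise_canvas <- matrix(40, 400, 600) +
    matrix(rnorm(400 * 600, sd = 4), 400, 600)
  tr <- window_samples(img, seed = 2, noise_canvas = noise_canvas)
  clf <- train_cascade(tr$features, tr$labels, n_stages = 2,
                       rounds_per_stage = 8)
  # held-out windows from an independently seeded scene
  te <- window_samples(make_scene(seed = 9), seed = 14)
  expect_gte(mean(strong_classify(te$features, clf) == te$labels), 0.9)

  # blank image: nothing to detect
  set.seed(3)
  blank <- matrix(40, 400, 600) + matrix(rnorm(400 * 600, sd = 4), 400, 600)
  expect_equal(nrow(sliding_window_detect(blank, clf, c(180, 380),
                                          step = 20, scales = 1)), 0L)
  expect_error(crop_body(blank, data.frame()), class = "crop_failed")

  det <- sliding_window_detect(img, clf, c(180, 380), step = 20, scales = 1)
  expect_gt(nrow(det), 0)
  iou <- function(a, b) {
    ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    inter / (a[3] * a[4] + b[3] * b[4] - inter)
  }
  ious <- apply(det, 1, function(d)
    iou(c(d[["x"]], d[["y"]], d[["w"]], d[["h"]]),
        unname(torso_box)))
  expect_gte(max(ious), 0.5)

  crop <- crop_body(img, det)
  expect_equal(unname(crop$box[["w"]]), ncol(crop$image))
  # union crop covers nearly all of the torso region
  ib <- crop$box
  ix <- max(0, min(ib[["x"]] + ib[["w"]], torso_box[["x"]] + torso_box[["w"]]) -
              max(ib[["x"]], torso_box[["x"]]))
  iy <- max(0, min(ib[["y"]] + ib[["h"]], torso_box[["y"]] + torso_box[["h"]]) -
              max(ib[["y"]], torso_box[["y"]]))
  expect_gte(ix * iy / (torso_box[["w"]] * torso_box[["h"]]), 0.95)

  # translation: shifting the scene right moves the detections with it
  det2 <- sliding_window_detect(make_scene(seed = 1, shift_x = 20), clf,
                                c(180, 380), step = 20, scales = 1)
  expect_gt(nrow(det2), 0)
  expect_lte(abs((min(det2$x) - min(det$x)) - 20), 20)

  # single detection crops exactly that window; two overlap to their union
  one <- data.frame(x = 10, y = 12, w = 30, h = 40)
  expect_equal(unname(crop_body(img, one)$box), c(10, 12, 30, 40))
  two <- rbind(one, data.frame(x = 25, y = 30, w = 30, h = 40))
  expect_equal(unname(crop_body(img, two)$box), c(10, 12, 45, 58))
})

test_that("classifier JSON round trips through disk", {
  clf <- strong_classifier(data.frame(feature_index = c(3L, 200L),
                                      threshold = c(0.25, 0.0125),
                                      polarity = c(1, -1),
                                      beta = c(0.31, 0.07)))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_classifier(clf, path)
  back <- read_classifier(path)
  expect_length(back, 1L)
  expect_equal(back[[1]]$weak, clf$weak)
  cas <- structure(list(clf, clf), class = "cascade_classifier")
  write_classifier(cas, path)
  expect_length(read_classifier(path), 2L)
})
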
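test_that("score filtering keeps exactly the boxes above threshold", {
  s <- straight_column(17)
  expect_equal(nrow(filter_by_score(s, 0.5)), 17L)

  scores <- rep(0.9, 17); scores[c(4, 11)] <- 0.4
  s2 <- spine_sequence(seq_corner_matrix(s), scores = scores)
  kept <- filter_by_score(s2, 0.5)
  expect_equal(nrow(kept), 15L)
  expect_true(all(diff(vertebra_centers(kept)$y) > 0))

  set.seed(42)
  scores <- runif(17)
  s3 <- spine_sequence(seq_corner_matrix(s), scores = scores)
  if (sum(scores > 0.5) >= 5) {
    kept <- filter_by_score(s3, 0.5)
    # oracle: independent per-box comparison
    expect_equal(kept$score, scores[order(vertebra_centers(s)$y)][
      scores[order(vertebra_centers(s)$y)] > 0.5])
    expect_equal(nrow(kept), sum(scores > 0.5))
  }
  expect_error(filter_by_score(straight_column(6, score = 0.3), 0.5),
               class = "cobb_infeasible")
  expect_error(filter_by_score(straight_column(6, score = 0.3), 0.5),
               "only 0 box")
})

test_that("lateral outliers are flagged exactly at half the box width", {
  s <- straight_column(17)
  expect_identical(detect_outliers(s), integer(0))

  shift_box <- function(s, i, dx) {
    m <- seq_corner_matrix(s)
    m[i, c(1, 3, 5, 7)] <- m[i, c(1, 3, 5, 7)] + dx
    rebuild_sequence(s, m)
  }
  expect_identical(detect_outliers(shift_box(s, 9, 2 * 40)), 9L)
  # boundary of the rule: width 40, threshold at half width = 20 px
  expect_identical(detect_outliers(shift_box(s, 9, 0.51 * 40)), 9L)
  expect_identical(detect_outliers(shift_box(s, 9, 0.49 * 40)), integer(0))
  # first/last boxes compare against their single neighbour
  expect_identical(detect_outliers(shift_box(s, 1, 0.51 * 40)), 1L)
  expect_identical(detect_outliers(shift_box(s, 17, 30)), 17L)
})

test_that("curve-fit imputation reconstructs boxes on the centerline", {
  # default-amplitude phantom: a moderate single arch
  ph <- generate_phantom(phantom_config(corner_noise_sigma = 0, seed = 5))
  expect_identical(impute_boxes(ph$seq, integer(0)), ph$seq)

  imp <- impute_boxes(ph$seq, 8L)
  expect_true(imp$imputed[8])
  expect_equal(sum(imp$imputed), 1L)
  cfg <- ph$config
  cen <- vertebra_centers(imp)
  truth_x <- cfg$image_width / 2 + cfg$amplitude *
    sin(pi * (cen$y[8] - cfg$arch_top) / cfg$arch_len)
  expect_lt(abs(cen$x[8] - truth_x), 1)

  # two reconstructed boxes perturb the measured angle by < 2 degrees
  ph2 <- phantom_for_angle(35, seed = 5, noise = 0)
  intact <- measure_cobb(ph2$seq)
  imp2 <- impute_boxes(ph2$seq, c(5L, 12L))
  expect_lt(abs(measure_cobb(imp2)$angle_deg - intact$angle_deg), 2)

  expect_error(impute_boxes(ph$seq, c(3L, 7L, 11L)), class = "cobb_infeasible")
})

test_that("edge tilt is the signed inclination of the endplate", {
  flat <- straight_column(5)
  expect_equal(edge_tilt(flat, "top"), rep(0, 5))
  expect_equal(edge_tilt(flat, "bottom"), rep(0, 5))

  mk <- function(tl, tr) {
    # one box with prescribed top corners and a deep parallel bottom edge
    spine_sequence(rbind(c(tl, tr, tl + c(0, 60), tr + c(0, 60))))
  }
  expect_equal(edge_tilt(mk(c(0, 0), c(10, 10)), "top"), 45)
  expect_equal(edge_tilt(mk(c(0, 0), c(20, -5)), "top"),
               atan2(-5, 20) * 180 / pi, tolerance = 1e-12)
  expect_equal(round(edge_tilt(mk(c(0, 0), c(20, -5)), "top"), 2), -14.04)
  degenerate <- rbind(c(5, 5, 5, 5, 0, 60, 10, 60))
  expect_error(edge_tilt(spine_sequence(degenerate), "top"), "degenerate")
})

test_that("gap profile measures corner-to-corner distances between neighbours", {
  touching <- straight_column(2, height = 34, spacing = 34)
  gp <- gap_profile(touching)
  expect_equal(gp$left, 0)
  expect_equal(gp$right, 0)

  apart <- straight_column(2, height = 27, spacing = 34)  # 7 px clearance
  gp <- gap_profile(apart)
  expect_equal(gp$left, 7)
  expect_equal(gp$right, 7)

  ph <- phantom_for_angle(30, seed = 2, noise = 0)
  gp <- gap_profile(ph$seq)
  expect_length(gp$left, nrow(ph$seq) - 1L)
  # the arch bulges toward +x (right-convex): gaps open on the right
  expect_gt(sum(gp$right), sum(gp$left))
  expect_identical(find_apex(ph$seq)$direction, "right-convex")
})

test_that("apex is the center farthest from the first-last chord", {
  st <- straight_column(17)
  a <- find_apex(st)
  expect_true(a$zero_curve)
  expect_equal(a$apex_index, 9L)

  ph <- phantom_for_angle(40, seed = 11, noise = 0)
  a <- find_apex(ph$seq)
  expect_false(a$zero_curve)
  expect_equal(a$apex_index, ph$true_apex_index)
  expect_equal(a$apex_index, brute_apex(ph$seq))

  m <- find_apex(mirror_seq(ph$seq))
  expect_equal(m$apex_index, a$apex_index)
  expect_false(m$direction == a$direction)
})

test_that("end vertebrae are the most tilted above and below the apex", {
  # all flat except box 2's top edge at 12 degrees; apex forced at 8 by
  # using the selection directly
  tilts <- rep(0, 10); tilts[2] <- 12
  s <- tilted_sequence(tilts, xs = rep(100, 10))
  ends <- select_end_vertebrae(s, 8L)
  expect_equal(ends$superior_index, 2L)

  # monotone tilts away from the apex: the extremes win
  ph <- phantom_for_angle(45, seed = 3, noise = 0)
  apex <- find_apex(ph$seq)$apex_index
  ends <- select_end_vertebrae(ph$seq, apex)
  expect_equal(ends$superior_index, 1L)
  expect_equal(ends$inferior_index, nrow(ph$seq))
  expect_equal(ends, brute_ends(ph$seq, apex))

  # equal maximal tilts above the apex: the one farther from the apex wins
  tilts <- rep(0, 10); tilts[c(2, 4)] <- 9
  s <- tilted_sequence(tilts, xs = rep(100, 10))
  expect_equal(select_end_vertebrae(s, 8L)$superior_index, 2L)
})

test_that("full measurement recovers constructed and analytic angles", {
  expect_equal(measure_cobb(straight_column(17))$angle_deg, 0)

  # superior top edge +10 deg, inferior bottom edge -15 deg -> 25 deg
  tilts <- c(10, 6, 2, -2, -8, -15)
  xs <- 100 + c(0, 5, 8, 8, 5, 0)
  r <- measure_cobb(tilted_sequence(tilts, xs))
  expect_equal(r$angle_deg, 25, tolerance = 1e-9)
  expect_equal(r$angle_deg_rounded, 25L)
  expect_equal(r$superior_index, 1L)
  expect_equal(r$inferior_index, 6L)

  ph <- phantom_for_angle(40, seed = 17, noise = 0)
  r <- measure_cobb(ph$seq)
  expect_lt(abs(r$angle_deg - ph$true_cobb_deg), 1)
  expect_equal(r$angle_deg, abs(r$tilt_sup_deg - r$tilt_inf_deg))
  expect_true(r$superior_index <= r$apex_index)
  expect_true(r$apex_index <= r$inferior_index)
})

test_that("integer reporting rounds halves away from zero", {
  expect_identical(cobbangle:::round_half_away(c(0.5, 1.4, 1.5, 2.5, -0.5)),
                   c(1L, 1L, 2L, 3L, -1L))
})
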
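test_that("eye aspect vector matches hand computation and degenerates to zero", {
  expect_equal(eav(open_eye), c(0.5, 0.5))
  closed <- open_eye
  closed[c("p2", "p4"), 2] <- 0; closed[c("p3", "p5"), 2] <- 0
  closed["p3", ] <- closed["p2", ]; closed["p5", ] <- closed["p4", ]
  expect_equal(eav(closed), c(0, 0))
  degen <- open_eye; degen["p6", ] <- degen["p1", ]
  expect_error(eav(degen), "degenerate")
})

test_that("ratio features are invariant to rotation, translation and scale", {
  set.seed(5)
  for (i in 1:25) {
    ang <- runif(1, 0, 2 * pi); sc <- runif(1, 0.2, 5); sh <- runif(2, -50, 50)
    eye2 <- rigid_transform(open_eye, ang, sc, sh)
    mouth2 <- rigid_transform(open_mouth, ang, sc, sh)
    expect_equal(eav(eye2), eav(open_eye), tolerance = 1e-9)
    expect_equal(mav(mouth2), mav(open_mouth), tolerance = 1e-9)
    expect_equal(eoa(eye2), eoa(open_eye), tolerance = 1e-9)
    expect_equal(moa(mouth2), moa(open_mouth), tolerance = 1e-9)
    # s_mp is translation invariant only (axis-aligned construction)
    shifted <- sweep(open_mouth, 2, -runif(2, -30, 30))
    expect_equal(s_mp(shifted), s_mp(open_mouth), tolerance = 1e-9)
  }
})

test_that("eye opening angle follows the arcsin construction", {
  # p2 = (1,1), corners (0,0)-(4,0): perp dist 1, hyp sqrt(2) -> pi/4
  expect_equal(eoa(open_eye), pi / 4)
  flat <- open_eye; flat["p2", ] <- c(1, 0)
  expect_equal(eoa(flat), 0)
  set.seed(8)
  for (i in 1:20) {
    pts <- open_eye + matrix(rnorm(12, sd = 0.3), 6, 2)
    a <- eoa(pts)
    expect_gte(a, 0); expect_lte(a, pi / 2)
  }
})

test_that("mouth opening angle and area proxy match hand computations", {
  # M3 = (2,2) with corners (0,0)-(4,0): arcsin(2/sqrt(8)) = pi/4
  m <- open_mouth; m["m3", ] <- c(2, 2)
  expect_equal(moa(m), pi / 4)
  flat <- open_mouth; flat["m3", ] <- c(2, 0)
  expect_equal(moa(flat), 0)
  # s_mp: |x_M8 - x_M1| * |y_M7 - y_M3|
  m2 <- open_mouth
  m2["m8", ] <- c(3, -2); m2["m1", ] <- c(1, 0)
  m2["m7", ] <- c(2, -2); m2["m3", ] <- c(2, 2)
  expect_equal(s_mp(m2), 2 * 4)
  m2["m8", 1] <- m2["m1", 1]
  expect_equal(s_mp(m2), 0)
})

test_that("mouth aspect vector normalizes the three lip pairs by mouth width", {
  expect_equal(mav(open_mouth), c(0.5, 0.75, 0.5))
  closed <- open_mouth
  closed["m6", ] <- closed["m4", ]; closed["m7", ] <- closed["m3", ]
  closed["m8", ] <- closed["m2", ]
  expect_equal(mav(closed), c(0, 0, 0))
})

test_that("eye closure area ratio is the normalized axis product", {
  calib <- eye_calibration(a_max = 4, b_max = 2)
  # current canthus 2, mean lid 1 -> (2*1)/(4*2)
  eye <- rbind(c(0, 0), c(0.5, 0.5), c(0.5, -0.5), c(1.5, 0.5), c(1.5, -0.5),
               c(2, 0))
  expect_equal(s_ar(eye, calib), 0.25)
  full <- rbind(c(0, 0), c(1, 1), c(1, -1), c(3, 1), c(3, -1), c(4, 0))
  expect_equal(s_ar(full, eye_calibration(4, 2)), 1)
  shut <- full; shut[3, ] <- full[2, ]; shut[5, ] <- full[4, ]
  expect_equal(s_ar(shut, eye_calibration(4, 2)), 0)
  expect_error(s_ar(full, list(a_max = 0)), "calib")
})

test_that("per-frame closure rule thresholds at 20% of baseline", {
  calib <- eye_calibration(a_max = 4, b_max = 2, baseline_open = 2)
  expect_true(is_eye_closed(0, calib))
  expect_false(is_eye_closed(2, calib))
  expect_true(is_eye_closed(0.19 * 2, calib))
  expect_false(is_eye_closed(0.21 * 2, calib))
  expect_equal(is_eye_closed(c(0, 2), calib), c(TRUE, FALSE))
})

test_that("blink frequency equals the closed-frame fraction", {
  expect_equal(blink_frequency(c(rep(TRUE, 3), rep(FALSE, 7))), 0.3)
  expect_equal(blink_frequency(rep(FALSE, 5)), 0)
  expect_equal(blink_frequency(rep(TRUE, 4)), 1)
  expect_error(blink_frequency(logical(0)), "empty")
  set.seed(3)
  for (i in 1:20) {
    flags <- runif(sample(5:200, 1)) < 0.3
    expect_equal(blink_frequency(flags), sum(flags) / length(flags))
  }
})

test_that("yawn frequency gates runs by duration, excluding speech bursts", {
  fps <- 15
  n <- 60 * fps
  mav_mid <- rep(0.05, n)
  mav_mid[100:(100 + 4 * fps - 1)] <- 0.85          # one 4 s yawn
  expect_equal(yawn_frequency(mav_mid, fps), (4 * fps) / n)
  mav_mid2 <- rep(0.05, n)
  mav_mid2[200:(200 + fps - 1)] <- 0.85             # 1 s speech burst
  expect_equal(yawn_frequency(mav_mid2, fps), 0)
  expect_equal(yawn_frequency(rep(0.05, n), fps), 0)
  expect_error(yawn_frequency(numeric(0), fps), "empty")
})

test_that("scalarize produces the fixed 11-feature order with component means", {
  frame <- list(eav = c(0.4, 0.6), mav = c(0.3, 0.6, 0.3), s_ar = 0.8,
                s_mp = 12, pitch = 1, yaw = -2, roll = 0.5, eoa = 0.7,
                moa = 0.2)
  win <- list(f_blink = 0.1, f_yawn = 0.02)
  v <- scalarize(frame, win)
  expect_length(v, 11)
  expect_equal(names(v), c("eav", "mav", "s_ar", "s_mp", "pitch", "yaw",
                           "roll", "eoa", "moa", "f_blink", "f_yawn"))
  expect_equal(unname(v["eav"]), 0.5)
  expect_equal(unname(v["mav"]), 0.4)
  frame$s_ar <- NA_real_
  expect_error(scalarize(frame, win), "non-finite")
})

test_that("extracted blink frequency is higher in fatigued than awake sessions", {
  p <- subject_profile()
  fat <- extract_features(simulate_session(p, "fatigued", 300, 15, seed = 2))
  awa <- extract_features(simulate_session(p, "awake", 300, 15, seed = 2))
  expect_gt(mean(fat$f_blink), mean(awa$f_blink))
  expect_gt(mean(fat$f_yawn), mean(awa$f_yawn))
  expect_true(all(fat$label == 1))
  expect_true(all(awa$label == 0))
  expect_equal(names(fat)[1:13],
               c("t", "eav", "eoa", "s_ar", "mav", "moa", "s_mp", "pitch",
                 "yaw", "roll", "f_blink", "f_yawn", "label"))
})
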
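test_that("a pure 0.5-Hz lateral sway yields 2-s cycles", {
  tt <- (0:(60 * 100 - 1)) / 100
  s <- sensor_stream("imu", 100, list(acc_y = -cos(2 * pi * tt / 2)))
  cyc <- detect_cycles(s)
  expect_equal(nrow(cyc), 30)
  dur <- cyc$t_end - cyc$t_start
  expect_equal(median(dur), 2)
  # the trailing edge cycle may be clipped by up to the smoothing support
  expect_true(all(abs(dur - 2) < 0.1))
})

test_that("degenerate streams yield no cycles", {
  s <- sensor_stream("imu", 100, list(acc_y = rep(1, 1000)))
  expect_equal(nrow(detect_cycles(s)), 0)
  short <- sensor_stream("imu", 100, list(acc_y = rnorm(100)))
  expect_equal(nrow(detect_cycles(short)), 0)
  nochan <- sensor_stream("imu", 100, list(acc_x = rnorm(1000)))
  expect_error(detect_cycles(nochan), "acc_y")
})

test_that("noiseless boundaries are recovered to within one sample", {
  im <- generate_imu(rep("G3", 60), rep(18, 60), noise_free(), seed = 7)
  det <- detect_cycles(im$stream)
  truth <- im$cycles$t_start
  # each detected start matches a ground-truth boundary
  err <- vapply(det$t_start, function(t) min(abs(truth - t)), 0)
  expect_lte(max(err), 1 / im$stream$rate)
  expect_lte(abs(nrow(det) - nrow(im$cycles)), 1)
})

test_that("cycle counts stay within one per bout at default noise", {
  for (seed in 1:5) {
    g <- sample(c("G2", "G3", "G4"), 1)
    im <- generate_imu(rep(g, 45), rep(16, 45), noise_defaults(),
                       seed = 100 + seed)
    det <- detect_cycles(im$stream)
    expect_lte(abs(nrow(det) - nrow(im$cycles)), 1)
  }
})

test_that("feature vectors have fixed length and scale as defined", {
  im <- generate_imu(rep("G3", 20), rep(18, 20), noise_free(), seed = 1)
  cyc <- im$cycles
  f1 <- extract_features(im$stream, cyc$t_start[2], cyc$t_end[2])
  expect_length(f1, 3 * 30 + 4)
  expect_identical(f1, extract_features(im$stream, cyc$t_start[2],
                                        cyc$t_end[2]))
  # doubling the amplitude quadruples variances, leaves shapes unchanged
  im2 <- im
  im2$stream$channels <- lapply(im$stream$channels, `*`, 2)
  f2 <- extract_features(im2$stream, cyc$t_start[2], cyc$t_end[2])
  vr <- grepl("^var_", names(f1))
  expect_equal(f2[vr], 4 * f1[vr], tolerance = 1e-9)
  expect_equal(f2[!vr & names(f1) != "duration"],
               f1[!vr & names(f1) != "duration"], tolerance = 1e-9)
  expect_error(extract_features(im$stream, 5, 5), "degenerate")
})

test_that("the gear classifier separates the sub-techniques", {
  tr <- fx_gear_data(seed = 1)
  model <- fx_gear_model()
  expect_gte(mean(classify_gears(model, tr$features) == tr$labels), 0.99)
  te <- fx_gear_data(seed = 99)
  expect_gte(mean(classify_gears(model, te$features) == te$labels), 0.95)
})

test_that("classifier training validates its inputs", {
  tr <- fx_gear_data(seed = 1)
  expect_error(train_gear_model(tr$features, rep("G2", nrow(tr$features))),
               "two classes")
  expect_error(train_gear_model(tr$features, rep("G9", nrow(tr$features))),
               "unknown gear")
  model <- fx_gear_model()
  expect_error(classify_gears(model, tr$features[, 1:10]), "feature length")
})

test_that("classification is invariant to training-set order", {
  tr <- fx_gear_data(seed = 1)
  te <- fx_gear_data(seed = 50)
  m1 <- train_gear_model(tr$features, tr$labels, seed = 3)
  set.seed(77)
  perm <- sample(nrow(tr$features))
  m2 <- train_gear_model(tr$features[perm, ], tr$labels[perm], seed = 3)
  expect_equal(classify_gears(m1, te$features), classify_gears(m2, te$features))
})

test_that("cycle kinematics satisfy cl * cr = 60 * speed exactly", {
  cyc <- data.frame(t_start = c(0, 2), t_end = c(2, 3))
  k <- cycle_kinematics(cyc, 18)  # 18 km/h = 5 m/s
  expect_equal(k$cl[1], 10)
  expect_equal(k$cr[1], 30)
  # halving the duration halves cl and doubles cr
  expect_equal(k$cl[2], 5)
  expect_equal(k$cr[2], 60)
  expect_equal(k$cl * k$cr, 60 * k$mean_speed)
  expect_error(cycle_kinematics(data.frame(t_start = 1, t_end = 1), 18),
               "positive")
})

test_that("end-to-end cycle processing labels and measures a mixed bout", {
  g <- rep(c("G3", "G2"), each = 40)
  im <- generate_imu(g, rep(16, 80), noise_defaults(), seed = 31)
  out <- process_cycles(im$stream, fx_gear_model(), 16)
  expect_true(all(c("gear", "cl", "cr") %in% names(out)))
  expect_equal(out$cl * out$cr, 60 * out$mean_speed)
  # most cycles agree with ground truth labels
  truth_at <- function(t) {
    j <- which(im$cycles$t_start <= t & im$cycles$t_end > t)
    if (length(j)) im$cycles$gear[j] else "Other"
  }
  mid <- (out$t_start + out$t_end) / 2
  agree <- mean(out$gear == vapply(mid, truth_at, ""))
  expect_gte(agree, 0.9)
})
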
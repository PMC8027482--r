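test_that("zero-phase low-pass keeps DC, kills 50 Hz, stays symmetric", {
  expect_equal(lowpass(rep(3, 500), 200), rep(3, 500), tolerance = 1e-8)
  tt <- (0:999) / 200
  hum <- sin(2 * pi * 50 * tt)
  out <- lowpass(hum, 200)
  mid <- 200:800
  atten <- 20 * log10(max(abs(out[mid])) / 1)
  expect_lt(atten, -40)
  imp <- c(rep(0, 250), 1, rep(0, 250))
  resp <- lowpass(imp, 200)
  expect_equal(resp, rev(resp), tolerance = 1e-9)
  expect_error(lowpass(rnorm(100), 20), "Nyquist")
})

test_that("CoM is the segment-weighted mean of marker positions", {
  n <- 10
  mk <- function(val) rep(val, n)
  nm <- rownames(skimass:::marker_offsets())
  # all markers coincident at p = (1, 2, 3)
  ch <- list()
  for (m in nm) {
    ch[[paste0(m, "_x")]] <- mk(1)
    ch[[paste0(m, "_y")]] <- mk(2)
    ch[[paste0(m, "_z")]] <- mk(3)
  }
  s <- sensor_stream("markers", 200, ch)
  com <- compute_com(s)
  expect_equal(unname(com[, "x"]), mk(1))
  expect_equal(unname(com[, "z"]), mk(3))
  # rigid translation by d translates the CoM by d
  ch2 <- lapply(ch, `+`, 0.7)
  com2 <- compute_com(sensor_stream("markers", 200, ch2))
  expect_equal(com2, com + 0.7)
  # missing marker is reported by name
  ch3 <- ch
  ch3$hip_l_x <- NULL
  expect_error(compute_com(sensor_stream("markers", 200, ch3)), "hip_l_x")
})

test_that("a two-segment toy body has its CoM at the weighted point", {
  seg <- data.frame(segment = c("a", "b"),
                    proximal = c("p1", "p2"), distal = c("p2", "p3"),
                    mass_frac = c(0.6, 0.4), com_frac = c(0, 0))
  # segment CoMs collapse onto p1 and p2
  ch <- list(p1_x = 0, p1_y = 0, p1_z = 0,
             p2_x = 10, p2_y = 0, p2_z = 0,
             p3_x = 99, p3_y = 0, p3_z = 0)
  s <- sensor_stream("markers", 200, ch)
  com <- compute_com(s, segments = seg)
  expect_equal(unname(com[, "x"]), 0.6 * 0 + 0.4 * 10)
})

test_that("numerical differentiation is exact for linear motion", {
  com <- cbind(x = 3 * (0:99) / 100, y = rep(1, 100), z = rep(0, 100))
  v <- com_velocity(com, 100)
  expect_equal(unname(v[, "x"]), rep(3, 100))
  expect_equal(unname(v[, "y"]), rep(0, 100))
  expect_error(com_velocity(com[1:2, ], 100), "3 samples")
  # second-order accuracy on a sine
  err_at <- function(rate) {
    tt <- (0:(rate - 1)) / rate
    p <- cbind(x = sin(2 * pi * tt), y = 0 * tt, z = 0 * tt)
    v <- com_velocity(p, rate)
    max(abs(v[2:(rate - 1), "x"] - 2 * pi * cos(2 * pi * tt[2:(rate - 1)])))
  }
  expect_gt(err_at(50) / err_at(100), 3.5)  # halving h quarters the error
})

test_that("pole force direction follows the handle-to-tip vector", {
  n <- 3
  handle <- cbind(x = rep(0, n), y = rep(0, n), z = rep(1.5, n))
  tip_v <- cbind(x = rep(0, n), y = rep(0, n), z = rep(0, n))
  f <- pole_force_vector(rep(100, n), handle, tip_v)
  expect_equal(unname(f[1, ]), c(0, 0, -100))
  tip45 <- cbind(x = rep(1.5, n), y = rep(0, n), z = rep(0, n))
  f45 <- pole_force_vector(rep(100, n), handle, tip45)
  expect_equal(unname(f45[1, ]), c(70.7107, 0, -70.7107), tolerance = 1e-4)
  expect_equal(unname(pole_force_vector(rep(0, n), handle, tip45)[2, ]),
               c(0, 0, 0))
  expect_error(pole_force_vector(rep(1, n), handle, handle), "zero-length")
})

test_that("pole power is the force-velocity dot product and is bilinear", {
  f <- cbind(x = c(50, 0), y = c(0, 10), z = c(0, 0))
  v <- cbind(x = c(3, 0), y = c(0, 0), z = c(0, 5))
  p <- pole_power(f, v)
  expect_equal(p, c(150, 0))   # orthogonal force does no work
  expect_equal(pole_power(2.5 * f, v), 2.5 * p)
  expect_equal(pole_power(f, -v), -p)
  expect_error(pole_power(f, v[1, , drop = FALSE]), "lengths differ")
})

test_that("touchdown alignment recovers the force-clock offset", {
  prof <- skier_profile()
  fm <- generate_force_and_markers(rep("G3", 30), rep(18, 30), rep(5, 30),
                                   prof, noise_free(), sync_offset = 0.12,
                                   seed = 2)
  al <- align_streams(fm$force, fm$markers)
  expect_lt(abs(al$offset - 0.12), 0.02)
  dead <- fm$force
  dead$channels$force_l[] <- 0
  dead$channels$force_r[] <- 0
  expect_error(align_streams(dead, fm$markers), "never reaches")
})

test_that("power decomposition percentages always close to 100", {
  prof <- skier_profile(pole_frac = 0.60, lr_left = 0.55)
  fm <- generate_force_and_markers(rep("G3", 45), rep(18, 45), rep(5, 45),
                                   prof, noise_defaults(), seed = 9)
  dec <- power_pipeline(fm$markers, fm$force, fm$truth$cycles, prof$mass,
                        5, 18)
  ok <- !is.na(dec$pct_pole)
  expect_true(any(ok))
  expect_equal(dec$pct_pole[ok] + dec$pct_ski[ok], rep(100, sum(ok)))
  expect_equal(dec$pct_pole_left[ok] + dec$pct_pole_right[ok],
               rep(100, sum(ok)))
  expect_equal(dec$p_ski[ok], dec$p_cycle[ok] - dec$p_pole[ok])
})

test_that("noiseless decomposition recovers the true power split", {
  prof <- skier_profile(pole_frac = 0.60, lr_left = 0.55)
  fm <- generate_force_and_markers(rep("G3", 60), rep(18, 60), rep(5, 60),
                                   prof, noise_free(), seed = 2)
  dec <- power_pipeline(fm$markers, fm$force, fm$truth$cycles, prof$mass,
                        5, 18)
  expect_equal(mean(dec$pct_pole, na.rm = TRUE), 60, tolerance = 1 / 60)
  expect_equal(mean(dec$pct_pole_left, na.rm = TRUE), 55, tolerance = 2 / 55)
})

test_that("non-positive cycle work rate flags percentages as missing", {
  cyc <- data.frame(t_start = 0, t_end = 2)
  tt <- seq(0, 2, by = 0.01)
  dec <- decompose_cycles(cyc, tt, rep(10, length(tt)), rep(10, length(tt)),
                          mass = 80, incline = -10, speed = 18)
  expect_true(is.na(dec$pct_pole))
  expect_false(is.na(dec$p_pole))
})

test_that("missing force samples propagate as missing power", {
  cyc <- data.frame(t_start = c(0, 2), t_end = c(2, 4))
  tt <- seq(0, 4, by = 0.01)
  pl <- rep(50, length(tt))
  pl[tt >= 2] <- NA
  dec <- decompose_cycles(cyc, tt, pl, rep(50, length(tt)),
                          mass = 80, incline = 5, speed = 18)
  expect_false(is.na(dec$pct_pole[1]))
  expect_true(is.na(dec$pct_pole[2]))
})
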
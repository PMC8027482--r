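test_that("generation is deterministic given the seed", {
  g <- rep(c("G3", "Other"), each = 30)
  v <- rep(18, 60)
  a <- generate_imu(g, v, noise_defaults(), seed = 5)
  b <- generate_imu(g, v, noise_defaults(), seed = 5)
  expect_identical(a$stream$channels, b$stream$channels)
  expect_identical(a$cycles, b$cycles)
  c <- generate_imu(g, v, noise_defaults(), seed = 6)
  expect_false(identical(a$stream$channels$acc_y, c$stream$channels$acc_y))
})

test_that("IMU stream length and cycle construction follow the schedule", {
  g <- rep("G3", 60)
  im <- generate_imu(g, rep(18, 60), noise_free(), seed = 7)
  expect_equal(stream_length(im$stream), ceiling(60 * 256))
  # 60 s at the G3 period of 1.9 s packs floor(60/1.9) = 31 whole cycles
  expect_equal(nrow(im$cycles), 31)
  expect_true(all(diff(im$cycles$t_start) > 0))
  expect_error(generate_imu(rep("G9", 10), rep(18, 10)), "unknown gear")
})

test_that("non-cycling windows carry no ground-truth cycles", {
  im <- generate_imu(rep("Other", 60), rep(25, 60), noise_free(), seed = 3)
  expect_equal(nrow(im$cycles), 0)
})

test_that("first-order kinetics reach 63% of a step after one time constant", {
  step <- c(rep(0, 5), rep(100, 120))
  resp <- skimass:::first_order(step, tau = 30, init = 0)
  expect_equal(resp[5 + 30] / 100, 1 - exp(-30 / 30), tolerance = 0.02)
  # tau -> 0 limit: measured equals demand
  fast <- skimass:::first_order(step, tau = 1e-9, init = 0)
  expect_equal(fast, step)
})

test_that("generated VO2 and HR respect personal maxima and recover GE", {
  prof <- skier_profile(tte = 60, seed = 21)
  sched <- protocol_schedule(build_protocol(), tte = 60)
  gears <- skimass:::assign_gears(sched, prof$break_times)
  br <- generate_breath_series(sched, gears, prof, noise_defaults(), seed = 21)
  vo2max_l <- prof$vo2max * prof$mass / 1000
  expect_true(all(br$vo2$channels$vo2 <= vo2max_l + 1e-9))
  expect_true(all(br$hr$channels$hr <= prof$hrmax + 1e-9))
  # noiseless bout-level energy consistency within 0.1 pp
  ge <- aggregate_efficiency(gross_efficiency(
    simulate_ge_bouts(prof, noise_free())))
  expect_equal(as.numeric(ge$ge_per_gear[c("G2", "G3", "G4")]),
               as.numeric(prof$ge_by_gear[c("G2", "G3", "G4")]),
               tolerance = 0.1 / 15)
  expect_equal(ge$n_bouts, 12L)
})

test_that("a break inserts a contiguous Other window of 30 s", {
  prof <- skier_profile(tte = 0, break_times = 400, seed = 2)
  sched <- protocol_schedule(build_protocol(), tte = 0)
  gears <- skimass:::assign_gears(sched, prof$break_times)
  brk <- which(gears == "Other" & sched$t >= 400 & sched$t < 430)
  expect_equal(length(brk), 30)
  expect_equal(brk, seq(brk[1], brk[1] + 29))
})

test_that("axial pole force exceeds 10 N only during ground contact", {
  prof <- skier_profile(pole_frac = 0.6)
  fm <- generate_force_and_markers(rep("G3", 30), rep(18, 30), rep(5, 30),
                                   prof, noise_free(), seed = 4)
  f <- pmax(fm$force$channels$force_l, fm$force$channels$force_r)
  # 10 N is crossed strictly inside the 0.4-s contact of each 1.9-s cycle
  expect_lt(mean(f > 10), 0.4 / 1.9)
  expect_gt(mean(f > 10), 0.15)
  expect_true(all(f >= 0))
  # swing phase is force-free
  expect_gt(mean(f == 0), 0.5)
})

test_that("trial generation covers all phases and errors on a long AOS", {
  tr <- fx_trial()
  expect_setequal(names(tr$streams),
                  c("imu", "baro", "hr", "vo2", "nirs", "pole_force",
                    "markers"))
  n_s <- nrow(tr$truth$per_second)
  expect_equal(n_s, 1260 + 90)
  expect_equal(stream_length(tr$streams$imu), 256 * n_s)
  expect_equal(stream_length(tr$streams$baro), 64 * n_s)
  expect_error(generate_trial(build_protocol(), skier_profile(tte = 1e5)),
               "horizon")
})

test_that("stream CSV round-trip preserves data and metadata", {
  s <- sensor_stream("demo", 32, list(a = sin(1:100), b = cos(1:100)),
                     t0_offset = 1.5)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_stream_csv(s, path)
  r <- read_stream_csv(path)
  expect_equal(r$instrument, "demo")
  expect_equal(r$rate, 32)
  expect_equal(r$t0_offset, 1.5)
  expect_equal(r$channels$a, s$channels$a, tolerance = 1e-12)
})
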
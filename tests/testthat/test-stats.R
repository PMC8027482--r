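test_that("lap drift uses the kind-specific baseline lap", {
  m <- matrix(rep(c(10, 10.5, 11, 11.5, 12, 12.5, 13), 5), nrow = 5,
              byrow = TRUE)
  phys <- lap_drift(m, "physiological")
  expect_equal(phys$drift, 13 - 10.5)
  kin <- lap_drift(m, "kinematic")
  expect_equal(kin$drift, 3)
  flat <- matrix(5, nrow = 4, ncol = 7)
  d0 <- lap_drift(flat)
  expect_equal(d0$drift, 0)
  expect_equal(d0$p, 1)
  expect_error(lap_drift(m[, 1:6]), "7 lap")
})

test_that("drift recovers a known injected effect across skiers", {
  set.seed(12)
  lap_means <- t(replicate(9, 85 + 1.58 * (0:6) + rnorm(7, 0, 0.4)))
  d <- lap_drift(lap_means, "physiological")
  expect_equal(d$drift, 1.58 * 5, tolerance = 0.1)
  expect_lt(d$p, 0.001)
})

test_that("segment contrasts match a closed-form ANOVA", {
  df <- data.frame(segment = rep(c("S1", "S2"), each = 4),
                   value = c(5, 6, 7, 8, 9, 10, 11, 12))
  sc <- segment_contrasts(df)
  # two groups, n = 4 each: F = n * (d/2)^2 * 2 / pooled variance
  gm <- mean(df$value)
  ssb <- 4 * ((mean(5:8) - gm)^2 + (mean(9:12) - gm)^2)
  ssw <- sum((df$value - ave(df$value, df$segment))^2)
  expect_equal(sc$f, (ssb / 1) / (ssw / 6))
  expect_error(segment_contrasts(data.frame(segment = "S1", value = 1:3)),
               "two segments")
  same <- data.frame(segment = rep(c("S1", "S2", "S3"), each = 5),
                     value = rep(c(1, 2, 3, 4, 5), 3))
  expect_lt(segment_contrasts(same)$f, 1e-20)
})

test_that("a constructed segment intensity dip is detected", {
  set.seed(5)
  df <- expand.grid(skier = 1:9, segment = c("S1", "S2", "S3", "S4"))
  df$value <- 90 + rnorm(nrow(df), 0, 1.5) - 8 * (df$segment == "S1")
  sc <- segment_contrasts(df)
  expect_lt(sc$p, 0.05)
  s1p <- sc$tukey$p_adj[grepl("S1", sc$tukey$pair)]
  expect_true(all(s1p < 0.05))
})

test_that("spearman equals the exhaustive mid-rank oracle for small n", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    x <- sample(1:4, n, replace = TRUE)   # ties likely
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_cor(x, y)$coefficient, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(spearman_cor(1:5, 5:1)$coefficient, -1)
  expect_true(is.na(spearman_cor(rep(1, 5), 1:5)$coefficient))
})

test_that("pearson handles affine relations and pairwise deletion", {
  tte <- c(130, 119, 101, 91, 82, 74, 65, 60, 47)
  expect_equal(pearson_cor(tte, 2 * tte + 1)$coefficient, 1)
  y <- c(2, 4, 1, 5, 3, 7, 6, 9, NA)
  r <- pearson_cor(tte, y)
  expect_equal(r$n, 8L)
  short <- pearson_cor(c(1, 2), c(3, 4))
  expect_true(is.na(short$coefficient))
})

test_that("magnitude labels follow the published bands", {
  expect_equal(magnitude_label(0.52), "large")
  expect_equal(magnitude_label(-0.87), "very large")
  expect_equal(magnitude_label(0), "trivial")
  expect_equal(magnitude_label(0.1), "small")
  expect_equal(magnitude_label(0.95), "extremely large")
  expect_error(magnitude_label(1.2), "<= 1")
})

test_that("embedded summary tables load, verify and join", {
  t2 <- skier_physiology()
  t3 <- skier_kinematics()
  expect_equal(nrow(t2), 13)
  expect_equal(nrow(t3), 13)
  expect_equal(t2$rank, 1:13)
  expect_equal(sum(t2$breaks == 0), 9)
  # two skiers lost their pole-force recordings
  expect_equal(sum(is.na(t3$pct_pole_ip)), 2)
  s <- skier_summaries()
  expect_equal(nrow(s), 13)
  # gear shares close on 100%
  shares <- s$g2_ip + s$g3_ip + s$g4_ip + s$other_ip
  expect_true(all(abs(shares - 100) <= 1))
})

test_that("the correlation battery reproduces the headline values", {
  rep_ <- reproduce_correlations()
  sp <- rep_$spearman
  get <- function(v) sp$coefficient[sp$variable == v]
  expect_equal(abs(get("pct_hrmax_ip")), 0.87, tolerance = 0.005)
  expect_equal(abs(get("vo2max")), 0.68, tolerance = 0.005)
  expect_equal(abs(get("rpe_ip")), 0.73, tolerance = 0.005)
  expect_equal(abs(get("vo2_reserve")), 0.72, tolerance = 0.005)
  expect_equal(round(abs(get("hr_reserve")), 2), 0.76)
  expect_equal(unname(rep_$cohort_means["vo2max"]), 69.5, tolerance = 0.05)
  # better rank (lower number) goes with lower relative intensity
  expect_gt(get("pct_hrmax_ip"), 0)
  expect_lt(get("vo2max"), 0)
})
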
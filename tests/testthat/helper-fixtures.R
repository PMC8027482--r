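# Shared lazily-built fixtures (generated once per test run).

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# default noisy trial: one break, 90-s AOS
fx_trial <- function() fx_cached("trial", function() {
  generate_trial(build_protocol(),
                 skier_profile(tte = 90, break_times = 700, seed = 11))
})

fx_master <- function() fx_cached("master", function() {
  build_master_timeline(fx_trial())
})

# labelled cycle features from a four-bout IMU recording (one per gear)
fx_gear_data <- function(seed, noise = noise_defaults(), bout_s = 120) {
  g <- rep(c("G2", "G3", "G4", "Other"), each = bout_s)
  im <- generate_imu(g, rep(16, length(g)), noise, seed = seed)
  det <- detect_cycles(im$stream)
  lab <- vapply(seq_len(nrow(det)), function(i) {
    mid <- (det$t_start[i] + det$t_end[i]) / 2
    j <- which(im$cycles$t_start <= mid & im$cycles$t_end > mid)
    if (length(j)) im$cycles$gear[j] else "Other"
  }, "")
  feats <- t(vapply(seq_len(nrow(det)), function(i)
    extract_features(im$stream, det$t_start[i], det$t_end[i]),
    numeric(94)))
  list(features = feats, labels = lab)
}

fx_gear_model <- function() fx_cached("gear_model", function() {
  tr <- fx_gear_data(seed = 1)
  train_gear_model(tr$features, tr$labels)
})

# brute-force mid-rank Spearman: ranks by counting, Pearson by sums
oracle_spearman <- function(x, y) {
  br <- function(v) vapply(seq_along(v), function(i)
    1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2, 0)
  rx <- br(x) - mean(br(x))
  ry <- br(y) - mean(br(y))
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

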
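#' Detect movement cycles from the chest IMU
#'
#' Cycle detection is based on the sidewise movement of the upper body: the
#' mediolateral acceleration channel is Gaussian-smoothed and a cycle starts
#' at the point where the upper body is in its leftmost position with lowest
#' (most negative) acceleration. Local minima closer together than
#' `min_period` are pruned keeping the most negative; consecutive retained
#' minima delimit cycles. The defaults (sigma 0.1 s, minimum period 0.8 s,
#' i.e. at most 75 cycles/min) leave generous headroom around the observed
#' cycle-rate range of roughly 29-36 cpm.
#'
#' @param imu a [sensor_stream()] with an `acc_y` channel (leftward lateral
#'   acceleration negative)
#' @param smoothing_sigma Gaussian kernel SD, s
#' @param min_period minimum admissible cycle duration, s
#' @return data.frame of cycle boundaries `t_start`, `t_end` (seconds on the
#'   stream clock); empty for streams shorter than 2 s
#' @export
detect_cycles <- function(imu, smoothing_sigma = 0.1, min_period = 0.8) {
  if (!"acc_y" %in% names(imu$channels))
    stop("IMU stream has no mediolateral channel 'acc_y'")
  y <- imu$channels$acc_y
  n <- length(y)
  if (n / imu$rate < 2) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0)))
  }
  ys <- gaussian_smooth(y, smoothing_sigma * imu$rate)
  # strict local minima, on a reflection-padded copy so that a cycle start
  # sitting exactly on a stream edge is still found
  guard <- ceiling(3 * smoothing_sigma * imu$rate)
  ysp <- c(rev(ys[seq(2, guard + 1)]), ys,
           rev(ys[seq(n - guard, n - 1)]))
  d <- diff(ysp)
  cand <- which(d[-length(d)] < 0 & d[-1] > 0) + 1 - guard
  cand <- unique(pmin(pmax(cand, 1L), n))
  if (length(cand) < 2) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0)))
  }
  # prune minima closer than min_period, keeping the most negative
  min_gap <- round(min_period * imu$rate)
  ord <- cand[order(ys[cand])]
  keep <- logical(n)
  blocked <- logical(n)
  for (i in ord) {
    if (blocked[i]) next
    keep[i] <- TRUE
    blocked[max(1, i - min_gap):min(n, i + min_gap)] <- TRUE
  }
  mins <- sort(which(keep))
  # drop shallow minima: a cycle-start minimum must dip below the local
  # signal spread (rejects ripple in non-cycling windows)
  depth <- ys[mins] - (mean(ys) - 0.5 * stats::sd(ys))
  mins <- mins[depth < 0]
  if (length(mins) < 2) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0)))
  }
  tt <- stream_time(imu)
  data.frame(t_start = tt[mins[-length(mins)]], t_end = tt[mins[-1]])
}

# FIR Gaussian smoothing with reflected edges; sigma in samples.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[length(x) - seq_len(half) + 1]))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + length(x))]
}

#' Fixed-length feature vector for one detected cycle
#'
#' Each accelerometer axis is time-normalised to `n_points` samples by
#' linear interpolation and standardised within the window (so the shape
#' features are amplitude-invariant), then the cycle duration and the raw
#' per-axis variances are appended: 3 x 30 + 4 = 94 features by default.
#'
#' @param imu a [sensor_stream()] with acc_x/acc_y/acc_z
#' @param t_start,t_end cycle boundaries, s on the stream clock
#' @param n_points resampled points per axis
#' @return named numeric feature vector
#' @export
extract_features <- function(imu, t_start, t_end, n_points = 30) {
  if (t_end <= t_start) stop("degenerate cycle window")
  tt <- stream_time(imu)
  sel <- tt >= t_start & tt < t_end
  if (sum(sel) < 4) stop("cycle window too short for feature extraction")
  grid <- seq(t_start, t_end, length.out = n_points)
  feats <- numeric(0)
  vars <- numeric(3)
  axes <- c("acc_x", "acc_y", "acc_z")
  for (i in seq_along(axes)) {
    x <- imu$channels[[axes[i]]][sel]
    shape <- stats::approx(tt[sel], x, xout = grid, rule = 2)$y
    s <- stats::sd(shape)
    shape <- if (s > 0) (shape - mean(shape)) / s else shape * 0
    feats <- c(feats, shape)
    vars[i] <- stats::var(x)
  }
  out <- c(feats, t_end - t_start, vars)
  names(out) <- c(paste0(rep(axes, each = n_points), "_", seq_len(n_points)),
                  "duration", paste0("var_", axes))
  out
}

#' Train the sub-technique (gear) classifier
#'
#' A support-vector classifier with RBF kernel over the cycle feature
#' vectors, with feature standardisation constants kept in the model. The
#' class set is fixed to G2/G3/G4/Other; training data must contain at
#' least two of them.
#'
#' @param features matrix (cycles x features) from [extract_features()]
#' @param labels gear labels, same length as rows
#' @param seed integer seed for the SVM fit
#' @return a `gear_model`
#' @export
train_gear_model <- function(features, labels, seed = 1L) {
  classes <- c("G2", "G3", "G4", "Other")
  bad <- setdiff(unique(labels), classes)
  if (length(bad)) stop("unknown gear label: ", paste(bad, collapse = ", "))
  if (length(unique(labels)) < 2)
    stop("training data must contain at least two classes")
  features <- as.matrix(features)
  mu <- colMeans(features)
  sd_ <- apply(features, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  scaled <- sweep(sweep(features, 2, mu), 2, sd_, "/")
  set.seed(seed)
  fit <- e1071::svm(scaled, factor(labels, levels = classes),
                    kernel = "radial", scale = FALSE)
  structure(list(fit = fit, mu = mu, sd = sd_, classes = classes,
                 n_features = ncol(features)),
            class = "gear_model")
}

#' @rdname train_gear_model
#' @param model a `gear_model`
#' @export
classify_gears <- function(model, features) {
  stopifnot(inherits(model, "gear_model"))
  features <- as.matrix(features)
  if (is.null(dim(features)) || ncol(features) != model$n_features)
    stop("feature length does not match the trained model (",
         model$n_features, ")")
  scaled <- sweep(sweep(features, 2, model$mu), 2, model$sd, "/")
  as.character(stats::predict(model$fit, scaled))
}

#' Save / load a gear model
#' @param model a `gear_model`
#' @param path file path
#' @export
save_gear_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_gear_model
#' @export
load_gear_model <- function(path) readRDS(path)

#' Cycle length and cycle rate from boundaries and belt speed
#'
#' CL is the mean belt speed (m/s) over the cycle times its duration; CR is
#' 60 divided by the duration (cycles per minute), so CL x CR = 60 x mean
#' speed holds exactly for every cycle.
#'
#' @param cycles data.frame with `t_start`, `t_end`
#' @param speed_of function mapping time (s) to belt speed (km/h), or a
#'   single constant speed in km/h
#' @return `cycles` with `cl` (m), `cr` (cpm) and `mean_speed` (m/s) added
#' @export
cycle_kinematics <- function(cycles, speed_of) {
  dur <- cycles$t_end - cycles$t_start
  if (any(dur <= 0)) stop("cycle durations must be positive")
  if (is.numeric(speed_of) && length(speed_of) == 1) {
    v <- rep(speed_of / 3.6, nrow(cycles))
  } else {
    v <- vapply(seq_len(nrow(cycles)), function(i) {
      tt <- seq(cycles$t_start[i], cycles$t_end[i], by = 0.05)
      mean(speed_of(tt)) / 3.6
    }, 0)
  }
  cycles$mean_speed <- v
  cycles$cl <- v * dur
  cycles$cr <- 60 / dur
  cycles
}

#' End-to-end cycle processing of an IMU stream
#'
#' Detects cycles, extracts features, classifies each cycle with the given
#' model, and derives CL and CR.
#'
#' @param imu a [sensor_stream()]
#' @param model a trained `gear_model`
#' @param speed_of per-time belt speed (see [cycle_kinematics()])
#' @param overrides optional data.frame (`t_start`, `gear`) of manual label
#'   corrections applied by nearest cycle start
#' @return data.frame of cycles with gear, cl, cr
#' @export
process_cycles <- function(imu, model, speed_of, overrides = NULL) {
  cyc <- detect_cycles(imu)
  if (!nrow(cyc)) return(cbind(cyc, gear = character(0)))
  feats <- t(vapply(seq_len(nrow(cyc)), function(i)
    extract_features(imu, cyc$t_start[i], cyc$t_end[i]),
    numeric(3 * 30 + 4)))
  cyc$gear <- classify_gears(model, feats)
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      j <- which.min(abs(cyc$t_start - overrides$t_start[i]))
      cyc$gear[j] <- overrides$gear[i]
    }
  }
  cycle_kinematics(cyc, speed_of)
}
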
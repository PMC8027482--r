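#' Zero-phase Butterworth low-pass filter
#'
#' 8th-order Butterworth with 15-Hz cutoff, applied forward-backward
#' (zero phase lag), as used on marker and pole-force data before any
#' kinematic computation.
#'
#' @param x numeric series (NAs are passed through untouched)
#' @param rate sampling rate, Hz (must exceed twice the cutoff)
#' @param cutoff cutoff frequency, Hz
#' @param order filter order
#' @export
lowpass <- function(x, rate, cutoff = 15, order = 8) {
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency")
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  bf <- signal::butter(order, cutoff / (rate / 2))
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- x
  for (i in which(runs$values)) {
    seg <- starts[i]:ends[i]
    if (length(seg) > 3 * order)
      out[seg] <- filtfilt_padded(bf, x[seg], rate, cutoff)
  }
  out
}

# forward-backward filtering with odd-reflection end padding long enough
# for the startup transient to die out, so that constant signals pass
# unchanged and edges carry no artefact
filtfilt_padded <- function(bf, x, rate, cutoff) {
  n <- length(x)
  np <- min(n - 1, ceiling(45 * rate / (2 * cutoff)))
  head_pad <- 2 * x[1] - x[seq(np + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - np)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(np + 1):(np + n)]
}

# central differences interior, one-sided at the ends
num_gradient <- function(x, dt) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate")
  c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / dt
}

# Segment inertial parameters: mass fraction of body mass and longitudinal
# CoM position as a fraction of the proximal->distal marker vector
# (de Leva's adjusted male values; head+trunk as one segment bounded by the
# hip and shoulder markers, forearm+hand combined). Fractions sum to 1.
ski_segment_table <- function() {
  data.frame(
    segment  = c("head_trunk", "thigh_l", "thigh_r", "shank_l", "shank_r",
                 "foot_l", "foot_r", "upper_arm_l", "upper_arm_r",
                 "forearm_hand_l", "forearm_hand_r"),
    proximal = c("shoulder_mid", "hip_l", "hip_r", "knee_l", "knee_r",
                 "ankle_l", "ankle_r", "shoulder_l", "shoulder_r",
                 "elbow_l", "elbow_r"),
    distal   = c("hip_mid", "knee_l", "knee_r", "ankle_l", "ankle_r",
                 "boot_l", "boot_r", "elbow_l", "elbow_r",
                 "wrist_l", "wrist_r"),
    mass_frac = c(0.5040, 0.1416, 0.1416, 0.0433, 0.0433,
                  0.0137, 0.0137, 0.0271, 0.0271, 0.0223, 0.0223),
    com_frac = c(0.45, 0.4095, 0.4095, 0.4459, 0.4459,
                 0.4415, 0.4415, 0.5772, 0.5772, 0.60, 0.60),
    stringsAsFactors = FALSE
  )
}

marker_xyz <- function(markers, name) {
  if (endsWith(name, "_mid")) {
    base <- sub("_mid$", "", name)
    l <- marker_xyz(markers, paste0(base, "_l"))
    r <- marker_xyz(markers, paste0(base, "_r"))
    return((l + r) / 2)
  }
  cols <- paste0(name, "_", c("x", "y", "z"))
  missing <- setdiff(cols, names(markers$channels))
  if (length(missing)) stop("missing marker channel: ", missing[1])
  cbind(x = markers$channels[[cols[1]]],
        y = markers$channels[[cols[2]]],
        z = markers$channels[[cols[3]]])
}

#' Whole-body centre of mass from marker positions
#'
#' The CoM is the mass-fraction-weighted sum of segment CoMs; each segment
#' CoM sits at a published fraction of the proximal-to-distal marker vector.
#'
#' @param markers a [sensor_stream()] of `<marker>_<axis>` channels
#'   (x forward, y left-positive, z up, metres)
#' @param mass body mass, kg (carried through; positions depend only on the
#'   mass fractions)
#' @param segments segment parameter table (default [ski_segment_table()];
#'   `mass_frac` must sum to 1)
#' @return matrix with columns x, y, z (one row per sample)
#' @export
compute_com <- function(markers, mass = NULL, segments = ski_segment_table()) {
  if (abs(sum(segments$mass_frac) - 1) > 1e-6)
    stop("segment mass fractions must sum to 1")
  com <- NULL
  for (i in seq_len(nrow(segments))) {
    p <- marker_xyz(markers, segments$proximal[i])
    d <- marker_xyz(markers, segments$distal[i])
    seg_com <- p + segments$com_frac[i] * (d - p)
    contrib <- segments$mass_frac[i] * seg_com
    com <- if (is.null(com)) contrib else com + contrib
  }
  com
}

#' Centre-of-mass velocity by numerical differentiation
#'
#' Central differences in the interior, one-sided differences at the ends.
#'
#' @param com matrix with columns x, y, z
#' @param rate sampling rate, Hz
#' @return velocity matrix, m/s
#' @export
com_velocity <- function(com, rate) {
  if (nrow(com) < 3) stop("need at least 3 samples to differentiate")
  apply(com, 2, num_gradient, dt = 1 / rate)
}

#' Resolve axial pole force into 3D components
#'
#' The instrumented grips measure the resultant force along the pole; its
#' direction is the unit vector from the handle marker toward the tip
#' marker.
#'
#' @param axial axial force magnitude, N (vector)
#' @param handle,tip matrices with columns x, y, z
#' @return 3D force matrix, N
#' @export
pole_force_vector <- function(axial, handle, tip) {
  d <- tip - handle
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-9, na.rm = TRUE)) stop("zero-length pole vector")
  axial * d / len
}

#' Instantaneous pole power
#'
#' \eqn{P = F_x V_x + F_y V_y + F_z V_z} per pole; poles are computed
#' independently and then summed by the caller.
#'
#' @param f 3D force matrix, N
#' @param v CoM velocity matrix, m/s
#' @return power series, W
#' @export
pole_power <- function(f, v) {
  if (nrow(f) != nrow(v)) stop("force and velocity lengths differ")
  rowSums(f * v)
}

#' Align the pole-force stream to the kinematic clock
#'
#' The first pole touchdown is defined as the first instant the axial force
#' reaches 10 N; its kinematic counterpart is the first ground contact of a
#' pole tip (first time the tip's vertical position dips to its contact
#' minimum). The force clock is shifted so the two coincide, and force is
#' resampled onto the (authoritative) kinematic clock by linear
#' interpolation.
#'
#' @param force a 100-Hz [sensor_stream()] with `force_l`, `force_r`
#' @param markers a 200-Hz [sensor_stream()] with pole tip channels
#' @param threshold touchdown force threshold, N
#' @return list: `force_l`, `force_r` on the marker clock, `t` (marker
#'   times), and the applied `offset` (s)
#' @export
align_streams <- function(force, markers, threshold = 10) {
  ftot <- pmax(force$channels$force_l, force$channels$force_r)
  tf <- stream_time(force)
  above <- which(!is.na(ftot) & ftot >= threshold)
  if (!length(above)) stop("pole force never reaches ", threshold, " N")
  i <- above[1]
  t_force <- if (i > 1 && !is.na(ftot[i - 1])) {
    # linear interpolation to the exact crossing instant
    tf[i - 1] + (threshold - ftot[i - 1]) / (ftot[i] - ftot[i - 1]) *
      (tf[i] - tf[i - 1])
  } else tf[i]

  tm <- stream_time(markers)
  tipz <- pmin(markers$channels$pole_tip_l_z, markers$channels$pole_tip_r_z)
  zmin <- min(tipz, na.rm = TRUE)
  # first ground contact: first local minimum of tip height that comes
  # close to the overall contact height
  dz <- diff(tipz)
  lm <- which(dz[-length(dz)] < 0 & dz[-1] >= 0) + 1
  lm <- lm[!is.na(tipz[lm]) & tipz[lm] <= zmin + 0.05]
  if (!length(lm)) stop("no pole touchdown found in the tip trajectory")
  t_kin <- tm[lm[1]]
  offset <- t_kin - t_force
  list(force_l = stats::approx(tf + offset, force$channels$force_l,
                               xout = tm)$y,
       force_r = stats::approx(tf + offset, force$channels$force_r,
                               xout = tm)$y,
       t = tm, offset = offset)
}

#' Decompose cycle work rate into pole and ski power
#'
#' The cycle work rate (`p_cycle`) is the external work rate against
#' gravity and rolling friction at the cycle's speed and incline; the
#' cycle-average of the summed instantaneous pole power is `p_pole`, and the
#' residual `p_ski = p_cycle - p_pole` is attributed to the ski push-offs.
#' Negative instantaneous pole power is retained in the average (clipping
#' would break the p_cycle = p_pole + p_ski accounting). Percentages of pole
#' power per side are included; cycles with non-positive `p_cycle` get NA
#' percentages.
#'
#' @param cycles data.frame with `t_start`, `t_end`
#' @param t time base of the power series, s
#' @param p_left,p_right per-pole instantaneous power, W
#' @param mass skier mass, kg
#' @param incline incline, percent (single value or function of time)
#' @param speed belt speed, km/h (single value or function of time)
#' @param mu rolling friction coefficient
#' @return data.frame with p_cycle, p_pole, p_ski, pct_pole, pct_ski,
#'   pct_pole_left, pct_pole_right per cycle
#' @export
decompose_cycles <- function(cycles, t, p_left, p_right, mass, incline,
                             speed, mu = 0.016) {
  inc_of <- if (is.function(incline)) incline else function(tt)
    rep(incline, length(tt))
  spd_of <- if (is.function(speed)) speed else function(tt)
    rep(speed, length(tt))
  out <- cycles
  out$p_cycle <- out$p_pole <- out$p_ski <- NA_real_
  out$pct_pole <- out$pct_ski <- NA_real_
  out$pct_pole_left <- out$pct_pole_right <- NA_real_
  for (i in seq_len(nrow(cycles))) {
    sel <- t >= cycles$t_start[i] & t < cycles$t_end[i]
    if (!any(sel)) next
    pl <- p_left[sel]
    pr <- p_right[sel]
    if (anyNA(pl) || anyNA(pr)) next   # missing-data contract: propagate NA
    tt <- t[sel]
    p_cycle <- mean(external_work_rate(mass, inc_of(tt), spd_of(tt) / 3.6,
                                       mu = mu))
    p_pole_l <- mean(pl)
    p_pole_r <- mean(pr)
    p_pole <- p_pole_l + p_pole_r
    out$p_cycle[i] <- p_cycle
    out$p_pole[i] <- p_pole
    out$p_ski[i] <- p_cycle - p_pole
    if (p_cycle > 0) {
      out$pct_pole[i] <- 100 * p_pole / p_cycle
      out$pct_ski[i] <- 100 * (p_cycle - p_pole) / p_cycle
    }
    if (abs(p_pole) > 1e-12) {
      out$pct_pole_left[i] <- 100 * p_pole_l / p_pole
      out$pct_pole_right[i] <- 100 * p_pole_r / p_pole
    }
  }
  out
}

#' Full power pipeline for one recorded window
#'
#' Low-pass filters markers and forces, computes the CoM and its velocity,
#' aligns the force clock by the 10-N touchdown rule, resolves per-pole 3D
#' forces, and decomposes every cycle into pole and ski power.
#'
#' @param markers,force [sensor_stream()]s as produced by
#'   [generate_force_and_markers()] (or read from CSV)
#' @param cycles data.frame of cycle boundaries on the marker clock
#' @param mass skier mass, kg
#' @param incline,speed incline (%) and belt speed (km/h): constants or
#'   functions of time
#' @param mu rolling friction coefficient
#' @return output of [decompose_cycles()]
#' @export
power_pipeline <- function(markers, force, cycles, mass, incline, speed,
                           mu = 0.016) {
  mf <- markers
  mf$channels <- lapply(mf$channels, lowpass, rate = markers$rate)
  ff <- force
  ff$channels <- lapply(ff$channels, lowpass, rate = force$rate)
  com <- compute_com(mf, mass)
  vel <- com_velocity(com, mf$rate)
  al <- align_streams(ff, mf)
  p <- list()
  for (side in c("l", "r")) {
    axial <- al[[paste0("force_", side)]]
    handle <- marker_xyz(mf, paste0("pole_handle_", side))
    tip <- marker_xyz(mf, paste0("pole_tip_", side))
    fv <- pole_force_vector(ifelse(is.na(axial), 0, axial), handle, tip)
    p[[side]] <- pole_power(fv, vel)
    p[[side]][is.na(axial)] <- NA
  }
  decompose_cycles(cycles, al$t, p$l, p$r, mass, incline, speed, mu = mu)
}
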
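#' Skier profile for the synthetic trial generator
#'
#' Physiology defaults follow the cohort of thirteen elite male skiers the
#' analysis is designed around (mass 79.3 kg, VO2Max 69.5 mL/min/kg, HRMax
#' 193.5 bpm) with gear-specific gross efficiencies in the observed ranges.
#' VO2 and HR respond to workload with first-order (mono-exponential)
#' kinetics; HR additionally drifts linearly with time on task at `hr_drift`
#' percentage points of HRMax per lap (default 7.9/5, i.e. 7.9 pp between
#' laps 2 and 7), and arm-muscle TSI drifts at `tsi_arm_drift` pp per lap
#' (default -3.0/5).
#'
#' @param mass body mass, kg
#' @param vo2max maximal oxygen uptake, mL/min/kg
#' @param hrmax maximal heart rate, bpm
#' @param ge_by_gear named percent gross efficiency for G2, G3, G4
#' @param vo2_tau,hr_tau first-order time constants, s
#' @param hr_drift HR drift, pp of HRMax per lap
#' @param tsi_arm_drift arm TSI drift, pp per lap (negative = desaturation)
#' @param rer respiratory exchange ratio assumed for oxygen-equivalent
#'   conversion of the simulated metabolic demand
#' @param break_times start times of 30-s breaks, s since start of the
#'   initial part
#' @param tte time to exhaustion in the AOS, s
#' @param pole_frac true fraction of cycle work rate delivered through the
#'   poles (0-1)
#' @param lr_left left pole's share of pole power (0-1)
#' @param basal_met resting metabolic rate floor, W
#' @param seed integer seed making the whole trial reproducible
#' @export
skier_profile <- function(mass = 79.3, vo2max = 69.5, hrmax = 193.5,
                          ge_by_gear = c(G2 = 17.0, G3 = 14.9, G4 = 12.4),
                          vo2_tau = 25, hr_tau = 20,
                          hr_drift = 7.9 / 5, tsi_arm_drift = -3.0 / 5,
                          rer = 0.91, break_times = numeric(0), tte = 90,
                          pole_frac = 0.60, lr_left = 0.50,
                          basal_met = 120, seed = 1L) {
  stopifnot(mass > 0, vo2_tau > 0, hr_tau > 0, tte >= 0,
            all(c("G2", "G3", "G4") %in% names(ge_by_gear)),
            all(ge_by_gear > 0 & ge_by_gear < 30),
            pole_frac > 0, pole_frac < 1, lr_left > 0, lr_left < 1)
  structure(list(mass = mass, vo2max = vo2max, hrmax = hrmax,
                 ge_by_gear = ge_by_gear, vo2_tau = vo2_tau, hr_tau = hr_tau,
                 hr_drift = hr_drift, tsi_arm_drift = tsi_arm_drift,
                 rer = rer, break_times = break_times, tte = tte,
                 pole_frac = pole_frac, lr_left = lr_left,
                 basal_met = basal_met, seed = as.integer(seed)),
            class = "skier_profile")
}

#' Noise configuration for the generator
#'
#' All channels receive additive Gaussian noise; the study gives no
#' physiological noise magnitudes, so these are free parameters chosen to be
#' small relative to the signals they perturb. `nirs_gap_rate` injects 1-s
#' NIRS dropouts (the artefact the 3-s averaging rule exists to remove).
#'
#' @param imu_sd accelerometer noise, m/s^2
#' @param hr_sd heart-rate noise, bpm
#' @param vo2_sd noise on 10-s VO2 values, L/min
#' @param tsi_sd TSI noise, pp
#' @param force_sd axial pole-force noise, N
#' @param marker_sd marker position noise, m
#' @param baro_sd altitude noise, m
#' @param nirs_gap_rate expected 1-s NIRS gaps per minute
#' @export
noise_defaults <- function(imu_sd = 0.3, hr_sd = 1.0, vo2_sd = 0.05,
                           tsi_sd = 0.8, force_sd = 0.5, marker_sd = 0.002,
                           baro_sd = 0.3, nirs_gap_rate = 0.5) {
  list(imu_sd = imu_sd, hr_sd = hr_sd, vo2_sd = vo2_sd, tsi_sd = tsi_sd,
       force_sd = force_sd, marker_sd = marker_sd, baro_sd = baro_sd,
       nirs_gap_rate = nirs_gap_rate)
}

#' @rdname noise_defaults
#' @export
noise_free <- function() noise_defaults(0, 0, 0, 0, 0, 0, 0, 0)

# Movement-cycle parameters per gear. Periods sit in the observed
# cycle-rate range (about 29-36 cpm with headroom); the harmonic patterns
# encode the poling/leg-push phase structure that separates the gears:
# G2 one asymmetric pole push per two leg pushes, G3 a pole push with every
# leg push, G4 a symmetric push every other leg push.
gear_params <- function() {
  list(
    G2 = list(period = 1.75, ay = 2.0,
              fx = function(p) 1.2 * sin(p + 0.5) + 1.5 * sin(2 * p),
              fz = function(p) 1.8 * cos(p + 2.0) + 0.8 * cos(2 * p)),
    G3 = list(period = 1.90, ay = 2.6,
              fx = function(p) 2.4 * sin(p + 1.0) + 0.4 * sin(2 * p),
              fz = function(p) 1.0 * cos(2 * p + 0.6)),
    G4 = list(period = 1.65, ay = 2.2,
              fx = function(p) 0.8 * sin(p) + 1.0 * sin(3 * p),
              fz = function(p) 1.4 * cos(2 * p + 2.5))
  )
}

# Contiguous constant-gear blocks of a per-second gear vector.
gear_blocks <- function(gears) {
  r <- rle(gears)
  ends <- cumsum(r$lengths)
  data.frame(gear = r$values, t_start = c(0, ends[-length(ends)]),
             t_end = ends, stringsAsFactors = FALSE)
}

# Ground-truth cycle boundaries: whole cycles of the gear-specific period
# packed into each block; the trailing partial cycle is not a cycle.
cycles_from_blocks <- function(blocks) {
  gp <- gear_params()
  out <- lapply(seq_len(nrow(blocks)), function(i) {
    g <- blocks$gear[i]
    if (!g %in% names(gp)) return(NULL)
    T <- gp[[g]]$period
    n <- floor((blocks$t_end[i] - blocks$t_start[i]) / T)
    if (n < 1) return(NULL)
    st <- blocks$t_start[i] + (0:(n - 1)) * T
    data.frame(t_start = st, t_end = st + T, gear = g,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      gear = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Cycle phase (radians) at arbitrary times, given the per-second gear
# vector. Times in non-cycling (Other) blocks get NA.
cycle_phase_at <- function(tv, gears) {
  gp <- gear_params()
  blocks <- gear_blocks(gears)
  phase <- rep(NA_real_, length(tv))
  for (i in seq_len(nrow(blocks))) {
    g <- blocks$gear[i]
    if (!g %in% names(gp)) next
    sel <- tv >= blocks$t_start[i] & tv < blocks$t_end[i]
    phase[sel] <- 2 * pi *
      ((tv[sel] - blocks$t_start[i]) %% gp[[g]]$period) / gp[[g]]$period
  }
  phase
}

# Slowly varying aperiodic signal for non-cycling (Other) windows.
aperiodic_signal <- function(tv, amp = 0.5) {
  f <- stats::runif(3, 0.05, 0.25)
  ph <- stats::runif(3, 0, 2 * pi)
  a <- amp * stats::runif(3, 0.4, 1)
  a[1] * sin(2 * pi * f[1] * tv + ph[1]) +
    a[2] * sin(2 * pi * f[2] * tv + ph[2]) +
    a[3] * sin(2 * pi * f[3] * tv + ph[3])
}

#' Generate the chest-IMU stream for a gear/speed schedule
#'
#' The mediolateral channel (`acc_y`) is quasi-periodic with exactly one
#' minimum per cycle at the leftmost body position (cycle start; leftward
#' lateral acceleration is negative by convention). The other accelerometer
#' axes carry gear-specific harmonic signatures. Non-cycling windows
#' (`Other`) carry an aperiodic low-frequency signal.
#'
#' @param gears per-second gear labels (G2/G3/G4/Other)
#' @param speeds per-second belt speed, km/h (same length)
#' @param noise output of [noise_defaults()]
#' @param rate sampling rate, Hz
#' @param seed integer seed
#' @return list of `stream` (a [sensor_stream()]) and `cycles`
#'   (ground-truth boundaries)
#' @export
generate_imu <- function(gears, speeds, noise = noise_defaults(),
                         rate = 256, seed = 1L) {
  stopifnot(length(gears) == length(speeds))
  bad <- setdiff(unique(gears), c("G2", "G3", "G4", "Other"))
  if (length(bad)) stop("unknown gear label: ", paste(bad, collapse = ", "))
  set.seed(seed)
  dur <- length(gears)
  n <- ceiling(dur * rate)
  tv <- (seq_len(n) - 1) / rate
  phase <- cycle_phase_at(tv, gears)
  gear_at <- gears[pmin(floor(tv) + 1, dur)]
  gp <- gear_params()

  acc_x <- acc_y <- numeric(n)
  acc_z <- rep(9.81, n)
  for (g in names(gp)) {
    sel <- which(gear_at == g & !is.na(phase))
    if (!length(sel)) next
    p <- phase[sel]
    acc_y[sel] <- -gp[[g]]$ay * cos(p)
    acc_x[sel] <- gp[[g]]$fx(p)
    acc_z[sel] <- 9.81 + gp[[g]]$fz(p)
  }
  oth <- which(is.na(phase))
  if (length(oth)) {
    acc_x[oth] <- aperiodic_signal(tv[oth])
    acc_y[oth] <- aperiodic_signal(tv[oth])
    acc_z[oth] <- 9.81 + aperiodic_signal(tv[oth], amp = 0.3)
  }
  cyc <- !is.na(phase)
  gyro_x <- gyro_y <- gyro_z <- numeric(n)
  gyro_x[cyc] <- 0.5 * sin(phase[cyc])
  gyro_y[cyc] <- 0.5 * cos(phase[cyc])
  gyro_z[cyc] <- 0.3 * sin(2 * phase[cyc])
  ch <- list(acc_x = acc_x, acc_y = acc_y, acc_z = acc_z,
             gyro_x = gyro_x, gyro_y = gyro_y, gyro_z = gyro_z)
  if (noise$imu_sd > 0)
    ch <- lapply(ch, function(x) x + stats::rnorm(n, 0, noise$imu_sd))
  list(stream = sensor_stream("imu", rate, ch),
       cycles = cycles_from_blocks(gear_blocks(gears)))
}

# Exact discretisation of dx/dt = (demand - x) / tau on a 1-s grid.
first_order <- function(demand, tau, init = demand[1], dt = 1) {
  stopifnot(tau > 0)
  a <- exp(-dt / tau)
  x <- numeric(length(demand))
  prev <- init
  for (i in seq_along(demand)) {
    prev <- demand[i] + (prev - demand[i]) * a
    x[i] <- prev
  }
  x
}

# Per-second metabolic demand (W) for a schedule + gear assignment:
# work-positive cycling seconds demand 100 * work / GE(gear), everything
# else (breaks, downhill tuck, Other) sits at the basal floor.
metabolic_demand <- function(schedule, gears, profile, mu = 0.016) {
  work <- external_work_rate(profile$mass, schedule$incline,
                             schedule$speed / 3.6, mu = mu)
  demand <- rep(profile$basal_met, nrow(schedule))
  act <- gears %in% c("G2", "G3", "G4") & work > 0
  demand[act] <- 100 * work[act] / profile$ge_by_gear[gears[act]]
  demand
}

#' Generate breath-by-breath (10-s mixing chamber) VO2 and 1-Hz HR
#'
#' Metabolic demand follows the external work rate divided by the
#' gear-specific gross efficiency (converted to VO2 via the oxygen
#' equivalent at the profile RER); measured VO2 follows first-order kinetics
#' with time constant `vo2_tau` and is binned into 10-s means. HR demand is
#' an affine function of relative VO2 demand plus the linear time-on-task
#' drift, filtered with `hr_tau`. Both are capped at the profile maxima.
#'
#' @param schedule per-second schedule from [protocol_schedule()]
#' @param gears per-second gear labels (breaks already marked `Other`)
#' @param profile a [skier_profile()]
#' @param noise output of [noise_defaults()]
#' @param seed integer seed
#' @return list of `vo2` (0.1-Hz stream, L/min), `hr` (1-Hz stream, bpm)
#'   and `demand` (per-second truth: metabolic watts, VO2 and HR demand)
#' @export
generate_breath_series <- function(schedule, gears, profile,
                                   noise = noise_defaults(), seed = 1L) {
  set.seed(seed)
  vo2max_l <- profile$vo2max * profile$mass / 1000
  demand_w <- metabolic_demand(schedule, gears, profile)
  vo2_demand <- pmin(vo2_for_metabolic_rate(demand_w, profile$rer), vo2max_l)
  basal_l <- vo2_for_metabolic_rate(profile$basal_met, profile$rer)
  vo2 <- pmin(first_order(vo2_demand, profile$vo2_tau, init = basal_l),
              vo2max_l)

  # HR demand: affine in relative VO2 demand (fraction of VO2Max), plus the
  # lap-linear drift term (zero before the initial part begins).
  t_ip <- schedule$t - min(schedule$t[schedule$phase != "fam"])
  lap_len <- 180
  drift_pp <- profile$hr_drift * pmax(0, t_ip / lap_len - 1)
  drift_pp[schedule$phase == "fam"] <- 0
  if (any(schedule$phase == "aos")) {
    ip_end <- max(t_ip[schedule$phase == "ip"])
    drift_pp[schedule$phase == "aos"] <-
      profile$hr_drift * max(0, ip_end / lap_len - 1)
  }
  hr_frac <- 0.33 + 0.58 * vo2_demand / vo2max_l
  hr_demand <- pmin(hr_frac, 1) * profile$hrmax +
    drift_pp / 100 * profile$hrmax
  hr <- pmin(first_order(hr_demand, profile$hr_tau,
                         init = 0.45 * profile$hrmax), profile$hrmax)

  n10 <- floor(length(vo2) / 10)
  vo2_10s <- colMeans(matrix(vo2[seq_len(n10 * 10)], nrow = 10))
  if (noise$vo2_sd > 0)
    vo2_10s <- vo2_10s + stats::rnorm(n10, 0, noise$vo2_sd)
  vo2_10s <- pmin(pmax(vo2_10s, 0), vo2max_l)
  if (noise$hr_sd > 0)
    hr <- pmin(hr + stats::rnorm(length(hr), 0, noise$hr_sd), profile$hrmax)

  list(vo2 = sensor_stream("vo2", 0.1, list(vo2 = vo2_10s)),
       hr = sensor_stream("hr", 1, list(hr = hr)),
       demand = data.frame(t = schedule$t, met_w = demand_w,
                           vo2_demand = vo2_demand, hr_demand = hr_demand))
}

#' Generate 10-Hz NIRS tissue saturation (leg and arm)
#'
#' TSI is a baseline minus an intensity-proportional desaturation (smoothed
#' with a short time constant), plus an arm-specific linear drift across
#' laps; 1-s dropout gaps are injected at `nirs_gap_rate` per minute as NA
#' runs, mimicking the quality-filtered gaps the 3-s averaging rule removes.
#'
#' @inheritParams generate_breath_series
#' @export
generate_nirs <- function(schedule, gears, profile,
                          noise = noise_defaults(), seed = 1L) {
  set.seed(seed)
  vo2max_l <- profile$vo2max * profile$mass / 1000
  demand_w <- metabolic_demand(schedule, gears, profile)
  intensity <- pmin(vo2_for_metabolic_rate(demand_w, profile$rer) /
                      vo2max_l, 1)
  intensity <- first_order(intensity, tau = 8, init = intensity[1])
  t_ip <- schedule$t - min(schedule$t[schedule$phase != "fam"])
  drift <- profile$tsi_arm_drift * pmax(0, t_ip / 180 - 1)
  drift[schedule$phase == "fam"] <- 0
  leg_1hz <- 68 - 8 * intensity
  arm_1hz <- 62 - 10 * intensity + drift
  up <- function(x) rep(x, each = 10)
  n <- 10 * length(leg_1hz)
  leg <- up(leg_1hz)
  arm <- up(arm_1hz)
  if (noise$tsi_sd > 0) {
    leg <- leg + stats::rnorm(n, 0, noise$tsi_sd)
    arm <- arm + stats::rnorm(n, 0, noise$tsi_sd)
  }
  n_gaps <- stats::rpois(1, noise$nirs_gap_rate * length(leg_1hz) / 60)
  if (n_gaps > 0) {
    starts <- sample.int(n - 10, n_gaps)
    for (s in starts) {
      leg[s:(s + 9)] <- NA
      arm[s:(s + 9)] <- NA
    }
  }
  sensor_stream("nirs", 10, list(tsi_leg = leg, tsi_arm = arm))
}

# Rigid-body marker offsets (m) relative to the CoM trajectory, standing
# posture; constant offsets keep the computed CoM an exact translate of the
# true one, so CoM velocity is preserved.
marker_offsets <- function() {
  m <- rbind(
    hip_l      = c(0.00, 0.10, -0.05),  hip_r      = c(0.00, -0.10, -0.05),
    shoulder_l = c(0.00, 0.15, 0.45),   shoulder_r = c(0.00, -0.15, 0.45),
    elbow_l    = c(0.10, 0.25, 0.20),   elbow_r    = c(0.10, -0.25, 0.20),
    wrist_l    = c(0.25, 0.30, 0.00),   wrist_r    = c(0.25, -0.30, 0.00),
    knee_l     = c(0.05, 0.12, -0.55),  knee_r     = c(0.05, -0.12, -0.55),
    ankle_l    = c(0.00, 0.12, -0.95),  ankle_r    = c(0.00, -0.12, -0.95),
    boot_l     = c(0.10, 0.12, -0.98),  boot_r     = c(0.10, -0.12, -0.98),
    ski_front_l = c(0.60, 0.12, -1.00), ski_front_r = c(0.60, -0.12, -1.00),
    ski_rear_l = c(-0.50, 0.12, -1.00), ski_rear_r = c(-0.50, -0.12, -1.00)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

#' Generate pole-force and marker streams for a gear/speed window
#'
#' The centre of mass advances at belt speed (ground-equivalent frame; x
#' forward, y left-positive, z up) with small cycle-locked oscillations;
#' body markers ride rigidly on it. Each cycle of a poling gear contains one
#' double-pole action: half-sine axial force impulses on both poles during a
#' 0.4-s ground contact in which the pole tip stays planted (so the pole
#' leans progressively backward), and a raised tip during the swing. Impulse
#' amplitudes are scaled per cycle so that the cycle-average summed pole
#' power equals `pole_frac` of the cycle work rate, split `lr_left` /
#' `1 - lr_left` between the poles. Axial force exceeds 10 N only during
#' ground contact.
#'
#' @param gears per-second gear labels
#' @param speeds per-second belt speed, km/h
#' @param inclines per-second incline, percent
#' @param profile a [skier_profile()] (mass, pole_frac, lr_left)
#' @param noise output of [noise_defaults()]
#' @param sync_offset true clock offset of the force stream relative to the
#'   kinematic clock, s (recorded in the truth, not in the stream header:
#'   recovering it is [align_streams()]'s job)
#' @param seed integer seed
#' @param mu rolling friction coefficient
#' @return list of `force` (100-Hz stream: force_l, force_r), `markers`
#'   (200-Hz stream, `<marker>_<axis>` channels) and `truth` (per-cycle
#'   pole fraction and left share, plus `sync_offset`)
#' @export
generate_force_and_markers <- function(gears, speeds, inclines, profile,
                                       noise = noise_defaults(),
                                       sync_offset = 0.12, seed = 1L,
                                       mu = 0.016) {
  stopifnot(length(gears) == length(speeds),
            length(gears) == length(inclines))
  set.seed(seed)
  rate_m <- 200
  dur <- length(gears)
  n <- dur * rate_m
  tv <- (seq_len(n) - 1) / rate_m
  sec <- pmin(floor(tv) + 1, dur)
  v_mps <- speeds[sec] / 3.6
  phase <- cycle_phase_at(tv, gears)
  ph0 <- ifelse(is.na(phase), 0, phase)

  com <- cbind(x = cumsum(v_mps) / rate_m + 0.05 * sin(ph0),
               y = 0.12 * cos(ph0),
               z = 1.05 + 0.04 * cos(2 * ph0))
  vel <- apply(com, 2, num_gradient, dt = 1 / rate_m)

  cycles <- cycles_from_blocks(gear_blocks(gears))
  contact_dur <- 0.4
  plant_frac <- 0.1
  pole_len <- 1.0
  handle_off <- list(l = c(0.20, 0.35, -0.05), r = c(0.20, -0.35, -0.05))

  # pole shaft direction (handle toward tip) during contact: forward-down,
  # at 15 degrees off vertical at plant and lift-off and 30 degrees at
  # mid-contact. The symmetric angle profile makes the cycle-average pole
  # power second-order insensitive to small force-clock alignment errors,
  # and the tip's lowest point falls at the plant instant (the kinematic
  # touchdown used for alignment).
  pole_dir <- function(theta, side_sign) {
    d <- cbind(sin(theta), side_sign * 0.05, -cos(theta))
    d / sqrt(rowSums(d^2))
  }
  force <- list(l = numeric(n), r = numeric(n))
  tip <- list(l = NULL, r = NULL)
  for (side in c("l", "r")) {
    ho <- handle_off[[side]]
    handle <- sweep(com, 2, ho, "+")
    # swing default: tip held forward and raised
    usw <- pole_dir(rep(-20 * pi / 180, n), sign(ho[2]))
    tip[[side]] <- handle + 0.75 * pole_len * usw
  }
  truth_frac <- rep(NA_real_, nrow(cycles))
  for (j in seq_len(nrow(cycles))) {
    ts <- cycles$t_start[j]
    te <- cycles$t_end[j]
    Tj <- te - ts
    t_plant <- ts + plant_frac * Tj
    t_off <- min(t_plant + contact_dur, te)
    idx_cyc <- which(tv >= ts & tv < te)
    idx_ct <- which(tv >= t_plant & tv < t_off)
    if (!length(idx_ct) || !length(idx_cyc)) next
    s <- (tv[idx_ct] - t_plant) / (t_off - t_plant)
    shape <- sin(pi * s)
    pu <- list()
    for (side in c("l", "r")) {
      ho <- handle_off[[side]]
      theta <- (15 + 15 * sin(pi * s)) * pi / 180
      u <- pole_dir(theta, sign(ho[2]))
      tip[[side]][idx_ct, ] <- com[idx_ct, , drop = FALSE] +
        matrix(ho, length(idx_ct), 3, byrow = TRUE) + pole_len * u
      pu[[side]] <- shape * rowSums(u * vel[idx_ct, , drop = FALSE])
      # smooth swing transitions (lift-off, and pre-plant of the next
      # cycle) so the tip trajectory has no steps for the filter to ring on
      blend <- function(idx, w, th_a, len_a, th_b, len_b) {
        if (!length(idx)) return()
        th <- th_a + (th_b - th_a) * w
        ln <- len_a + (len_b - len_a) * w
        ub <- pole_dir(th, sign(ho[2]))
        tip[[side]][idx, ] <<- com[idx, , drop = FALSE] +
          matrix(ho, length(idx), 3, byrow = TRUE) + ln * ub
      }
      bl <- 0.15
      i_out <- which(tv >= t_off & tv < t_off + bl)
      blend(i_out, (1 - cos(pi * (tv[i_out] - t_off) / bl)) / 2,
            15 * pi / 180, pole_len, -20 * pi / 180, 0.75 * pole_len)
      i_in <- which(tv >= t_plant - bl & tv < t_plant)
      blend(i_in, (1 - cos(pi * (tv[i_in] - (t_plant - bl)) / bl)) / 2,
            -20 * pi / 180, 0.75 * pole_len, 15 * pi / 180, pole_len)
    }
    p_cycle <- mean(external_work_rate(profile$mass, inclines[sec[idx_cyc]],
                                       v_mps[idx_cyc], mu = mu))
    target <- profile$pole_frac * p_cycle
    mean_l <- sum(pu$l) / length(idx_cyc)
    mean_r <- sum(pu$r) / length(idx_cyc)
    if (mean_l <= 0 || mean_r <= 0) next
    force$l[idx_ct] <- profile$lr_left * target / mean_l * shape
    force$r[idx_ct] <- (1 - profile$lr_left) * target / mean_r * shape
    truth_frac[j] <- profile$pole_frac
  }

  mo <- marker_offsets()
  ch <- list()
  for (i in seq_len(nrow(mo))) {
    nm <- rownames(mo)[i]
    for (a in c("x", "y", "z")) {
      val <- com[, a] + mo[i, a]
      if (noise$marker_sd > 0)
        val <- val + stats::rnorm(n, 0, noise$marker_sd)
      ch[[paste0(nm, "_", a)]] <- val
    }
  }
  for (side in c("l", "r")) {
    ho <- handle_off[[side]]
    for (a in c("x", "y", "z")) {
      hv <- com[, a] + ho[match(a, c("x", "y", "z"))]
      ch[[paste0("pole_handle_", side, "_", a)]] <- hv
      ch[[paste0("pole_tip_", side, "_", a)]] <- tip[[side]][, a]
    }
  }
  markers <- sensor_stream("markers", rate_m, ch)

  # force stream on its own (shifted) clock: sample the 200-Hz force at
  # 100 Hz at times t - sync_offset of the kinematic clock
  rate_f <- 100
  tf <- (seq_len(dur * rate_f) - 1) / rate_f
  fl <- stats::approx(tv, force$l, xout = tf + sync_offset, rule = 2)$y
  fr <- stats::approx(tv, force$r, xout = tf + sync_offset, rule = 2)$y
  if (noise$force_sd > 0) {
    fl <- fl + stats::rnorm(length(fl), 0, noise$force_sd)
    fr <- fr + stats::rnorm(length(fr), 0, noise$force_sd)
  }
  cycles$pole_frac <- truth_frac
  cycles$lr_left <- ifelse(is.na(truth_frac), NA, profile$lr_left)
  list(force = sensor_stream("pole_force", rate_f,
                             list(force_l = fl, force_r = fr)),
       markers = markers,
       truth = list(cycles = cycles, sync_offset = sync_offset))
}

# per-second gear assignment: natural gear per segment, G3 in the AOS,
# Other during the simulated downhill and during breaks
segment_gear <- c(S1 = "G3", S2 = "G4", S3 = "G2", S4 = "Other",
                  AOS = "G3")

assign_gears <- function(schedule, break_times, break_duration = 30) {
  gears <- unname(segment_gear[schedule$segment])
  ip0 <- min(schedule$t[schedule$phase == "ip"])
  for (b in break_times) {
    sel <- schedule$phase == "ip" & schedule$t >= ip0 + b &
      schedule$t < ip0 + b + break_duration
    gears[sel] <- "Other"
  }
  gears
}

#' Generate a complete synthetic mass-start trial
#'
#' Produces the full multi-rate sensor bundle of one skier -- chest IMU
#' (256 Hz) with barometric altitude (64 Hz), HR (1 Hz), VO2 (10-s values),
#' NIRS TSI (10 Hz), and pole force (100 Hz) + markers (200 Hz) over the
#' recorded laps -- together with a ground-truth sidecar (cycle boundaries
#' and gears, per-second demand, per-cycle power split). Deterministic given
#' the profile seed.
#'
#' @param spec a [build_protocol()] spec
#' @param profile a [skier_profile()]
#' @param noise output of [noise_defaults()]
#' @param include_familiarization prepend the low-intensity familiarization
#'   pass (part of the full protocol; skippable when only the mass-start is
#'   analysed)
#' @param marker_laps initial-part laps with motion capture + pole force
#'   (the study recorded every other lap to bound data volume; the power
#'   analysis uses laps 1-3)
#' @param aos_horizon longest supported AOS, s
#' @return list with `streams` (named [sensor_stream()]s), `truth`, `spec`,
#'   `profile`
#' @export
generate_trial <- function(spec, profile, noise = noise_defaults(),
                           include_familiarization = FALSE,
                           marker_laps = c(1, 3), aos_horizon = 600) {
  stopifnot(inherits(spec, "protocol_spec"), inherits(profile, "skier_profile"))
  if (profile$tte > aos_horizon)
    stop("tte exceeds the stream horizon (", aos_horizon, " s)")
  sched <- protocol_schedule(spec, tte = profile$tte,
                             include_familiarization = include_familiarization)
  gears <- assign_gears(sched, profile$break_times, spec$break_duration)
  seed <- profile$seed

  imu <- generate_imu(gears, sched$speed, noise, seed = seed)
  breath <- generate_breath_series(sched, gears, profile, noise,
                                   seed = seed + 1L)
  nirs <- generate_nirs(sched, gears, profile, noise, seed = seed + 2L)

  # barometric altitude consistent with incline x speed integration
  set.seed(seed + 3L)
  alt_1hz <- cumsum(sched$speed / 3.6 * sched$incline / 100)
  tb <- (seq_len(64 * nrow(sched)) - 1) / 64
  alt <- stats::approx(sched$t, alt_1hz, xout = tb, rule = 2)$y
  if (noise$baro_sd > 0) alt <- alt + stats::rnorm(length(alt), 0, noise$baro_sd)
  baro <- sensor_stream("baro", 64, list(altitude = alt))

  # force + markers over the recorded IP laps (contiguous span; unrecorded
  # laps inside the span are NA, as with the study's every-other-lap capture)
  fm <- NULL
  if (length(marker_laps)) {
    ip <- sched[sched$phase == "ip", ]
    span <- range(marker_laps)
    sel <- ip$lap >= span[1] & ip$lap <= span[2]
    w <- ip[sel, ]
    wg <- gears[sched$phase == "ip"][sel]
    fm <- generate_force_and_markers(wg, w$speed, w$incline, profile, noise,
                                     seed = seed + 4L)
    na_laps <- setdiff(seq.int(span[1], span[2]), marker_laps)
    if (length(na_laps)) {
      rel <- w$t - w$t[1]
      na_sec <- rel[w$lap %in% na_laps]
      blank <- function(stream) {
        st <- stream_time(stream) - stream$t0_offset
        drop <- floor(st) %in% na_sec
        stream$channels <- lapply(stream$channels,
                                  function(x) { x[drop] <- NA; x })
        stream
      }
      fm$force <- blank(fm$force)
      fm$markers <- blank(fm$markers)
    }
    t_w0 <- w$t[1]
    fm$force$t0_offset <- t_w0       # nominal; true offset adds sync_offset
    fm$markers$t0_offset <- t_w0
    fm$truth$cycles$t_start <- fm$truth$cycles$t_start + t_w0
    fm$truth$cycles$t_end <- fm$truth$cycles$t_end + t_w0
  }

  per_second <- cbind(sched, gear = gears,
                      breath$demand[, c("met_w", "vo2_demand", "hr_demand")])
  truth <- list(cycles = imu$cycles, per_second = per_second,
                ge_by_gear = profile$ge_by_gear,
                pole = if (!is.null(fm)) fm$truth else NULL)
  streams <- list(imu = imu$stream, baro = baro, hr = breath$hr,
                  vo2 = breath$vo2, nirs = nirs)
  if (!is.null(fm)) {
    streams$pole_force <- fm$force
    streams$markers <- fm$markers
  }
  list(streams = streams, truth = truth, spec = spec, profile = profile)
}

#' Sample a cohort of skier profiles
#'
#' Draws anthropometrics and physiology around the study cohort means
#' (mass 79.3 +/- 5.2 kg, VO2Max 69.5 +/- 3.6 mL/min/kg, HRMax 193.5 +/- 7
#' bpm), with gear efficiencies, breaks and TTE spread as in the observed
#' field.
#'
#' @param n number of skiers
#' @param seed integer seed
#' @return list of [skier_profile()]s
#' @export
cohort_profiles <- function(n = 13, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    ge3 <- stats::rnorm(1, 14.9, 0.5)
    skier_profile(
      mass = stats::rnorm(1, 79.3, 5.2),
      vo2max = stats::rnorm(1, 69.5, 3.6),
      hrmax = stats::rnorm(1, 193.5, 7.0),
      ge_by_gear = c(G2 = ge3 + 2.1, G3 = ge3, G4 = ge3 - 2.5),
      tte = stats::runif(1, 45, 135),
      seed = seed * 1000L + i
    )
  })
}

#' Simulate the separate-day gross-efficiency protocol
#'
#' Twelve 4-min submaximal bouts (G2 at 12% incline, 6-9 km/h; G3 at 5%,
#' 10-16 km/h; G4 at 2%, 15-24 km/h), each measured as the last-minute mean
#' VO2 of the simulated mixing-chamber series. The returned table feeds
#' [gross_efficiency()] directly, so on noiseless input the computed GE
#' equals the profile's gear efficiencies (up to the residual of the
#' first-order kinetics over a 4-min stage).
#'
#' @param profile a [skier_profile()]
#' @param noise output of [noise_defaults()]
#' @param drop_bouts optional indices of bouts to omit (the study lost one
#'   skier's highest-intensity G2 bout)
#' @return data.frame with gear, incline, speed, vo2, rer, mass
#' @export
simulate_ge_bouts <- function(profile, noise = noise_defaults(),
                              drop_bouts = integer(0)) {
  grid <- rbind(
    data.frame(gear = "G2", incline = 12, speed = c(6, 7, 8, 9)),
    data.frame(gear = "G3", incline = 5, speed = c(10, 12, 14, 16)),
    data.frame(gear = "G4", incline = 2, speed = c(15, 18, 21, 24))
  )
  if (length(drop_bouts)) grid <- grid[-drop_bouts, ]
  out <- lapply(seq_len(nrow(grid)), function(i) {
    sched <- data.frame(t = 0:239, phase = "ip", lap = 1L,
                        segment = "S1", speed = grid$speed[i],
                        incline = grid$incline[i])
    br <- generate_breath_series(sched, rep(grid$gear[i], 240), profile,
                                 noise, seed = profile$seed + 100L + i)
    vo2 <- br$vo2$channels$vo2
    data.frame(gear = grid$gear[i], incline = grid$incline[i],
               speed = grid$speed[i], vo2 = mean(utils::tail(vo2, 6)),
               rer = profile$rer, mass = profile$mass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
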
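#' Resample a stream to the 1-Hz master timeline
#'
#' Each output second is the mean of the samples falling in `[t, t+1)` after
#' applying the stream's clock offset (plus any extra correction). Streams
#' slower than 1 Hz (the 10-s mixing-chamber VO2 values) are step-held: each
#' value covers all the seconds of its bin. Seconds with no samples are NA.
#'
#' @param stream a [sensor_stream()]
#' @param channel channel name (default: first channel)
#' @param offset additional clock correction, s
#' @param t_end last second of the master timeline (exclusive); default is
#'   the stream's own span
#' @return data.frame `t`, `value` with one row per second from 0
#' @export
resample_1hz <- function(stream, channel = names(stream$channels)[1],
                         offset = 0, t_end = NULL) {
  x <- stream$channels[[channel]]
  if (is.null(x)) stop("no channel ", channel)
  tt <- stream_time(stream) + offset
  if (stream$rate < 1) {
    # step-hold: replicate each value across its whole bin
    hold <- round(1 / stream$rate)
    tt <- rep(tt, each = hold) + rep(seq_len(hold) - 1, length(x))
    x <- rep(x, each = hold)
  }
  if (is.null(t_end)) t_end <- floor(max(tt)) + 1
  sec <- floor(tt)
  keep <- sec >= 0 & sec < t_end & !is.na(x)
  sums <- tapply(x[keep], sec[keep], mean)
  out <- data.frame(t = seq_len(t_end) - 1, value = NA_real_)
  idx <- as.integer(names(sums)) + 1
  out$value[idx] <- as.numeric(sums)
  out
}

#' Clean a 10-Hz NIRS series into 1-Hz values
#'
#' Quality filtering leaves 1-s dropouts in the TSI signal. Each fully
#' missing second is filled with the mean of its two neighbouring seconds,
#' then a centred 3-s moving mean, sampled at 1 Hz, removes the residual
#' seams. Gaps longer than 1 s remain missing.
#'
#' @param nirs a [sensor_stream()]
#' @param channel channel name
#' @param offset clock correction, s
#' @param t_end master-timeline end, s
#' @return data.frame `t`, `value`
#' @export
clean_nirs <- function(nirs, channel = "tsi_leg", offset = 0, t_end = NULL) {
  one <- resample_1hz(nirs, channel, offset, t_end)
  v <- one$value
  gap <- which(is.na(v))
  for (i in gap) {
    lo <- if (i > 1) v[i - 1] else NA
    hi <- if (i < length(v)) v[i + 1] else NA
    if (!is.na(lo) && !is.na(hi)) v[i] <- (lo + hi) / 2
    # neighbours missing too: gap > 1 s, stays NA
  }
  sm <- v
  for (i in seq_along(v)) {
    w <- v[max(1, i - 1):min(length(v), i + 1)]
    sm[i] <- if (anyNA(w)) NA else mean(w)
  }
  one$value <- sm
  one
}

#' Build the fused 1-Hz master timeline for one trial
#'
#' Fuses belt schedule, HR, VO2, NIRS and per-cycle records into one table
#' with a row per second: t, speed, incline, phase, lap, segment, HR,
#' %HRMax, VO2 (mL/min/kg), %VO2Max, TSI leg/arm, gear, CL, CR and the
#' power split of the covering cycle. Per-second gear is the gear of the
#' covering cycle (`Other` when none covers it). Missing values stay NA.
#'
#' @param trial output of [generate_trial()] (or an equivalent list of
#'   streams read from CSV plus `spec`/`profile`)
#' @param cycles classified cycle records (e.g. [process_cycles()]); NULL
#'   uses the ground-truth cycles with kinematics attached
#' @param power optional per-cycle power decomposition to join by cycle
#' @param offsets named list of per-stream clock corrections, s
#' @return data.frame, one row per second
#' @export
build_master_timeline <- function(trial, cycles = NULL, power = NULL,
                                  offsets = list()) {
  sched <- trial$truth$per_second
  n <- nrow(sched)
  off <- function(nm) if (!is.null(offsets[[nm]])) offsets[[nm]] else 0
  hr <- resample_1hz(trial$streams$hr, "hr", off("hr"), t_end = n)$value
  vo2_l <- resample_1hz(trial$streams$vo2, "vo2", off("vo2"), t_end = n)$value
  tsi_leg <- clean_nirs(trial$streams$nirs, "tsi_leg", off("nirs"),
                        t_end = n)$value
  tsi_arm <- clean_nirs(trial$streams$nirs, "tsi_arm", off("nirs"),
                        t_end = n)$value
  vo2_rel <- vo2_l * 1000 / trial$profile$mass   # mL/min/kg
  out <- data.frame(
    t = sched$t, phase = sched$phase, lap = sched$lap,
    segment = sched$segment, speed = sched$speed, incline = sched$incline,
    hr = hr, pct_hrmax = relative_intensity(hr, trial$profile$hrmax),
    vo2 = vo2_rel,
    pct_vo2max = relative_intensity(vo2_rel, trial$profile$vo2max),
    tsi_leg = tsi_leg, tsi_arm = tsi_arm,
    stringsAsFactors = FALSE
  )
  if (is.null(cycles)) {
    cycles <- trial$truth$cycles
    sp <- stats::approxfun(sched$t, sched$speed, rule = 2)
    cycles <- cycle_kinematics(cycles, sp)
  }
  annotate_cycles(out, cycles, power)
}

# join per-cycle fields onto the per-second table
annotate_cycles <- function(master, cycles, power = NULL) {
  n <- nrow(master)
  master$gear <- "Other"
  master$cl <- master$cr <- NA_real_
  master$p_cycle <- master$pct_pole <- master$pct_ski <- NA_real_
  master$pct_pole_left <- master$pct_pole_right <- NA_real_
  if (!nrow(cycles)) return(master)
  if (is.unsorted(cycles$t_start)) cycles <- cycles[order(cycles$t_start), ]
  if (any(cycles$t_start[-1] < cycles$t_end[-nrow(cycles)] - 1e-9))
    stop("overlapping cycles")
  if (!is.null(power)) {
    cycles <- merge(cycles, power[, c("t_start", "p_cycle", "pct_pole",
                                      "pct_ski", "pct_pole_left",
                                      "pct_pole_right")],
                    by = "t_start", all.x = TRUE, suffixes = c("", ".p"))
  }
  idx <- findInterval(master$t + 0.5, cycles$t_start)
  cover <- idx >= 1 & (master$t + 0.5) < cycles$t_end[pmax(idx, 1)]
  for (col in c("gear", "cl", "cr")) {
    if (col %in% names(cycles))
      master[[col]][cover] <- cycles[[col]][idx[cover]]
  }
  if (!is.null(power)) {
    for (col in c("p_cycle", "pct_pole", "pct_ski", "pct_pole_left",
                  "pct_pole_right"))
      master[[col]][cover] <- cycles[[col]][idx[cover]]
  }
  master
}

#' Restrict a master timeline to the comparison windows
#'
#' Mean values are compared over laps 1-3 of the initial part (so that all
#' skiers, including those who took breaks, contribute the same load) and,
#' for the AOS, over the first three 15-s speed steps only.
#'
#' @param master a master timeline
#' @param window `"ip_laps_1_3"` or `"aos_first_3_steps"`
#' @export
timeline_window <- function(master,
                            window = c("ip_laps_1_3", "aos_first_3_steps")) {
  window <- match.arg(window)
  if (window == "ip_laps_1_3") {
    master[master$phase == "ip" & master$lap <= 3, ]
  } else {
    aos <- master[master$phase == "aos", ]
    aos[aos$t - min(aos$t) < 45, ]
  }
}
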
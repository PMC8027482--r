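#' Simulated mass-start protocol
#'
#' The simulated mass-start consists of a 21-min initial part (IP) of seven
#' identical 3-min laps, each made of four segments -- a moderate uphill (S1),
#' a flat segment (S2), a steep uphill (S3) and a simulated downhill (S4) --
#' immediately followed by an incremental all-out sprint (AOS) at 5% incline,
#' starting at 20 km/h and increasing by 1 km/h every 15 s until exhaustion.
#' Skiers may take an unlimited number of 30-s breaks during the IP while the
#' belt keeps running; performance rank is breaks first, then time to
#' exhaustion (TTE) in the AOS.
#'
#' Segment inclines and within-lap durations are configuration, not measured
#' ground truth: the defaults (S1 5%/60 s, S2 2%/35 s, S3 12%/45 s,
#' S4 -3%/40 s) pair each segment with the incline at which its natural gear
#' is used in the efficiency protocol (G3 at 5%, G4 at 2%, G2 at 12%).
#'
#' @param config optional named list (or path to a YAML file) overriding any
#'   of: `laps`, `segments` (data.frame with columns `label`, `incline`,
#'   `speed`, `fam_speed`, `duration`), `aos_incline`, `aos_start_speed`,
#'   `aos_step`, `aos_step_duration`, `break_duration`.
#' @return an object of class `protocol_spec`.
#' @export
build_protocol <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("protocol config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  spec <- list(
    laps = 7L,
    lap_duration = 180,
    segments = data.frame(
      label     = c("S1", "S2", "S3", "S4"),
      incline   = c(5, 2, 12, -3),
      speed     = c(18, 24, 14, 25),
      fam_speed = c(14, 20, 8, 18),
      duration  = c(60, 35, 45, 40),
      stringsAsFactors = FALSE
    ),
    aos_incline = 5,
    aos_start_speed = 20,
    aos_step = 1,
    aos_step_duration = 15,
    break_duration = 30
  )
  for (nm in names(config)) {
    if (!nm %in% names(spec)) stop("unknown protocol field: ", nm)
    if (nm == "segments") {
      seg <- as.data.frame(config$segments)
      for (col in names(seg)) {
        if (!col %in% names(spec$segments)) stop("unknown segment column: ", col)
        spec$segments[[col]] <- seg[[col]]
      }
    } else {
      spec[[nm]] <- config[[nm]]
    }
  }
  validate_protocol(spec)
}

validate_protocol <- function(spec) {
  seg <- spec$segments
  if (!setequal(seg$label, c("S1", "S2", "S3", "S4")))
    stop("segments must be labelled S1..S4")
  if (any(seg$duration <= 0)) stop("segment durations must be positive")
  if (any(seg$speed < 0) || any(seg$fam_speed < 0))
    stop("segment speeds must be non-negative")
  if (abs(sum(seg$duration) - spec$lap_duration) > 1e-9)
    stop("segment durations must sum to ", spec$lap_duration, " s per lap")
  if (spec$laps < 1) stop("laps must be >= 1")
  if (spec$aos_step_duration <= 0) stop("aos_step_duration must be positive")
  if (spec$aos_start_speed < 0 || spec$aos_step < 0)
    stop("AOS speeds must be non-negative")
  structure(spec, class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("Simulated mass-start protocol\n")
  cat(sprintf("  initial part: %d laps x %g s = %g s\n",
              x$laps, x$lap_duration, x$laps * x$lap_duration))
  print(x$segments, row.names = FALSE)
  cat(sprintf("  AOS: %g%% incline, %g km/h + %g km/h per %g s\n",
              x$aos_incline, x$aos_start_speed, x$aos_step,
              x$aos_step_duration))
  invisible(x)
}

#' Total duration of the initial part, in seconds
#' @param spec a `protocol_spec`
#' @export
initial_part_duration <- function(spec) spec$laps * spec$lap_duration

#' Belt speed during the all-out sprint
#'
#' The AOS speed schedule is a staircase: `aos_start_speed` plus one
#' `aos_step` for every completed `aos_step_duration` interval.
#'
#' @param spec a `protocol_spec`
#' @param t seconds since the start of the AOS (vectorised)
#' @return speed in km/h
#' @export
aos_speed_at <- function(spec, t) {
  if (any(t < 0)) stop("t must be >= 0 (seconds since AOS start)")
  spec$aos_start_speed + floor(t / spec$aos_step_duration) * spec$aos_step
}

#' Per-second protocol schedule
#'
#' Expands a protocol into one row per second: phase (`fam`, `ip`, `aos`),
#' lap, segment, belt speed (km/h) and incline (%). Time `t` starts at 0 at
#' the beginning of the first included phase. Break windows are a property of
#' the skier, not the belt, and are therefore not represented here.
#'
#' @param spec a `protocol_spec`
#' @param tte time to exhaustion in the AOS, s (0 for no AOS rows)
#' @param include_familiarization prepend the low-intensity familiarization
#'   pass of the same track (segment speeds `fam_speed`)?
#' @return data.frame with columns t, phase, lap, segment, speed, incline
#' @export
protocol_schedule <- function(spec, tte = 0, include_familiarization = FALSE) {
  seg <- spec$segments
  seg_idx <- rep.int(seq_len(nrow(seg)), seg$duration)   # within-lap seconds
  lap_sec <- function(speeds) {
    data.frame(segment = seg$label[seg_idx], speed = speeds[seg_idx],
               incline = seg$incline[seg_idx], stringsAsFactors = FALSE)
  }
  blocks <- list()
  if (include_familiarization) {
    fam <- do.call(rbind, replicate(spec$laps, lap_sec(seg$fam_speed),
                                    simplify = FALSE))
    fam$phase <- "fam"
    fam$lap <- rep(seq_len(spec$laps), each = spec$lap_duration)
    blocks <- c(blocks, list(fam))
  }
  ip <- do.call(rbind, replicate(spec$laps, lap_sec(seg$speed),
                                 simplify = FALSE))
  ip$phase <- "ip"
  ip$lap <- rep(seq_len(spec$laps), each = spec$lap_duration)
  blocks <- c(blocks, list(ip))
  if (tte > 0) {
    ta <- seq_len(ceiling(tte)) - 1
    aos <- data.frame(segment = "AOS", speed = aos_speed_at(spec, ta),
                      incline = spec$aos_incline, phase = "aos",
                      lap = NA_integer_, stringsAsFactors = FALSE)
    blocks <- c(blocks, list(aos))
  }
  out <- do.call(rbind, blocks)
  out$t <- seq_len(nrow(out)) - 1
  rownames(out) <- NULL
  out[, c("t", "phase", "lap", "segment", "speed", "incline")]
}

#' Rank skiers by breaks, then time to exhaustion
#'
#' All skiers finishing the initial part without breaks are ranked before
#' those requiring one, two or three breaks; within the same number of
#' breaks, longer TTE in the AOS ranks first. Exact ties (same breaks and
#' TTE) keep input order and are flagged.
#'
#' @param outcomes data.frame with columns `skier_id`, `breaks`, `tte`
#' @return the input reordered with columns `rank` and `tie` added
#' @export
rank_skiers <- function(outcomes) {
  stopifnot(is.data.frame(outcomes), nrow(outcomes) > 0,
            all(c("skier_id", "breaks", "tte") %in% names(outcomes)))
  if (anyDuplicated(outcomes$skier_id)) stop("duplicate skier_ids")
  if (any(outcomes$breaks < 0) || any(outcomes$tte < 0))
    stop("breaks and tte must be non-negative")
  ord <- order(outcomes$breaks, -outcomes$tte)
  out <- outcomes[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  key <- paste(out$breaks, out$tte)
  out$tie <- key %in% key[duplicated(key)]
  rownames(out) <- NULL
  out
}
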
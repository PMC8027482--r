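#' External work rate on an inclined treadmill
#'
#' Work rate is the sum of power against gravity,
#' \eqn{P_g = m g \sin(\alpha) v}, and against rolling friction,
#' \eqn{P_f = m g \cos(\alpha) \mu v}, where the treadmill angle is
#' \eqn{\alpha = \arctan(\mathrm{grade}/100)}. Inclines are given in percent
#' grade; at the steepest grade used here (12%) the arctan convention differs
#' from the small-angle one by under 1%.
#'
#' @param mass skier mass, kg
#' @param grade treadmill incline, percent (signed; vectorised)
#' @param speed belt speed, m/s (vectorised)
#' @param mu rolling friction coefficient (roller-ski category 2 wheels:
#'   0.016)
#' @param g gravitational acceleration, m/s^2
#' @return work rate in W; components available via [work_rate_components()]
#' @export
external_work_rate <- function(mass, grade, speed, mu = 0.016, g = 9.81) {
  if (any(mass <= 0)) stop("mass must be positive")
  if (any(speed < 0)) stop("speed must be non-negative")
  if (any(mu < 0)) stop("mu must be non-negative")
  alpha <- atan(grade / 100)
  mass * g * speed * (sin(alpha) + mu * cos(alpha))
}

#' @rdname external_work_rate
#' @export
work_rate_components <- function(mass, grade, speed, mu = 0.016, g = 9.81) {
  alpha <- atan(grade / 100)
  data.frame(pg = mass * g * sin(alpha) * speed,
             pf = mass * g * cos(alpha) * mu * speed)
}

# Non-protein respiratory-quotient energy equivalents of oxygen, kJ per L O2
# (Lusk-family table as tabulated by Peronnet & Massicotte), interpolated
# linearly between rows; RER is clamped to [0.70, 1.00] for the lookup since
# supra-1.0 RER reflects non-metabolic CO2.
rq_table <- data.frame(
  rq = seq(0.70, 1.00, by = 0.05),
  kcal_per_l = c(4.686, 4.739, 4.801, 4.862, 4.924, 4.985, 5.047)
)

#' Oxygen energy equivalent for a given RER
#' @param rer respiratory exchange ratio (VCO2/VO2); values above 1.0 are
#'   clamped to 1.0, values below 0.70 are an error
#' @return energy equivalent, kJ per litre O2
#' @export
oxygen_equivalent <- function(rer) {
  if (any(rer < 0.70)) stop("RER below 0.70 is outside the non-protein table")
  rer <- pmin(rer, 1.00)
  4.184 * stats::approx(rq_table$rq, rq_table$kcal_per_l, xout = rer)$y
}

#' Metabolic rate from oxygen uptake
#'
#' @param vo2 oxygen uptake, L/min
#' @param rer respiratory exchange ratio selecting the energy equivalent
#' @return metabolic rate, W
#' @export
metabolic_rate <- function(vo2, rer) {
  if (any(vo2 <= 0)) stop("vo2 must be positive")
  vo2 * oxygen_equivalent(rer) * 1000 / 60
}

#' Oxygen uptake needed to supply a metabolic rate (inverse of
#' [metabolic_rate()])
#' @param watts metabolic rate, W
#' @inheritParams metabolic_rate
#' @return VO2 in L/min
#' @export
vo2_for_metabolic_rate <- function(watts, rer) {
  watts / (oxygen_equivalent(rer) * 1000 / 60)
}

#' Gross efficiency of submaximal bouts
#'
#' GE is external work rate divided by metabolic rate, in percent. Bouts are
#' 4-min stages at fixed gear/incline/speed; metabolic rate comes from the
#' last-minute mean VO2 and the bout-average RER.
#'
#' @param bouts data.frame with columns `gear` (G2/G3/G4), `incline` (%),
#'   `speed` (km/h), `vo2` (L/min, last-minute mean), `rer`, `mass` (kg)
#' @param mu rolling friction coefficient
#' @return `bouts` with columns `work_rate`, `met_rate` and `ge` added
#' @export
gross_efficiency <- function(bouts, mu = 0.016) {
  stopifnot(all(c("gear", "incline", "speed", "vo2", "rer", "mass")
                %in% names(bouts)))
  if (any(bouts$rer < 0.7 | bouts$rer > 1.3)) stop("RER outside [0.7, 1.3]")
  bouts$work_rate <- external_work_rate(bouts$mass, bouts$incline,
                                        bouts$speed / 3.6, mu = mu)
  bouts$met_rate <- metabolic_rate(bouts$vo2, bouts$rer)
  if (any(bouts$met_rate <= 0)) stop("metabolic rate must be positive")
  bouts$ge <- 100 * bouts$work_rate / bouts$met_rate
  bouts
}

#' Aggregate bout efficiencies per gear and overall
#'
#' Overall GE is the unweighted arithmetic mean over the available bouts (11
#' or 12 in the study protocol; fewer bouts are carried with `n_bouts` as the
#' provenance record).
#'
#' @param bouts output of [gross_efficiency()]
#' @return list with `ge_per_gear` (named means), `ge_average` and `n_bouts`
#' @export
aggregate_efficiency <- function(bouts) {
  if (!"ge" %in% names(bouts)) bouts <- gross_efficiency(bouts)
  list(ge_per_gear = tapply(bouts$ge, bouts$gear, mean),
       ge_average = mean(bouts$ge),
       n_bouts = nrow(bouts))
}

#' Maximal oxygen uptake from 10-s mixing-chamber values
#'
#' VO2Max is defined as the highest 30-s moving average of the 10-s values,
#' i.e. the maximum over means of three consecutive values.
#'
#' @param vo2_10s numeric series of 10-s VO2 values (any unit)
#' @return the highest 30-s moving average, same unit
#' @export
vo2max_from_series <- function(vo2_10s) {
  n <- length(vo2_10s)
  if (n < 3) stop("need at least three 10-s values for a 30-s average")
  max(vapply(seq_len(n - 2), function(i) mean(vo2_10s[i:(i + 2)]), 0))
}

#' Relative intensity as percent of a personal maximum
#'
#' Used for %HRMax and %VO2Max; the personal maximum is the highest value
#' measured for that skier at any time during the tests.
#'
#' @param x measured series
#' @param personal_max the skier's maximum, same unit
#' @return 100 * x / personal_max
#' @export
relative_intensity <- function(x, personal_max) {
  if (length(personal_max) != 1 || !is.finite(personal_max) ||
      personal_max <= 0)
    stop("personal_max must be a single positive number")
  100 * x / personal_max
}
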
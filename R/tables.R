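# Embedded per-skier summary tables of the thirteen-skier elite cohort:
# cohort anthropometrics/physiology, the per-skier mass-start physiology
# (rank, breaks, TTE, lap-1-3 relative intensities, peaks, VO2Max, GE), and
# the per-skier kinematics/power summary (gear shares, power split, CL/CR
# over the first three AOS steps). Shipped as CSV with an integrity
# checksum; NA rows mark the two skiers whose pole-force recordings failed.

fixture_md5 <- c(
  table1_cohort.csv     = "a612aef8c6f0920a9894b7b3b6ff26c3",
  table2_physiology.csv = "5b8a72eb5f1925617f204811a391708e",
  table3_kinematics.csv = "e4841c818bee63faadcf6772bc87819f"
)

load_fixture <- function(name) {
  path <- system.file("extdata", name, package = "skimass")
  if (path == "") stop("fixture not installed: ", name)
  got <- unname(tools::md5sum(path))
  if (got != fixture_md5[[name]])
    stop("fixture checksum mismatch for ", name)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Embedded cohort summary tables
#'
#' `cohort_table()` gives cohort-level anthropometric and physiological
#' means/SDs; `skier_physiology()` one row per skier of mass-start
#' physiology and performance-determining variables; `skier_kinematics()`
#' one row per skier of gear distribution, power split and AOS cycle
#' characteristics (power columns NA for the two skiers with failed
#' pole-force recordings). Files are verified against an MD5 checksum at
#' load time.
#'
#' @return a data.frame
#' @export
cohort_table <- function() load_fixture("table1_cohort.csv")

#' @rdname cohort_table
#' @export
skier_physiology <- function() load_fixture("table2_physiology.csv")

#' @rdname cohort_table
#' @export
skier_kinematics <- function() load_fixture("table3_kinematics.csv")

#' One merged summary row per skier
#' @return physiology and kinematics tables joined on rank
#' @export
skier_summaries <- function() {
  merge(skier_physiology(), skier_kinematics(), by = "rank")
}
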
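# Closed-form quantities for the wet-lab assays: bead-normalized killing
# efficiency, proliferation normalization, caliper tumor volume with the
# humane-endpoint flag, and linear standard-curve calibration.

#' Bead-count record
#'
#' @param events Non-negative target-cell event count.
#' @param beads Positive counting-bead event count.
#' @return A `BeadCount` list.
#' @export
bead_count <- function(events, beads) {
  assert_that(is_count(events), "events must be a non-negative integer")
  assert_that(is_count(beads) && beads > 0, "beads must be a positive integer")
  structure(list(events = as.numeric(events), beads = as.numeric(beads)),
            class = "BeadCount")
}

#' T-cell killing efficiency
#'
#' `[1 - (TC_e/beads_e) / (TC_c/beads_c)] * 100` where the `e` sample is
#' the experimental coculture and the `c` sample the control (effector
#' cells lacking the target-specific TCR). Negative values (more surviving
#' targets than control) are reported as-is, never clipped.
#'
#' @param tc_e,tc_c [bead_count()] records for the experimental and
#'   control samples.
#' @return Killing efficiency in percent (<= 100).
#' @examples
#' killing_efficiency(bead_count(50, 100), bead_count(100, 100))  # 50
#' @export
killing_efficiency <- function(tc_e, tc_c) {
  assert_that(inherits(tc_e, "BeadCount") && inherits(tc_c, "BeadCount"),
              "arguments must be bead_count() records")
  assert_that(tc_c$events > 0, "control target count must be positive")
  ratio_e <- tc_e$events / tc_e$beads
  ratio_c <- tc_c$events / tc_c$beads
  (1 - ratio_e / ratio_c) * 100
}

#' Bead-normalized cell count
#'
#' Proliferated-cell events divided by counting-bead events.
#'
#' @param cells Non-negative cell event count.
#' @param beads Positive bead event count.
#' @return `cells / beads`.
#' @export
bead_normalized_count <- function(cells, beads) {
  assert_that(is_count(cells), "cells must be a non-negative integer")
  assert_that(is_count(beads) && beads > 0, "beads must be a positive integer")
  cells / beads
}

#' Caliper tumor volume and humane endpoint
#'
#' `V = 0.5 * a * b^2` with `a` the major and `b` the minor axis in mm; the
#' endpoint flag is raised when the volume reaches the 1500 mm^3 limit. If
#' the axes are given in the wrong order they are swapped with a warning.
#'
#' @param a_mm,b_mm Major and minor tumor axes in millimetres (positive).
#' @param endpoint_mm3 Endpoint volume, default 1500.
#' @return List with `volume_mm3` and logical `endpoint`.
#' @examples
#' tumor_volume(30, 10)  # 1500 mm^3, endpoint TRUE
#' @export
tumor_volume <- function(a_mm, b_mm, endpoint_mm3 = 1500) {
  assert_that(is_scalar_number(a_mm) && a_mm > 0 &&
                is_scalar_number(b_mm) && b_mm > 0,
              "axes must be positive numbers")
  if (a_mm < b_mm) {
    warning("major axis smaller than minor axis; swapping")
    tmp <- a_mm; a_mm <- b_mm; b_mm <- tmp
  }
  v <- 0.5 * a_mm * b_mm^2
  list(volume_mm3 = v, endpoint = v >= endpoint_mm3)
}

#' Linear standard-curve calibration
#'
#' Ordinary least-squares fit `reading = slope * conc + intercept` to the
#' known standards, with inversion of unknown readings back to
#' concentrations. Readings outside the standards' reading range are
#' flagged as extrapolation.
#'
#' @param concs Known standard concentrations (>= 2 distinct values).
#' @param readings Measured readings, same length.
#' @return A `StandardCurve` list: slope, intercept, r2, and the standards.
#' @export
standard_curve <- function(concs, readings) {
  assert_that(is.numeric(concs) && is.numeric(readings) &&
                length(concs) == length(readings),
              "concs and readings must be numeric vectors of equal length")
  assert_that(length(unique(concs)) >= 2,
              "at least two distinct standard concentrations are required")
  fit <- stats::lm(readings ~ concs)
  co <- stats::coef(fit)
  ss_tot <- sum((readings - mean(readings))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(co[2]), intercept = unname(co[1]), r2 = r2,
                 concs = concs, readings = readings),
            class = "StandardCurve")
}

#' @rdname standard_curve
#' @param curve A `StandardCurve`.
#' @param reading Reading(s) to invert.
#' @return `invert_reading` returns a data.frame with `concentration` and
#'   an `extrapolated` flag.
#' @export
invert_reading <- function(curve, reading) {
  assert_that(inherits(curve, "StandardCurve"), "curve must be a StandardCurve")
  scale <- max(abs(curve$readings), 1)
  assert_that(abs(curve$slope) > 1e-10 * scale,
              "cannot invert a zero-slope standard curve")
  conc <- (reading - curve$intercept) / curve$slope
  rng <- range(curve$readings)
  data.frame(reading = reading, concentration = conc,
             extrapolated = reading < rng[1] | reading > rng[2])
}
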
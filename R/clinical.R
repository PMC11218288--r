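#' Clinical motor-function evaluation
#'
#' Therapist-entered record for one patient visit: manual muscle testing
#' (MMT) grades for the assessed muscle groups, active range of motion
#' (ROM) per joint axis, Brunnstrom recovery stage, and an optional pain
#' score. This is the input the whole engine is driven from.
#'
#' The three joint axes the target-shooting game maps are
#' `shoulder_azimuth` (horizontal adduction/abduction),
#' `shoulder_elevation` (flexion) and `elbow` (flexion), each as an active
#' range `c(min_deg, max_deg)`.
#'
#' @param mmt_grades Integer vector of MMT grades, each in 0-5, one per
#'   assessed muscle group.
#' @param rom Named list of length-2 numeric vectors `c(min, max)` in
#'   degrees; must contain `shoulder_azimuth`, `shoulder_elevation`, `elbow`.
#' @param brunnstrom_stage `"IV"` or `"V"` (the mild-to-moderate stages the
#'   game targets).
#' @param pain_score Optional integer 0-10 (numeric rating scale).
#' @return A `clinical_evaluation` object.
#' @export
#' @examples
#' ev <- clinical_evaluation(
#'   mmt_grades = c(3, 3, 4),
#'   rom = list(shoulder_azimuth = c(0, 90),
#'              shoulder_elevation = c(0, 90),
#'              elbow = c(0, 90)),
#'   brunnstrom_stage = "IV"
#' )
#' requirements_from_evaluation(ev)
clinical_evaluation <- function(mmt_grades, rom, brunnstrom_stage,
                                pain_score = NULL) {
  ev <- structure(
    list(mmt_grades = as.numeric(mmt_grades),
         rom = lapply(rom, as.numeric),
         brunnstrom_stage = as.character(brunnstrom_stage),
         pain_score = if (is.null(pain_score)) NULL else as.numeric(pain_score)),
    class = "clinical_evaluation")
  issues <- validate_evaluation(ev, report = TRUE)
  if (length(issues)) {
    stop("invalid clinical evaluation:\n  ",
         paste(issues, collapse = "\n  "), call. = FALSE)
  }
  ev
}

#' @export
print.clinical_evaluation <- function(x, ...) {
  cat("<clinical_evaluation>\n")
  cat("  MMT grades:", paste(x$mmt_grades, collapse = ", "),
      sprintf("(pooled %.2f)", aggregate_strength_requirement(x$mmt_grades)), "\n")
  for (j in names(x$rom)) {
    cat(sprintf("  ROM %-19s [%g, %g] deg\n", j, x$rom[[j]][1], x$rom[[j]][2]))
  }
  cat("  Brunnstrom stage:", x$brunnstrom_stage, "\n")
  if (!is.null(x$pain_score)) cat("  Pain score:", x$pain_score, "/10\n")
  invisible(x)
}

#' Validate a clinical evaluation
#'
#' Checks the record's invariants (grades in 0-5, ROM min <= max, stage IV
#' or V, required joints present, pain in 0-10). With `report = TRUE` the
#' violations are returned as a character vector instead of erroring, so a
#' front-end can show them all at once.
#'
#' @param eval A `clinical_evaluation` (or a bare list with the same fields).
#' @param report If `TRUE`, return the violation messages (empty when
#'   valid); if `FALSE` (default), return the evaluation unchanged or error.
#' @return The evaluation, or a character vector of violations.
#' @export
validate_evaluation <- function(eval, report = FALSE) {
  issues <- character()
  g <- eval$mmt_grades
  if (length(g) == 0) {
    issues <- c(issues, "no MMT grades recorded")
  } else if (any(!is.finite(g)) || any(g < 0 | g > 5)) {
    issues <- c(issues, "MMT grade out of 0-5")
  }
  required <- c("shoulder_azimuth", "shoulder_elevation", "elbow")
  missing <- setdiff(required, names(eval$rom))
  if (length(missing)) {
    issues <- c(issues, paste0("missing ROM for joint: ",
                               paste(missing, collapse = ", ")))
  }
  for (j in names(eval$rom)) {
    r <- eval$rom[[j]]
    if (length(r) != 2 || any(!is.finite(r))) {
      issues <- c(issues, paste0("ROM for ", j, " must be c(min, max) degrees"))
    } else if (r[1] > r[2]) {
      issues <- c(issues, paste0("ROM min exceeds max for ", j))
    }
  }
  if (!eval$brunnstrom_stage %in% c("IV", "V")) {
    issues <- c(issues, "Brunnstrom stage must be 'IV' or 'V'")
  }
  if (!is.null(eval$pain_score) &&
      (!is.finite(eval$pain_score) || eval$pain_score < 0 || eval$pain_score > 10)) {
    issues <- c(issues, "pain score out of 0-10")
  }
  if (report) return(issues)
  if (length(issues)) {
    stop("invalid clinical evaluation:\n  ",
         paste(issues, collapse = "\n  "), call. = FALSE)
  }
  eval
}

#' Pool MMT grades into one strength requirement
#'
#' The engine carries a single continuous muscle-strength requirement in
#' MMT-grade units, the arithmetic mean of the per-muscle-group grades
#' (grades 3, 3, 4 pool to 3.33).
#'
#' @param grades Numeric vector of MMT grades in 0-5.
#' @return The mean grade, a real number in `[0, 5]`.
#' @export
aggregate_strength_requirement <- function(grades) {
  if (length(grades) == 0) stop("empty grade list", call. = FALSE)
  if (any(!is.finite(grades)) || any(grades < 0 | grades > 5)) {
    stop("MMT grade out of 0-5", call. = FALSE)
  }
  mean(grades)
}

#' Derive motor-function requirements from a clinical evaluation
#'
#' The controller's state: a required angular span per joint axis and one
#' pooled strength requirement. Each range requirement is the joint's
#' active ROM span clamped to the clinical feature bound of 90 degrees
#' (the rehabilitation motions for Brunnstrom IV-V patients use shoulder
#' adduction/abduction, shoulder flexion and elbow flexion within 0-90
#' degrees).
#'
#' @param eval A [clinical_evaluation()].
#' @param feature_bound Upper clinical bound on each axis requirement,
#'   degrees.
#' @return A `motor_requirements` object with fields `range_requirement`
#'   (named numeric, degrees) and `strength_requirement` (grade units).
#' @export
requirements_from_evaluation <- function(eval, feature_bound = 90) {
  eval <- validate_evaluation(eval)
  rng <- vapply(eval$rom, function(r) min(r[2] - r[1], feature_bound), numeric(1))
  motor_requirements(range_requirement = rng,
                     strength_requirement = aggregate_strength_requirement(eval$mmt_grades))
}

#' Motor-function requirements
#'
#' @param range_requirement Named numeric, required angular span per joint
#'   axis in degrees, each in `[0, 90]`.
#' @param strength_requirement Pooled strength requirement in `[0, 5]`
#'   MMT-grade units.
#' @return A `motor_requirements` object.
#' @export
motor_requirements <- function(range_requirement, strength_requirement) {
  if (any(range_requirement < 0 | range_requirement > 90)) {
    stop("range requirements must lie in [0, 90] degrees", call. = FALSE)
  }
  if (strength_requirement < 0 || strength_requirement > 5) {
    stop("strength requirement must lie in [0, 5]", call. = FALSE)
  }
  structure(list(range_requirement = range_requirement,
                 strength_requirement = strength_requirement),
            class = "motor_requirements")
}

#' @export
print.motor_requirements <- function(x, ...) {
  cat("<motor_requirements>\n")
  for (j in names(x$range_requirement)) {
    cat(sprintf("  range %-19s %6.1f deg\n", j, x$range_requirement[[j]]))
  }
  cat(sprintf("  strength requirement  %6.2f (MMT grade units)\n",
              x$strength_requirement))
  invisible(x)
}

#' Target spawn region from motor requirements
#'
#' Targets may appear anywhere the required motion can reach: azimuth and
#' elevation from 0 up to the (margin-shrunk) axis requirement, and a
#' reach interval derived from the elbow-flexion requirement under the
#' linear convention `reach(theta) = 1 - theta/180` (full extension, 0
#' degrees flexion, gives reach 1.0; the clinical 90-degree flexion gives
#' 0.5). The safety margin shrinks only the upper angular ends.
#'
#' @param req A [motor_requirements()] object with axes `shoulder_azimuth`,
#'   `shoulder_elevation`, `elbow`.
#' @param safety_margin Fraction in `[0, 1)` trimmed off the demanding end
#'   of each shoulder axis.
#' @return A `spawn_region` object: `azimuth` and `elevation` intervals in
#'   degrees, `reach` interval as a fraction of arm length in `[0, 1]`.
#' @export
spawn_region_from_requirements <- function(req, safety_margin = 0) {
  stopifnot(inherits(req, "motor_requirements"))
  if (safety_margin < 0 || safety_margin >= 1) {
    stop("safety margin must lie in [0, 1)", call. = FALSE)
  }
  rr <- req$range_requirement
  needed <- c("shoulder_azimuth", "shoulder_elevation", "elbow")
  if (!all(needed %in% names(rr))) {
    stop("requirements must cover shoulder_azimuth, shoulder_elevation, elbow",
         call. = FALSE)
  }
  reach_of <- function(theta) 1 - theta / 180
  structure(
    list(azimuth = c(0, (1 - safety_margin) * rr[["shoulder_azimuth"]]),
         elevation = c(0, (1 - safety_margin) * rr[["shoulder_elevation"]]),
         reach = c(reach_of(rr[["elbow"]]), reach_of(0))),
    class = "spawn_region")
}

#' @export
print.spawn_region <- function(x, ...) {
  cat(sprintf(
    "<spawn_region> azimuth [%g, %g] deg, elevation [%g, %g] deg, reach [%.3f, %.3f]\n",
    x$azimuth[1], x$azimuth[2], x$elevation[1], x$elevation[2],
    x$reach[1], x$reach[2]))
  invisible(x)
}
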
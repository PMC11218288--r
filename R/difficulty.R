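#' Default muscle-strength partition
#'
#' The three-set Ruspini partition (III, IV, V) of the continuous
#' MMT-grade axis used by the initial-difficulty model. Sets are
#' unit-spaced triangles peaking at grades 3, 4 and 5; the extreme sets
#' carry trapezoidal shoulders so degrees sum to 1 over the whole `[0, 5]`
#' support. A pooled requirement of 3.33 therefore fuzzifies to
#' III = 0.67, IV = 0.33, V = 0.
#'
#' @return A [fuzzy_partition()] over `[0, 5]`.
#' @export
strength_partition <- function() {
  fuzzy_partition(
    sets = list(
      III = mf_trapezoidal(0, 0, 3, 4),
      IV  = mf_triangular(3, 4, 5),
      V   = mf_trapezoidal(4, 5, 5, 5)
    ),
    support = c(0, 5)
  )
}

#' Game-parameter configuration
#'
#' Nominal (diameter, speed) pairs per strength set and the fixed session
#' geometry. Diameters must be strictly decreasing and speeds strictly
#' increasing from set III to set V: stronger patients get smaller,
#' faster targets.
#'
#' @param nominal_diameter Named numeric (metres), one value per set of
#'   `partition`, strictly decreasing in set order.
#' @param nominal_speed Named numeric (metres/second of target ascent),
#'   strictly increasing in set order.
#' @param round_duration Round length in seconds (default 30).
#' @param spawn_interval Seconds between consecutive target spawns.
#' @param ascent_distance Metres a target climbs before it disappears;
#'   with `nominal_speed` this sets each target's lifetime.
#' @param safety_margin Fraction trimmed from the demanding end of the
#'   spawn region (see [spawn_region_from_requirements()]).
#' @param partition Strength partition the nominal values attach to.
#' @return A `parameter_config` object.
#' @export
parameter_config <- function(nominal_diameter = c(III = 0.30, IV = 0.20, V = 0.12),
                             nominal_speed = c(III = 0.30, IV = 0.50, V = 0.75),
                             round_duration = 30,
                             spawn_interval = 3,
                             ascent_distance = 1.5,
                             safety_margin = 0,
                             partition = strength_partition()) {
  labels <- names(partition$sets)
  if (!setequal(names(nominal_diameter), labels) ||
      !setequal(names(nominal_speed), labels)) {
    stop("nominal values must be named after the partition sets", call. = FALSE)
  }
  nominal_diameter <- nominal_diameter[labels]
  nominal_speed <- nominal_speed[labels]
  if (any(diff(nominal_diameter) >= 0)) {
    stop("nominal diameters must be strictly decreasing from set III to V",
         call. = FALSE)
  }
  if (any(diff(nominal_speed) <= 0)) {
    stop("nominal speeds must be strictly increasing from set III to V",
         call. = FALSE)
  }
  stopifnot(round_duration > 0, spawn_interval > 0, ascent_distance > 0)
  structure(list(nominal_diameter = nominal_diameter,
                 nominal_speed = nominal_speed,
                 round_duration = round_duration,
                 spawn_interval = spawn_interval,
                 ascent_distance = ascent_distance,
                 safety_margin = safety_margin,
                 partition = partition),
            class = "parameter_config")
}

#' Map motor-function requirements to game parameters
#'
#' The "motor function to parameters" model: the spawn region comes from
#' the range requirements, while target diameter and ascent speed come
#' from fuzzifying the pooled strength requirement over the strength
#' partition and weighting each set's nominal value by its membership
#' degree. A requirement of exactly grade 4 activates set IV alone and
#' returns its nominal values; 3.33 mixes III and IV as 0.67/0.33.
#'
#' @param req A [motor_requirements()] object.
#' @param config A [parameter_config()].
#' @return A `game_parameters` object: `spawn_region`, `target_diameter`
#'   (m), `target_speed` (m/s), `target_lifetime` (s), `round_duration`
#'   (s), `spawn_interval` (s).
#' @export
#' @examples
#' req <- motor_requirements(
#'   c(shoulder_azimuth = 90, shoulder_elevation = 90, elbow = 90), 3.33)
#' motor_function_to_parameters(req, parameter_config())
motor_function_to_parameters <- function(req, config = parameter_config()) {
  stopifnot(inherits(req, "motor_requirements"),
            inherits(config, "parameter_config"))
  s <- req$strength_requirement
  if (s < 0 || s > 5) stop("strength requirement outside [0, 5]", call. = FALSE)
  deg <- fuzzify(s, config$partition)
  diameter <- weighted_defuzzify(deg, config$nominal_diameter)
  speed <- weighted_defuzzify(deg, config$nominal_speed)
  structure(
    list(spawn_region = spawn_region_from_requirements(req, config$safety_margin),
         target_diameter = diameter,
         target_speed = speed,
         target_lifetime = config$ascent_distance / speed,
         round_duration = config$round_duration,
         spawn_interval = config$spawn_interval),
    class = "game_parameters")
}

#' @export
print.game_parameters <- function(x, ...) {
  cat("<game_parameters>\n")
  cat(sprintf("  target diameter  %.3f m\n", x$target_diameter))
  cat(sprintf("  target speed     %.3f m/s (lifetime %.2f s)\n",
              x$target_speed, x$target_lifetime))
  cat(sprintf("  round duration   %g s, spawn every %g s\n",
              x$round_duration, x$spawn_interval))
  print(x$spawn_region)
  invisible(x)
}

#' Dynamic difficulty adjustment configuration
#'
#' The controller is two-stage. Stage 1 is a crisp comfort-band gate
#' motivated by the Yerkes-Dodson law: a per-round hit rate inside
#' `[lower_hit_threshold, upper_hit_threshold]` (default 50-70%) leaves
#' the requirements untouched. Stage 2, entered only outside the band,
#' is a Mamdani fuzzy module that decides *which* requirement moves and
#' by how much. Below the band, the share of misses that occurred beyond
#' `range_fraction_threshold` (default 70%) of the required range
#' apportions the reduction between the range requirement (misses far
#' out: range was the obstacle) and the strength requirement (misses
#' within comfortable range: target size/speed was the obstacle); the
#' magnitude scales with how far the hit rate sits below the band. Above
#' the band both requirements grow, split evenly, in proportion to the
#' excess hit rate.
#'
#' @param lower_hit_threshold,upper_hit_threshold The comfort band,
#'   fractions with `0 < lower < upper < 1`.
#' @param range_fraction_threshold A miss counts as "beyond range" when
#'   its position exceeds this fraction of the required range.
#' @param magnitude_rulebase The stage-2 [fuzzy_rulebase()]; default
#'   [dda_magnitude_rulebase()].
#' @return A `dda_config` object.
#' @export
dda_config <- function(lower_hit_threshold = 0.50,
                       upper_hit_threshold = 0.70,
                       range_fraction_threshold = 0.70,
                       magnitude_rulebase = dda_magnitude_rulebase()) {
  if (!(0 < lower_hit_threshold && lower_hit_threshold < upper_hit_threshold &&
        upper_hit_threshold < 1)) {
    stop("need 0 < lower < upper < 1 for the hit-rate thresholds", call. = FALSE)
  }
  if (range_fraction_threshold <= 0 || range_fraction_threshold >= 1) {
    stop("range_fraction_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(lower_hit_threshold = lower_hit_threshold,
                 upper_hit_threshold = upper_hit_threshold,
                 range_fraction_threshold = range_fraction_threshold,
                 magnitude_rulebase = magnitude_rulebase),
            class = "dda_config")
}

#' Default rule base for the DDA magnitude module
#'
#' Input: the beyond-range miss share on `[0, 1]` with a two-set Ruspini
#' partition (Low, High). Outputs: the signed range and strength
#' adjustments, each on `[-1, 1]` with the five-term partition
#' NL, NS, Z, PS, PL. The two rules encode the miss-location decision:
#' misses concentrated beyond the range threshold push the range
#' requirement down hard (NL) and the strength requirement down gently
#' (NS); misses within range do the opposite.
#'
#' @return A [fuzzy_rulebase()].
#' @export
dda_magnitude_rulebase <- function() {
  miss_part <- fuzzy_partition(
    list(Low = mf_triangular(0, 0, 1), High = mf_triangular(0, 1, 1)),
    support = c(0, 1))
  out_part <- fuzzy_partition(
    list(NL = mf_triangular(-1, -1, -0.5),
         NS = mf_triangular(-1, -0.5, 0),
         Z  = mf_triangular(-0.5, 0, 0.5),
         PS = mf_triangular(0, 0.5, 1),
         PL = mf_triangular(0.5, 1, 1)),
    support = c(-1, 1))
  fuzzy_rulebase(
    rules = list(
      list(if. = c(miss_beyond = "High"),
           then. = c(range_pct = "NL", strength_pct = "NS")),
      list(if. = c(miss_beyond = "Low"),
           then. = c(range_pct = "NS", strength_pct = "NL"))
    ),
    input_partitions = list(miss_beyond = miss_part),
    output_partitions = list(range_pct = out_part, strength_pct = out_part)
  )
}

#' Per-adjustment step sizes and requirement bounds
#'
#' The fuzzy module emits signed percentages of a maximum step; these
#' constants turn them into physical increments and keep the requirements
#' inside clinically meaningful bounds.
#'
#' @param max_range_step Degrees moved per full-amplitude adjustment.
#' @param max_strength_step Grade units moved per full-amplitude
#'   adjustment.
#' @param range_bounds,strength_bounds Length-2 clamping intervals for
#'   each requirement.
#' @return A `step_config` object.
#' @export
step_config <- function(max_range_step = 10,
                        max_strength_step = 0.5,
                        range_bounds = c(10, 90),
                        strength_bounds = c(0, 5)) {
  stopifnot(max_range_step > 0, max_strength_step > 0,
            range_bounds[1] < range_bounds[2],
            strength_bounds[1] < strength_bounds[2])
  structure(list(max_range_step = max_range_step,
                 max_strength_step = max_strength_step,
                 range_bounds = range_bounds,
                 strength_bounds = strength_bounds),
            class = "step_config")
}

#' Summarize one round of telemetry for the controller
#'
#' Reduces a round's hit/miss events to the two numbers the DDA needs:
#' the hit rate, and among the misses the share whose recorded position
#' (as a fraction of the required range at target disappearance) exceeded
#' the beyond-range threshold. A round with no misses has
#' `miss_beyond_fraction = 0` by convention; the gate, not that value,
#' decides at high hit rates.
#'
#' @param events A tibble of game events as produced by [run_round()], or
#'   any data frame with columns `kind` (`"hit"`/`"miss"` among others)
#'   and `fraction` (miss position, `NA` for non-miss rows).
#' @param dda A [dda_config()].
#' @return A `round_performance` object: `n_targets`, `n_hits`,
#'   `hit_rate`, `miss_positions`, `miss_beyond_fraction`.
#' @export
summarize_round <- function(events, dda = dda_config()) {
  stopifnot(is.data.frame(events), inherits(dda, "dda_config"))
  resolved <- events[events$kind %in% c("hit", "miss"), , drop = FALSE]
  n_targets <- nrow(resolved)
  if (n_targets == 0) stop("round contains no resolved targets", call. = FALSE)
  n_hits <- sum(resolved$kind == "hit")
  miss_positions <- resolved$fraction[resolved$kind == "miss"]
  round_performance(n_targets = n_targets, n_hits = n_hits,
                    miss_positions = miss_positions,
                    range_fraction_threshold = dda$range_fraction_threshold)
}

#' Round performance record
#'
#' @param n_targets,n_hits Target and hit counts, `n_hits <= n_targets`.
#' @param miss_positions Positions of the misses as fractions of the
#'   required range, each in `[0, 1]`.
#' @param range_fraction_threshold Threshold defining a "beyond range"
#'   miss.
#' @return A `round_performance` object.
#' @export
round_performance <- function(n_targets, n_hits, miss_positions = numeric(),
                              range_fraction_threshold = 0.70) {
  stopifnot(n_targets >= 1, n_hits >= 0, n_hits <= n_targets,
            length(miss_positions) == n_targets - n_hits)
  n_miss <- n_targets - n_hits
  structure(
    list(n_targets = n_targets,
         n_hits = n_hits,
         hit_rate = n_hits / n_targets,
         miss_positions = as.numeric(miss_positions),
         miss_beyond_fraction =
           if (n_miss == 0) 0
           else sum(miss_positions > range_fraction_threshold) / n_miss),
    class = "round_performance")
}

#' @export
print.round_performance <- function(x, ...) {
  cat(sprintf("<round_performance> %d/%d hits (%.0f%%), miss-beyond share %.2f\n",
              x$n_hits, x$n_targets, 100 * x$hit_rate, x$miss_beyond_fraction))
  invisible(x)
}

#' Compute the difficulty adjustment for one round
#'
#' Stage 1: if the hit rate lies inside the comfort band the output is
#' exactly `(0, 0)`. Stage 2 below the band: the Mamdani magnitude module
#' apportions a reduction between range and strength from the miss-location
#' share, and the (negative) amplitudes are scaled by how far the hit rate
#' sits below the lower threshold. Stage 2 above the band: both
#' requirements receive the same positive amplitude, proportional to the
#' excess over the upper threshold.
#'
#' @param perf A [round_performance()] (or output of [summarize_round()]).
#' @param dda A [dda_config()].
#' @return A `dda_adjustment` object: `range_pct` and `strength_pct` in
#'   `[-1, 1]` (signed percentages of the maximum step) and `gate`, one of
#'   `"reduce"`, `"hold"`, `"increase"`.
#' @export
compute_adjustment <- function(perf, dda = dda_config()) {
  stopifnot(inherits(perf, "round_performance"), inherits(dda, "dda_config"))
  h <- perf$hit_rate
  lo <- dda$lower_hit_threshold
  up <- dda$upper_hit_threshold
  if (h >= lo && h <= up) {
    return(new_adjustment(0, 0, "hold"))
  }
  if (h > up) {
    amplitude <- (h - up) / (1 - up)
    return(new_adjustment(amplitude, amplitude, "increase"))
  }
  severity <- (lo - h) / lo
  raw <- mamdani_evaluate(dda$magnitude_rulebase,
                          c(miss_beyond = perf$miss_beyond_fraction))
  new_adjustment(range_pct = severity * raw[["range_pct"]],
                 strength_pct = severity * raw[["strength_pct"]],
                 gate = "reduce")
}

new_adjustment <- function(range_pct, strength_pct, gate) {
  structure(list(range_pct = min(max(range_pct, -1), 1),
                 strength_pct = min(max(strength_pct, -1), 1),
                 gate = gate),
            class = "dda_adjustment")
}

#' @export
print.dda_adjustment <- function(x, ...) {
  cat(sprintf("<dda_adjustment> gate=%s range %+0.3f, strength %+0.3f (of max step)\n",
              x$gate, x$range_pct, x$strength_pct))
  invisible(x)
}

#' Apply an adjustment to the motor-function requirements
#'
#' Moves every joint-axis range requirement by the same signed fraction of
#' the maximum range step, and the strength requirement by its fraction of
#' the maximum strength step, clamping each to its bounds. A `(0, 0)`
#' adjustment is the identity.
#'
#' @param req A [motor_requirements()] object.
#' @param adj A `dda_adjustment` from [compute_adjustment()].
#' @param steps A [step_config()].
#' @return Updated [motor_requirements()].
#' @export
apply_adjustment <- function(req, adj, steps = step_config()) {
  stopifnot(inherits(req, "motor_requirements"),
            inherits(adj, "dda_adjustment"),
            inherits(steps, "step_config"))
  clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])
  rng <- clamp(req$range_requirement + adj$range_pct * steps$max_range_step,
               steps$range_bounds)
  stng <- clamp(req$strength_requirement + adj$strength_pct * steps$max_strength_step,
                steps$strength_bounds)
  motor_requirements(range_requirement = rng, strength_requirement = stng)
}

#' One full DDA step: telemetry in, new parameters out
#'
#' Composes [summarize_round()], [compute_adjustment()],
#' [apply_adjustment()] and [motor_function_to_parameters()], returning
#' every intermediate so a session log can record the controller's
#' reasoning.
#'
#' @param req Current [motor_requirements()].
#' @param events Round telemetry (see [summarize_round()]).
#' @param dda A [dda_config()].
#' @param steps A [step_config()].
#' @param config A [parameter_config()].
#' @return A list with `requirements` (updated), `parameters` (updated
#'   [game_parameters]), `performance`, `adjustment`.
#' @export
dda_step <- function(req, events, dda = dda_config(), steps = step_config(),
                     config = parameter_config()) {
  perf <- summarize_round(events, dda)
  adj <- compute_adjustment(perf, dda)
  new_req <- apply_adjustment(req, adj, steps)
  list(requirements = new_req,
       parameters = motor_function_to_parameters(new_req, config),
       performance = perf,
       adjustment = adj)
}
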
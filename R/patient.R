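#' Virtual patient for closed-loop testing
#'
#' A deliberately simple ground-truth model of a player with limited
#' motor function, used to exercise the difficulty loop without human
#' data. It is not a biomechanical arm model; its one job is to make the
#' hit rate respond monotonically to every difficulty parameter, which
#' the test suite asserts rather than assumes.
#'
#' The model has four ingredients:
#' * a true comfortable active range per joint axis (degrees) — targets
#'   demanding a larger fraction of the required range than the patient
#'   can attain are always missed;
#' * a true strength grade — a strength requirement above it inflates
#'   the aim noise by `1 + (required - true)`;
#' * Gaussian aim noise of standard deviation `aim_noise_sd` metres — a
#'   reachable target of diameter d is hit with probability
#'   `pnorm((d/2) / effective_noise)`;
#' * a timing gate — the interception time (the target's range fraction
#'   times `sweep_time`) must not exceed `reaction_budget + lifetime`.
#'
#' @param true_rom Named numeric, actual comfortable active range per
#'   axis in degrees (`shoulder_azimuth`, `shoulder_elevation`, `elbow`),
#'   each in `[0, 180]`.
#' @param true_strength Real in `[0, 5]`, MMT-grade units.
#' @param aim_noise_sd Endpoint aim scatter, metres, `> 0`.
#' @param reaction_budget Seconds of slack before interception, `> 0`.
#' @param sweep_time Seconds to traverse the full required range.
#' @param fatigue_rate Optional per-round multiplier on the aim noise
#'   (`> 1` inflates noise round over round); `NULL` disables fatigue so
#'   the patient is stationary.
#' @return A `virtual_patient` object.
#' @export
#' @examples
#' virtual_patient(true_rom = c(shoulder_azimuth = 70,
#'                              shoulder_elevation = 70, elbow = 90),
#'                 true_strength = 2.5, aim_noise_sd = 0.06)
virtual_patient <- function(true_rom,
                            true_strength,
                            aim_noise_sd = 0.06,
                            reaction_budget = 0.5,
                            sweep_time = 2.0,
                            fatigue_rate = NULL) {
  stopifnot(all(true_rom >= 0 & true_rom <= 180),
            true_strength >= 0, true_strength <= 5,
            aim_noise_sd > 0, reaction_budget > 0, sweep_time > 0)
  structure(list(true_rom = true_rom,
                 true_strength = true_strength,
                 aim_noise_sd = aim_noise_sd,
                 reaction_budget = reaction_budget,
                 sweep_time = sweep_time,
                 fatigue_rate = fatigue_rate),
            class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat("<virtual_patient>\n")
  cat("  true ROM:", paste(sprintf("%s=%g", names(x$true_rom), x$true_rom),
                           collapse = ", "), "deg\n")
  cat(sprintf("  true strength %.2f, aim noise %.3f m, reaction %.2f s\n",
              x$true_strength, x$aim_noise_sd, x$reaction_budget))
  if (!is.null(x$fatigue_rate)) cat("  fatigue rate:", x$fatigue_rate, "\n")
  invisible(x)
}

# Demand of one target as a fraction of the required range: the largest
# per-axis fraction, with the elbow demand expressed as the flexion angle
# implied by the target's reach under reach(theta) = 1 - theta/180.
target_range_fraction <- function(target, req) {
  rr <- req$range_requirement
  elbow_demand <- (1 - target$reach_fraction) * 180
  demands <- c(shoulder_azimuth = target$azimuth,
               shoulder_elevation = target$elevation,
               elbow = elbow_demand)
  frac <- ifelse(rr[names(demands)] > 0, demands / rr[names(demands)],
                 ifelse(demands > 0, Inf, 0))
  max(frac)
}

# Fraction of the required range the patient can cover in every direction.
attainable_fraction <- function(patient, req) {
  rr <- req$range_requirement
  axes <- names(rr)[rr > 0]
  if (length(axes) == 0) return(Inf)
  min(patient$true_rom[axes] / rr[axes])
}

#' Resolve one target attempt
#'
#' Applies the virtual patient's hit model to a single target. A target
#' demanding more than the patient's attainable fraction of the required
#' range is always missed (a reachability miss); otherwise the hit is a
#' Bernoulli draw at `pnorm((diameter/2) / effective_noise)`, gated on the
#' interception time. Either kind of miss records the target's own
#' fraction of the required range as the miss position — which for
#' reachability misses necessarily exceeds the attainable fraction, and
#' for noise misses never does.
#'
#' Uses the ambient RNG stream; seed it with the caller
#' (see [simulate_round()]).
#'
#' @param patient A [virtual_patient()].
#' @param target One row of a [spawn_schedule()] tibble.
#' @param req The [motor_requirements()] the round was generated from.
#' @param noise_multiplier Extra multiplier on the aim noise (fatigue).
#' @return `list(hit = TRUE)` or `list(hit = FALSE, fraction = )`.
#' @export
attempt_target <- function(patient, target, req, noise_multiplier = 1) {
  stopifnot(inherits(patient, "virtual_patient"),
            inherits(req, "motor_requirements"))
  f <- target_range_fraction(target, req)
  attainable <- attainable_fraction(patient, req)
  if (f > attainable) {
    return(list(hit = FALSE, fraction = f, reason = "reach"))
  }
  strength_deficit <- max(0, req$strength_requirement - patient$true_strength)
  noise_eff <- patient$aim_noise_sd * (1 + strength_deficit) * noise_multiplier
  p_aim <- stats::pnorm((target$diameter / 2) / noise_eff)
  time_ok <- f * patient$sweep_time <= patient$reaction_budget + target$lifetime
  p <- p_aim * as.numeric(time_ok)
  if (stats::runif(1) < p) list(hit = TRUE)
  else list(hit = FALSE, fraction = f, reason = "noise")
}

#' Simulate one round with a virtual patient
#'
#' Seeds a private RNG stream, generates the spawn schedule, resolves
#' every target with [attempt_target()], and summarizes the round for
#' the controller. Identical `(patient, params, req, seed)` give an
#' identical event stream.
#'
#' @param patient A [virtual_patient()].
#' @param params `game_parameters` for the round.
#' @param req The [motor_requirements()] behind `params`.
#' @param seed Integer seed.
#' @param dda A [dda_config()] (for the miss-beyond threshold).
#' @param round_index Round number stamped on events.
#' @param noise_multiplier Fatigue multiplier for this round.
#' @return A list: `performance` ([round_performance]), `result`
#'   (`round_result`), `events` (tibble).
#' @export
simulate_round <- function(patient, params, req, seed, dda = dda_config(),
                           round_index = 1L, noise_multiplier = 1) {
  local_rng(seed)
  out <- run_round(
    params,
    attempt_fn = function(tgt) attempt_target(patient, tgt, req,
                                              noise_multiplier),
    seed = (as.numeric(seed) + 1) %% 2147483647,
    round_index = round_index
  )
  list(performance = summarize_round(out$events, dda),
       result = out$result,
       events = out$events)
}

#' Simulate a full adaptive training course
#'
#' Closes the loop: each round is played by the virtual patient at the
#' current difficulty, the round's telemetry feeds the DDA, and the
#' adjusted requirements generate the next round's parameters. The
#' trajectory of requirements, parameters, performance and controller
#' decisions is returned as a tidy tibble inside a `dda_course` object
#' (see [tidy.dda_course()], [glance.dda_course()],
#' [autoplot.dda_course()]).
#'
#' @param patient A [virtual_patient()].
#' @param initial_req Starting [motor_requirements()] (normally from
#'   [requirements_from_evaluation()]).
#' @param n_rounds Number of rounds to play.
#' @param dda A [dda_config()]; pass `dda_enabled = FALSE` to freeze the
#'   requirements (open-loop baseline).
#' @param steps A [step_config()].
#' @param config A [parameter_config()].
#' @param seed Integer master seed; per-round seeds are derived from it.
#' @param dda_enabled If `FALSE` the controller output is discarded and
#'   the requirements stay constant.
#' @return A `dda_course` object with `$trajectory` (one row per round),
#'   `$events` (full telemetry), `$final_requirements`, and the configs.
#' @export
simulate_course <- function(patient, initial_req, n_rounds,
                            dda = dda_config(), steps = step_config(),
                            config = parameter_config(), seed = 1,
                            dda_enabled = TRUE) {
  stopifnot(inherits(patient, "virtual_patient"),
            inherits(initial_req, "motor_requirements"), n_rounds >= 1)
  req <- initial_req
  rows <- vector("list", n_rounds)
  all_events <- vector("list", n_rounds)
  base_seed <- as.numeric(seed) %% 2147483647
  for (k in seq_len(n_rounds)) {
    params <- motor_function_to_parameters(req, config)
    mult <- if (is.null(patient$fatigue_rate)) 1 else patient$fatigue_rate^(k - 1)
    sim <- simulate_round(patient, params, req,
                          seed = (base_seed + 7919 * k) %% 2147483647,
                          dda = dda, round_index = k, noise_multiplier = mult)
    adj <- compute_adjustment(sim$performance, dda)
    rows[[k]] <- tibble::tibble(
      round = k,
      n_targets = sim$performance$n_targets,
      n_hits = sim$performance$n_hits,
      hit_rate = sim$performance$hit_rate,
      miss_beyond_fraction = sim$performance$miss_beyond_fraction,
      range_req_azimuth = req$range_requirement[["shoulder_azimuth"]],
      range_req_elevation = req$range_requirement[["shoulder_elevation"]],
      range_req_elbow = req$range_requirement[["elbow"]],
      strength_req = req$strength_requirement,
      target_diameter = params$target_diameter,
      target_speed = params$target_speed,
      gate = adj$gate,
      range_pct = adj$range_pct,
      strength_pct = adj$strength_pct,
      points = sim$result$points,
      bgm_final_speed = sim$result$bgm_final_speed
    )
    all_events[[k]] <- sim$events
    if (dda_enabled) req <- apply_adjustment(req, adj, steps)
  }
  structure(list(trajectory = dplyr::bind_rows(rows),
                 events = dplyr::bind_rows(all_events),
                 final_requirements = req,
                 patient = patient, dda = dda, steps = steps,
                 config = config, seed = seed),
            class = "dda_course")
}

#' @export
print.dda_course <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("<dda_course> %d rounds, seed %s\n", nrow(tr), format(x$seed)))
  cat(sprintf("  mean hit rate %.3f (last 50: %.3f)\n", mean(tr$hit_rate),
              mean(utils::tail(tr$hit_rate, 50))))
  print(x$final_requirements)
  invisible(x)
}
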
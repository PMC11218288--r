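#' Seeded target spawn schedule for one round
#'
#' Targets spawn on a fixed interval grid (first spawn one interval into
#' the round) and every target must fully resolve before the round ends:
#' the number of targets is `floor((round_duration - lifetime) /
#' spawn_interval)`. Each target's direction and reach are drawn
#' independently and uniformly over the spawn-region intervals. The same
#' seed always reproduces the same schedule.
#'
#' @param params A [motor_function_to_parameters()] result.
#' @param seed Integer seed.
#' @return A tibble with one row per target: `target_id`, `spawn_time`,
#'   `azimuth`, `elevation`, `reach_fraction`, `diameter`, `ascent_speed`,
#'   `lifetime`.
#' @export
spawn_schedule <- function(params, seed) {
  stopifnot(inherits(params, "game_parameters"))
  region <- params$spawn_region
  widths <- c(diff(region$azimuth), diff(region$elevation), diff(region$reach))
  if (any(widths < 0)) stop("spawn region has an empty interval", call. = FALSE)
  n <- floor((params$round_duration - params$target_lifetime) /
               params$spawn_interval)
  if (n < 1) stop("spawn region/round too small: no target fits in the round",
                  call. = FALSE)
  rng <- local_rng(seed)
  runif_in <- function(k, iv) stats::runif(k, iv[1], iv[2])
  tibble::tibble(
    target_id = seq_len(n),
    spawn_time = seq_len(n) * params$spawn_interval,
    azimuth = runif_in(n, region$azimuth),
    elevation = runif_in(n, region$elevation),
    reach_fraction = runif_in(n, region$reach),
    diameter = params$target_diameter,
    ascent_speed = params$target_speed,
    lifetime = params$target_lifetime
  )
}

# Scoped RNG: seed the generator for the calling frame and restore the
# previous global state on exit, so simulations never disturb user RNG state.
local_rng <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible())
  restore <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    bquote(assign(".Random.seed", .(get(".Random.seed", globalenv())),
                  envir = globalenv()))
  } else {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  set.seed(as.numeric(seed) %% 2147483647)
  invisible()
}

#' Run one 30-second round of the shooting game
#'
#' Drives the simulated clock over a seeded spawn schedule, resolving each
#' target through `attempt_fn` (the virtual patient, or a log replay), and
#' emits the full event stream: a `round_start`, one `hit` or `miss` per
#' target (misses carry the recorded position fraction and trigger a
#' `bgm_change`), optional `points` payloads on hits, and a `round_end` at
#' exactly `round_duration` seconds of simulated time.
#'
#' Background music starts every round at speed 1.0 and, when
#' `bgm$compound` is `TRUE` (default), is multiplied by
#' `1 + per_miss_increase` on every miss; otherwise the increase is added.
#'
#' @param params A `game_parameters` object.
#' @param attempt_fn Function `(target_row) -> list(hit = TRUE)` or
#'   `list(hit = FALSE, fraction = <position in [0, 1]>)`.
#' @param seed Integer seed for the spawn schedule.
#' @param gun A [gun_profile()]; hits are scored with its point weight.
#' @param bgm List with `per_miss_increase` (default 0.10) and `compound`
#'   (default `TRUE`).
#' @param round_index Round number recorded on every event.
#' @return A list: `result` (a `round_result`: `success_rate`, `n_targets`,
#'   `n_hits`, `points`, `bgm_final_speed`, `duration`) and `events`
#'   (tibble: `round`, `time`, `kind`, `target_id`, `fraction`, `points`,
#'   `bgm_speed`).
#' @export
run_round <- function(params, attempt_fn, seed, gun = gun_profile("standard"),
                      bgm = list(per_miss_increase = 0.10, compound = TRUE),
                      round_index = 1L) {
  schedule <- spawn_schedule(params, seed)
  per_miss <- bgm$per_miss_increase %||% 0.10
  compound <- bgm$compound %||% TRUE

  ev <- list(event_row(round_index, 0, "round_start", bgm_speed = 1.0))
  bgm_speed <- 1.0
  points_total <- 0L
  n_hits <- 0L
  for (i in seq_len(nrow(schedule))) {
    tgt <- schedule[i, ]
    outcome <- attempt_fn(tgt)
    if (!is.list(outcome) || is.null(outcome$hit)) {
      stop("attempt_fn must return list(hit = , fraction = ); round aborted ",
           "after ", i - 1L, " targets", call. = FALSE)
    }
    resolve_time <- tgt$spawn_time + tgt$lifetime
    if (isTRUE(outcome$hit)) {
      pts <- award_points(gun = gun)
      points_total <- points_total + pts
      n_hits <- n_hits + 1L
      ev[[length(ev) + 1L]] <- event_row(round_index, resolve_time, "hit",
                                         target_id = tgt$target_id,
                                         points = pts, bgm_speed = bgm_speed)
    } else {
      frac <- outcome$fraction
      if (is.null(frac) || !is.finite(frac)) {
        stop("miss outcomes must carry a position fraction", call. = FALSE)
      }
      bgm_speed <- if (compound) bgm_speed * (1 + per_miss) else bgm_speed + per_miss
      ev[[length(ev) + 1L]] <- event_row(round_index, resolve_time, "miss",
                                         target_id = tgt$target_id,
                                         fraction = frac, bgm_speed = bgm_speed)
      ev[[length(ev) + 1L]] <- event_row(round_index, resolve_time, "bgm_change",
                                         bgm_speed = bgm_speed)
    }
  }
  ev[[length(ev) + 1L]] <- event_row(round_index, params$round_duration,
                                     "round_end", bgm_speed = bgm_speed)
  events <- dplyr::bind_rows(ev)
  result <- structure(
    list(success_rate = n_hits / nrow(schedule),
         n_targets = nrow(schedule),
         n_hits = n_hits,
         points = points_total,
         bgm_final_speed = bgm_speed,
         duration = params$round_duration),
    class = "round_result")
  list(result = result, events = events)
}

event_row <- function(round, time, kind, target_id = NA_integer_,
                      fraction = NA_real_, points = NA_integer_,
                      bgm_speed = NA_real_) {
  tibble::tibble(round = as.integer(round), time = as.numeric(time),
                 kind = kind, target_id = as.integer(target_id),
                 fraction = as.numeric(fraction),
                 points = as.integer(points), bgm_speed = as.numeric(bgm_speed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gun profiles of the reward economy
#'
#' Each unlockable gun trades pacing for scoring: e.g. the sniper rifle
#' halves the game speed (excluding movement mapping and bullet speed)
#' and also halves the points earned per hit. The numbers are engine
#' defaults; the structure (speed multiplier, point weight, unlock cost)
#' is what matters.
#'
#' @param id One of the profiles in `guns`.
#' @param guns Named list of profiles, each with `game_speed_multiplier`,
#'   `point_weight`, `unlock_cost`.
#' @return A `gun_profile` object.
#' @export
gun_profile <- function(id = "standard", guns = default_guns()) {
  if (!id %in% names(guns)) stop("unknown gun: ", id, call. = FALSE)
  g <- guns[[id]]
  stopifnot(g$game_speed_multiplier > 0, g$point_weight > 0, g$unlock_cost >= 0)
  structure(c(list(id = id), g), class = "gun_profile")
}

#' @rdname gun_profile
#' @export
default_guns <- function() {
  list(
    standard = list(game_speed_multiplier = 1.0, point_weight = 1.0,
                    unlock_cost = 0),
    sniper = list(game_speed_multiplier = 0.5, point_weight = 0.5,
                  unlock_cost = 100)
  )
}

#' Points awarded for one hit
#'
#' `round(base_points(target_type) * point_weight)` of the active gun;
#' different target types carry different base values.
#'
#' @param target_type Target type id.
#' @param gun A [gun_profile()].
#' @param base_points Named integer vector of base values per target type.
#' @return Non-negative integer points.
#' @export
award_points <- function(target_type = "standard", gun = gun_profile("standard"),
                         base_points = c(standard = 10L, bonus = 20L)) {
  if (!target_type %in% names(base_points)) {
    stop("unknown target type: ", target_type, call. = FALSE)
  }
  as.integer(round(base_points[[target_type]] * gun$point_weight))
}

#' Reward-economy wallet state
#'
#' @param points_balance Non-negative integer.
#' @param unlocked_items Character vector of unlocked gun/target ids.
#' @param active_gun Currently selected gun; must be unlocked.
#' @return A `reward_state` object.
#' @export
reward_state <- function(points_balance = 0L,
                         unlocked_items = "standard",
                         active_gun = "standard") {
  stopifnot(points_balance >= 0, active_gun %in% unlocked_items)
  structure(list(points_balance = as.integer(points_balance),
                 unlocked_items = unlocked_items,
                 active_gun = active_gun),
            class = "reward_state")
}

#' Spend points to unlock an item
#'
#' Decrements the balance and adds the item. An unaffordable or already
#' unlocked item leaves the state unchanged and sets `$rejected` with the
#' reason; the ledger can never go negative.
#'
#' @param state A [reward_state()].
#' @param item Item id present in `catalogue`.
#' @param catalogue Named numeric of unlock costs.
#' @return Updated `reward_state`; `attr(, "rejected")`-free on success,
#'   otherwise carrying `rejected = <reason>`.
#' @export
purchase <- function(state, item,
                     catalogue = c(sniper = 100, bonus_target = 150)) {
  stopifnot(inherits(state, "reward_state"))
  if (!item %in% names(catalogue)) stop("unknown item: ", item, call. = FALSE)
  if (item %in% state$unlocked_items) {
    attr(state, "rejected") <- "already unlocked"
    return(state)
  }
  cost <- catalogue[[item]]
  if (state$points_balance < cost) {
    attr(state, "rejected") <- "insufficient balance"
    return(state)
  }
  reward_state(points_balance = state$points_balance - cost,
               unlocked_items = c(state$unlocked_items, item),
               active_gun = state$active_gun)
}

#' Check the reward-cycle design constraint
#'
#' A long-term reward loop must span the whole prescribed programme:
#' `n_cycles * cycle_period >= rehabilitation_duration`.
#'
#' @param n_cycles Number of reward cycles.
#' @param cycle_period Length of one cycle, days.
#' @param rehabilitation_duration Prescribed programme length, days.
#' @return `TRUE` when the inequality holds.
#' @export
check_reward_cycle <- function(n_cycles, cycle_period, rehabilitation_duration) {
  if (any(c(n_cycles, cycle_period, rehabilitation_duration) <= 0)) {
    stop("reward-cycle fields must be positive", call. = FALSE)
  }
  n_cycles * cycle_period >= rehabilitation_duration
}

#' Pain-gated session continuation
#'
#' The state assessment between rounds: training continues while the
#' reported pain score stays at or below the therapist-set threshold;
#' an absent score defaults to continue.
#'
#' @param pain_score Integer 0-10, or `NULL` if not reported.
#' @param threshold Maximum tolerated score, default 4.
#' @return `TRUE` to continue, `FALSE` to stop for rest.
#' @export
should_continue <- function(pain_score = NULL, threshold = 4) {
  stopifnot(threshold >= 0, threshold <= 10)
  if (is.null(pain_score)) return(TRUE)
  if (!is.finite(pain_score) || pain_score < 0 || pain_score > 10) {
    stop("pain score out of 0-10", call. = FALSE)
  }
  pain_score <= threshold
}
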
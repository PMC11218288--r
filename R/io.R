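#' Load and resolve an engine configuration
#'
#' Reads a YAML configuration and resolves it against the engine
#' defaults: any omitted field is filled in (the DDA hit-rate thresholds
#' default to 0.50/0.70, the beyond-range threshold to 0.70, steps to 10
#' degrees / 0.5 grade) and the fully resolved values are recorded in the
#' returned object, so two runs from the same file always see the same
#' numbers. Unknown top-level keys are a schema error naming the key.
#'
#' Recognised top-level sections: `dda`, `steps`, `parameters`,
#' `session` (`pain_threshold`, `bgm`), `patient`.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A list of class `engine_config` with elements `dda`
#'   ([dda_config]), `steps` ([step_config]), `parameters`
#'   ([parameter_config]), `session` (list), `patient`
#'   ([virtual_patient] or `NULL`), and `resolved` (plain named list of
#'   every resolved scalar, suitable for dumping).
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("dda", "steps", "parameters", "session", "patient")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  d <- raw$dda %||% list()
  dda <- dda_config(
    lower_hit_threshold = d$lower_hit_threshold %||% 0.50,
    upper_hit_threshold = d$upper_hit_threshold %||% 0.70,
    range_fraction_threshold = d$range_fraction_threshold %||% 0.70)
  s <- raw$steps %||% list()
  steps <- step_config(
    max_range_step = s$max_range_step %||% 10,
    max_strength_step = s$max_strength_step %||% 0.5,
    range_bounds = unlist(s$range_bounds %||% c(10, 90)),
    strength_bounds = unlist(s$strength_bounds %||% c(0, 5)))
  p <- raw$parameters %||% list()
  params <- parameter_config(
    nominal_diameter = unlist(p$nominal_diameter %||%
                                c(III = 0.30, IV = 0.20, V = 0.12)),
    nominal_speed = unlist(p$nominal_speed %||%
                             c(III = 0.30, IV = 0.50, V = 0.75)),
    round_duration = p$round_duration %||% 30,
    spawn_interval = p$spawn_interval %||% 3,
    ascent_distance = p$ascent_distance %||% 1.5,
    safety_margin = p$safety_margin %||% 0)
  sess <- raw$session %||% list()
  session <- list(
    pain_threshold = sess$pain_threshold %||% 4,
    bgm = list(per_miss_increase = sess$bgm$per_miss_increase %||% 0.10,
               compound = sess$bgm$compound %||% TRUE))
  patient <- if (!is.null(raw$patient)) {
    pt <- raw$patient
    virtual_patient(true_rom = unlist(pt$true_rom),
                    true_strength = pt$true_strength,
                    aim_noise_sd = pt$aim_noise_sd %||% 0.06,
                    reaction_budget = pt$reaction_budget %||% 0.5,
                    sweep_time = pt$sweep_time %||% 2.0,
                    fatigue_rate = pt$fatigue_rate)
  }
  resolved <- list(
    dda = list(lower_hit_threshold = dda$lower_hit_threshold,
               upper_hit_threshold = dda$upper_hit_threshold,
               range_fraction_threshold = dda$range_fraction_threshold),
    steps = list(max_range_step = steps$max_range_step,
                 max_strength_step = steps$max_strength_step,
                 range_bounds = steps$range_bounds,
                 strength_bounds = steps$strength_bounds),
    parameters = list(nominal_diameter = as.list(params$nominal_diameter),
                      nominal_speed = as.list(params$nominal_speed),
                      round_duration = params$round_duration,
                      spawn_interval = params$spawn_interval,
                      ascent_distance = params$ascent_distance,
                      safety_margin = params$safety_margin),
    session = session)
  structure(list(dda = dda, steps = steps, parameters = params,
                 session = session, patient = patient, resolved = resolved),
            class = "engine_config")
}

#' Read a clinical evaluation from YAML
#'
#' The document needs keys `mmt_grades`, `rom` (named, each `[min, max]`
#' degrees), `brunnstrom_stage`, and optionally `pain_score`.
#'
#' @param path Path to a YAML file.
#' @return A validated [clinical_evaluation()].
#' @export
read_evaluation <- function(path) {
  doc <- yaml::read_yaml(path)
  clinical_evaluation(mmt_grades = unlist(doc$mmt_grades),
                      rom = lapply(doc$rom, unlist),
                      brunnstrom_stage = doc$brunnstrom_stage,
                      pain_score = doc$pain_score)
}

#' Write and read session telemetry as JSON Lines
#'
#' One event per line, append-friendly, bit-exact replay:
#' `read_event_log(write_event_log(x))` returns `x` unchanged.
#'
#' @param events Event tibble (from [run_round()]/[simulate_course()]).
#' @param path File path (`.jsonl`).
#' @return `write_event_log` returns `path` invisibly; `read_event_log`
#'   returns the event tibble.
#' @export
write_event_log <- function(events, path) {
  stopifnot(is.data.frame(events))
  lines <- vapply(seq_len(nrow(events)), function(i) {
    jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE, na = "null",
                     digits = I(17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x[vapply(x, is.null, logical(1))] <- NA
    tibble::as_tibble(x)
  })
  ev <- dplyr::bind_rows(rows)
  # restore stable column order and types
  ev <- ev[, c("round", "time", "kind", "target_id", "fraction", "points",
               "bgm_speed")]
  ev$round <- as.integer(ev$round)
  ev$time <- as.numeric(ev$time)
  ev$kind <- as.character(ev$kind)
  ev$target_id <- as.integer(ev$target_id)
  ev$fraction <- as.numeric(ev$fraction)
  ev$points <- as.integer(ev$points)
  ev$bgm_speed <- as.numeric(ev$bgm_speed)
  ev
}

#' Write a therapist report for a simulated or replayed course
#'
#' A per-round CSV (hit rate, requirements, parameters, controller
#' decision, points) and, optionally, a short Markdown summary.
#'
#' @param course A `dda_course` from [simulate_course()].
#' @param path CSV output path.
#' @param md_path Optional Markdown summary path.
#' @return `path`, invisibly.
#' @export
write_report <- function(course, path, md_path = NULL) {
  stopifnot(inherits(course, "dda_course"))
  utils::write.csv(course$trajectory, path, row.names = FALSE)
  if (!is.null(md_path)) {
    g <- glance(course)
    lines <- c(
      "# Training course report",
      "",
      sprintf("- Rounds played: %d (seed %s)", g$n_rounds, format(course$seed)),
      sprintf("- Mean hit rate: %.3f (last 50 rounds: %.3f)",
              g$mean_hit_rate, g$mean_hit_rate_last50),
      sprintf("- Rounds in the 50-70%% comfort band (rolling, last 50): %.0f%%",
              100 * g$in_band_share_last50),
      sprintf("- Final range requirement (azimuth/elevation/elbow): %.1f / %.1f / %.1f deg",
              g$final_range_azimuth, g$final_range_elevation, g$final_range_elbow),
      sprintf("- Final strength requirement: %.2f MMT-grade units",
              g$final_strength),
      sprintf("- Points earned: %d", g$total_points))
    writeLines(lines, md_path)
  }
  invisible(path)
}

#' Design-document completeness check
#'
#' The three-layer design checklist for a rehabilitation serious game:
#' the clinical layer (stage goals, rehab motion features, motor-function
#' evaluation, state assessment method), the function layer (motion
#' mapping, duration, game rules, feedback, difficulty) and the
#' engagement layer (reward mechanism, story, art design, music & sound
#' design) — thirteen elements in all. `validate_design` reports each
#' element's presence; a document is complete iff all thirteen carry
#' non-empty payloads. The check is order-insensitive and idempotent.
#'
#' @param doc A nested list (e.g. from `yaml::read_yaml`) with top-level
#'   keys `clinical`, `function`, `interesting`.
#' @return A tibble with columns `layer`, `element`, `present`;
#'   attribute `complete` is `TRUE` iff 13/13 are present.
#' @export
#' @examples
#' doc <- list(clinical = list(stage_goals = "upper-limb training"))
#' validate_design(doc)
validate_design <- function(doc) {
  if (!is.list(doc)) stop("design document must be a named list", call. = FALSE)
  schema <- design_schema()
  bad <- setdiff(names(doc), unique(schema$layer))
  if (length(bad)) {
    stop("malformed design document, unknown layer(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  present <- vapply(seq_len(nrow(schema)), function(i) {
    payload <- doc[[schema$layer[i]]][[schema$element[i]]]
    !is.null(payload) && !identical(payload, "") &&
      !(is.character(payload) && all(!nzchar(payload)))
  }, logical(1))
  out <- tibble::tibble(layer = schema$layer, element = schema$element,
                        present = present)
  attr(out, "complete") <- all(present)
  out
}

design_schema <- function() {
  tibble::tibble(
    layer = c(rep("clinical", 4), rep("function", 5), rep("interesting", 4)),
    element = c("stage_goals", "rehab_motion_features",
                "motor_function_evaluation", "state_assessment_method",
                "motion_mapping", "duration", "game_rules", "feedback",
                "difficulty",
                "reward_mechanism", "story", "art_design",
                "music_sound_design"))
}
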
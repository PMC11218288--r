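# Shared fixtures, built in code.

full_range_requirements <- function(strength = 10 / 3) {
  motor_requirements(
    range_requirement = c(shoulder_azimuth = 90, shoulder_elevation = 90,
                          elbow = 90),
    strength_requirement = strength)
}

# Mid-ability Brunnstrom-IV-like virtual patient used in closed-loop tests.
stationary_patient <- function() {
  virtual_patient(
    true_rom = c(shoulder_azimuth = 70, shoulder_elevation = 70, elbow = 90),
    true_strength = 2.5, aim_noise_sd = 0.06)
}

rom_limited_patient <- function(rom = 60) {
  virtual_patient(
    true_rom = c(shoulder_azimuth = rom, shoulder_elevation = rom, elbow = rom),
    true_strength = 2.5, aim_noise_sd = 0.06)
}

# Build a round_performance with an (approximately) prescribed hit rate and
# beyond-range miss share, using explicit miss position lists.
performance_at <- function(hit_rate, miss_beyond, n_targets = 1000,
                           threshold = 0.70) {
  n_hits <- round(hit_rate * n_targets)
  n_miss <- n_targets - n_hits
  k <- round(miss_beyond * n_miss)
  pos <- c(rep(0.9, k), rep(0.1, n_miss - k))
  round_performance(n_targets, n_hits, pos, threshold)
}

full_design_doc <- function() {
  pay <- function(x) paste("described:", x)
  list(
    clinical = list(stage_goals = pay("upper-limb training"),
                    rehab_motion_features = pay("shoulder/elbow 0-90"),
                    motor_function_evaluation = pay("MMT + active ROM"),
                    state_assessment_method = pay("pain scale")),
    `function` = list(motion_mapping = pay("shoulder+elbow to aim"),
                      duration = pay("30 s rounds"),
                      game_rules = pay("shoot ascending targets"),
                      feedback = pay("KP hand model, KR success rate"),
                      difficulty = pay("fuzzy initial + DDA")),
    interesting = list(reward_mechanism = pay("points and unlocks"),
                       story = pay("defend the village"),
                       art_design = pay("cartoon shells"),
                       music_sound_design = pay("BGM speed pacing")))
}

# Independent dense-grid Mamdani oracle: recomputes memberships from the
# breakpoints with its own formulas (approx()-based) and defuzzifies by
# trapezoidal integration, sharing no code path with the implementation.
oracle_mamdani <- function(rulebase, inputs, grid_n = 10001) {
  mf_degree <- function(x, mf) {
    bp <- unname(mf$breakpoints)
    xs <- bp
    ys <- if (mf$kind == "triangular") c(0, 1, 0) else c(0, 1, 1, 0)
    # collapse duplicated knots, keeping the max degree (vertical edges)
    ux <- unique(xs)
    uy <- vapply(ux, function(v) max(ys[xs == v]), numeric(1))
    if (length(ux) == 1) return(as.numeric(x == ux))
    approx(ux, uy, xout = x, yleft = 0, yright = 0)$y
  }
  firing <- vapply(rulebase$rules, function(r) {
    min(vapply(names(r$if.), function(v) {
      p <- rulebase$input_partitions[[v]]
      xi <- min(max(inputs[[v]], p$support[1]), p$support[2])
      mf_degree(xi, p$sets[[r$if.[[v]]]])
    }, numeric(1)))
  }, numeric(1))
  vapply(names(rulebase$output_partitions), function(v) {
    p <- rulebase$output_partitions[[v]]
    grid <- seq(p$support[1], p$support[2], length.out = grid_n)
    env <- numeric(grid_n)
    for (j in seq_along(rulebase$rules)) {
      lab <- rulebase$rules[[j]]$then.[[v]]
      if (is.null(lab) || firing[j] <= 0) next
      env <- pmax(env, pmin(firing[j], mf_degree(grid, p$sets[[lab]])))
    }
    if (all(env == 0)) return(0)
    h <- diff(grid[1:2])
    num <- sum((grid[-1] * env[-1] + grid[-grid_n] * env[-grid_n]) / 2) * h
    den <- sum((env[-1] + env[-grid_n]) / 2) * h
    num / den
  }, numeric(1))
}

# Random small Ruspini partition on [lo, hi] from sorted interior knots.
random_partition <- function(n_sets, support = c(0, 1)) {
  knots <- sort(c(support, runif(n_sets - 2, support[1], support[2])))
  sets <- lapply(seq_len(n_sets), function(i) {
    a <- if (i == 1) knots[1] else knots[i - 1]
    b <- knots[i]
    c <- if (i == n_sets) knots[n_sets] else knots[i + 1]
    mf_triangular(a, b, c)
  })
  names(sets) <- paste0("S", seq_len(n_sets))
  fuzzy_partition(sets, support)
}
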
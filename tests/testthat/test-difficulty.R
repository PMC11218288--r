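test_that("initial parameters weight the nominal values by strength membership", {
  cfg <- parameter_config()
  gp <- motor_function_to_parameters(full_range_requirements(10 / 3), cfg)
  # hand arithmetic on the worked grade mix: 0.67 * 0.30 + 0.33 * 0.20
  expect_equal(gp$target_diameter, (2 / 3) * 0.30 + (1 / 3) * 0.20,
               tolerance = 1e-12)
  expect_equal(round(gp$target_diameter, 3), 0.267)
  expect_equal(gp$round_duration, 30)

  exact4 <- motor_function_to_parameters(full_range_requirements(4), cfg)
  expect_equal(exact4$target_diameter, 0.20)
  expect_equal(exact4$target_speed, 0.50)
})

test_that("diameter shrinks and speed grows monotonically with strength", {
  cfg <- parameter_config()
  s_grid <- seq(0, 5, by = 0.1)
  gps <- lapply(s_grid, function(s)
    motor_function_to_parameters(full_range_requirements(s), cfg))
  d <- vapply(gps, `[[`, numeric(1), "target_diameter")
  v <- vapply(gps, `[[`, numeric(1), "target_speed")
  expect_true(all(diff(d) <= 1e-12))
  expect_true(all(diff(v) >= -1e-12))
})

test_that("parameter mapping equals an independent membership-weighted oracle", {
  cfg <- parameter_config()
  part <- cfg$partition
  set.seed(41)
  for (s in runif(30, 0, 5)) {
    deg <- vapply(part$sets, function(mf) evaluate_membership(s, mf), numeric(1))
    want <- sum(deg * cfg$nominal_diameter) / sum(deg)
    got <- motor_function_to_parameters(full_range_requirements(s), cfg)$target_diameter
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("nominal value ordering is enforced", {
  expect_error(parameter_config(nominal_diameter = c(III = 0.1, IV = 0.2, V = 0.3)),
               "strictly decreasing")
  expect_error(parameter_config(nominal_speed = c(III = 0.9, IV = 0.5, V = 0.2)),
               "strictly increasing")
})

test_that("round summaries compute hit rate and beyond-range miss share", {
  ev <- dplyr::bind_rows(
    tibble::tibble(kind = rep("hit", 6), fraction = NA_real_),
    tibble::tibble(kind = rep("miss", 4), fraction = c(0.8, 0.9, 0.5, 0.6)),
    tibble::tibble(kind = "round_end", fraction = NA_real_))
  perf <- summarize_round(ev, dda_config())
  expect_equal(perf$hit_rate, 0.6)
  expect_equal(perf$miss_beyond_fraction, 0.5)
  expect_equal(perf$n_targets, 10)

  all_hit <- tibble::tibble(kind = rep("hit", 5), fraction = NA_real_)
  expect_equal(summarize_round(all_hit)$miss_beyond_fraction, 0)
  expect_error(summarize_round(tibble::tibble(kind = "round_end",
                                              fraction = NA_real_)),
               "no resolved targets")
})

test_that("the comfort band gives exactly zero adjustment", {
  dda <- dda_config()
  for (m in c(0, 0.25, 0.5, 0.75, 1)) {
    for (h in seq(0.5, 0.7, length.out = 9)) {
      adj <- compute_adjustment(performance_at(h, m), dda)
      expect_identical(adj$range_pct, 0)
      expect_identical(adj$strength_pct, 0)
      expect_identical(adj$gate, "hold")
    }
  }
})

test_that("adjustment signs are correct on a dense input grid", {
  dda <- dda_config()
  for (h in seq(0, 1, length.out = 101)) {
    for (m in c(0, 0.33, 0.71, 1)) {
      adj <- compute_adjustment(performance_at(h, m, n_targets = 100), dda)
      hr <- round(h * 100) / 100
      if (hr < 0.5) {
        expect_lte(adj$range_pct, 0)
        expect_lte(adj$strength_pct, 0)
        expect_lt(min(adj$range_pct, adj$strength_pct), 0)
      } else if (hr > 0.7) {
        expect_gte(adj$range_pct, 0)
        expect_gte(adj$strength_pct, 0)
        expect_gt(max(adj$range_pct, adj$strength_pct), 0)
      } else {
        expect_identical(c(adj$range_pct, adj$strength_pct), c(0, 0))
      }
    }
  }
})

test_that("miss location decides which requirement is reduced", {
  dda <- dda_config()
  far <- compute_adjustment(performance_at(0.3, 1.0), dda)
  expect_lt(far$range_pct, 0)
  expect_gt(abs(far$range_pct), abs(far$strength_pct))
  near <- compute_adjustment(performance_at(0.3, 0.0), dda)
  expect_lt(near$strength_pct, 0)
  expect_gt(abs(near$strength_pct), abs(near$range_pct))
})

test_that("reduction surfaces are monotone in the beyond-range miss share", {
  dda <- dda_config()
  for (h in c(0.1, 0.3, 0.45)) {
    ms <- seq(0, 1, length.out = 101)
    adjs <- lapply(ms, function(m)
      compute_adjustment(performance_at(h, m, n_targets = 1000), dda))
    rng <- vapply(adjs, `[[`, numeric(1), "range_pct")
    stg <- vapply(adjs, `[[`, numeric(1), "strength_pct")
    expect_true(all(diff(rng) <= 1e-9))   # more far misses: stronger range cut
    expect_true(all(diff(stg) >= -1e-9))  # ... and weaker strength cut
  }
})

test_that("increase amplitude grows with the hit-rate excess and splits evenly", {
  dda <- dda_config()
  hs <- seq(0.71, 1, length.out = 30)
  amps <- vapply(hs, function(h)
    compute_adjustment(performance_at(h, 0, n_targets = 100), dda)$range_pct,
    numeric(1))
  expect_true(all(diff(amps) >= -1e-9))
  adj <- compute_adjustment(performance_at(0.9, 0.5), dda)
  expect_equal(adj$range_pct, adj$strength_pct)
  expect_equal(compute_adjustment(performance_at(1, 0), dda)$range_pct, 1)
})

test_that("adjustments move requirements by bounded clamped steps", {
  steps <- step_config()
  req <- motor_requirements(
    c(shoulder_azimuth = 80, shoulder_elevation = 80, elbow = 80), 3)
  down <- apply_adjustment(req, fuzzydda:::new_adjustment(-1, 0, "reduce"), steps)
  expect_equal(unname(down$range_requirement), rep(70, 3))
  expect_equal(down$strength_requirement, 3)

  same <- apply_adjustment(req, fuzzydda:::new_adjustment(0, 0, "hold"), steps)
  expect_equal(same, req)

  high <- motor_requirements(
    c(shoulder_azimuth = 85, shoulder_elevation = 85, elbow = 85), 4.9)
  up <- apply_adjustment(high, fuzzydda:::new_adjustment(1, 1, "increase"), steps)
  expect_equal(unname(up$range_requirement), rep(90, 3))
  expect_equal(up$strength_requirement, 5)

  set.seed(43)
  for (i in 1:30) {
    r0 <- motor_requirements(
      c(shoulder_azimuth = runif(1, 10, 90),
        shoulder_elevation = runif(1, 10, 90),
        elbow = runif(1, 10, 90)), runif(1, 0, 5))
    adj <- fuzzydda:::new_adjustment(runif(1, -1, 1), runif(1, -1, 1), "x")
    r1 <- apply_adjustment(r0, adj, steps)
    expect_true(all(r1$range_requirement >= 10 & r1$range_requirement <= 90))
    expect_true(all(abs(r1$range_requirement - r0$range_requirement) <=
                      steps$max_range_step + 1e-9))
    expect_lte(abs(r1$strength_requirement - r0$strength_requirement),
               steps$max_strength_step + 1e-9)
  }
})

test_that("a full DDA step composes summary, adjustment and remapping", {
  req <- full_range_requirements(10 / 3)
  in_band <- dplyr::bind_rows(
    tibble::tibble(kind = rep("hit", 6), fraction = NA_real_),
    tibble::tibble(kind = rep("miss", 4), fraction = rep(0.9, 4)))
  step1 <- dda_step(req, in_band)
  expect_equal(step1$requirements, req)
  expect_equal(step1$parameters$target_diameter,
               motor_function_to_parameters(req)$target_diameter)
  # idempotence: zero-adjustment rounds are a fixed point
  step2 <- dda_step(step1$requirements, in_band)
  expect_equal(step2$requirements, step1$requirements)

  all_far_miss <- tibble::tibble(kind = rep("miss", 10),
                                 fraction = rep(0.95, 10))
  red <- dda_step(req, all_far_miss)
  expect_true(all(red$requirements$range_requirement <
                    req$range_requirement))
  expect_lt(red$parameters$spawn_region$azimuth[2], 90)
})
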
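test_that("triangular membership is exact at peak, feet and interior points", {
  mf <- mf_triangular(3, 4, 5)
  expect_equal(evaluate_membership(4, mf), 1)
  expect_equal(evaluate_membership(3, mf), 0)
  expect_equal(evaluate_membership(5, mf), 0)
  expect_equal(evaluate_membership(3.33, mf), 0.33)
  expect_equal(evaluate_membership(3.33, mf_triangular(2, 3, 4)), 0.67)
  expect_equal(evaluate_membership(c(-1, 10), mf), c(0, 0))
})

test_that("trapezoidal membership plateaus at 1 and falls linearly", {
  mf <- mf_trapezoidal(0, 0, 3, 4)
  expect_equal(evaluate_membership(c(0, 1.7, 3), mf), c(1, 1, 1))
  expect_equal(evaluate_membership(3.5, mf), 0.5)
  expect_equal(evaluate_membership(4.2, mf), 0)
})

test_that("malformed breakpoints are rejected", {
  expect_error(mf_triangular(5, 4, 3), "non-decreasing")
  expect_error(mf_trapezoidal(0, 2, 1, 3), "non-decreasing")
  expect_error(mf_triangular(1, NA, 3), "finite")
})

test_that("membership is continuous and piecewise linear around breakpoints", {
  eps <- 1e-9
  for (mf in list(mf_triangular(3, 4, 5), mf_trapezoidal(1, 2, 3, 4))) {
    for (b in unname(mf$breakpoints)) {
      at <- evaluate_membership(b, mf)
      expect_lt(abs(evaluate_membership(b - eps, mf) - at), 1e-6)
      expect_lt(abs(evaluate_membership(b + eps, mf) - at), 1e-6)
    }
  }
})

test_that("strength-partition fuzzification reproduces the worked grade mix", {
  p <- strength_partition()
  deg <- fuzzify(10 / 3, p)
  expect_equal(unname(round(deg[c("III", "IV")], 2)), c(0.67, 0.33))
  expect_equal(unname(deg[["V"]]), 0)
  expect_equal(unname(fuzzify(5, p)), c(0, 0, 1))
  # out-of-support values clamp to the support ends
  expect_equal(fuzzify(-1, p), fuzzify(0, p))
  expect_equal(fuzzify(7, p), fuzzify(5, p))
})

test_that("fuzzified degrees sum to one across the support (Ruspini)", {
  parts <- list(strength_partition(),
                dda_magnitude_rulebase()$input_partitions$miss_beyond,
                dda_magnitude_rulebase()$output_partitions$range_pct)
  set.seed(11)
  for (k in 3:6) parts <- c(parts, list(random_partition(k)))
  for (p in parts) {
    xs <- seq(p$support[1], p$support[2], length.out = 101)
    for (x in xs) expect_equal(sum(fuzzify(x, p)), 1, tolerance = 1e-9)
  }
})

test_that("non-Ruspini families are refused at construction", {
  expect_error(
    fuzzy_partition(list(A = mf_triangular(0, 0.5, 1),
                         B = mf_triangular(0, 0.5, 1)),
                    support = c(0, 1)),
    "Ruspini")
  expect_error(fuzzy_partition(list(), c(0, 1)), "at least one")
  expect_error(
    fuzzy_partition(list(A = mf_triangular(0, 0, 1), A = mf_triangular(0, 1, 1)),
                    c(0, 1)),
    "unique")
})

test_that("weighted defuzzification matches hand arithmetic and stays bounded", {
  expect_equal(weighted_defuzzify(c(III = 1, IV = 0), c(III = 7, IV = 9)), 7)
  expect_equal(weighted_defuzzify(c(III = 0.5, IV = 0.5), c(III = 2, IV = 4)), 3)
  expect_equal(
    weighted_defuzzify(c(III = 0.67, IV = 0.33), c(III = 0.30, IV = 0.20)),
    0.267)
  expect_error(weighted_defuzzify(c(A = 0, B = 0), c(A = 1, B = 2)),
               "no fuzzy set")
  expect_error(weighted_defuzzify(c(A = 1), c(B = 1)), "same labels")
  set.seed(21)
  for (i in 1:50) {
    deg <- runif(4); names(deg) <- letters[1:4]
    val <- rnorm(4, sd = 10); names(val) <- letters[1:4]
    out <- weighted_defuzzify(deg, val)
    expect_gte(out, min(val))
    expect_lte(out, max(val))
  }
})

test_that("a single symmetric fired rule defuzzifies to its centre", {
  inp <- fuzzy_partition(list(L = mf_triangular(0, 0, 1),
                              H = mf_triangular(0, 1, 1)), c(0, 1))
  out <- fuzzy_partition(list(Lo = mf_triangular(-1, -0.25, 0.5),
                              Hi = mf_trapezoidal(-0.25, 0.5, 1, 1)),
                         c(-1, 1), check_ruspini = FALSE)
  rb <- fuzzy_rulebase(list(list(if. = c(x = "H"), then. = c(y = "Lo"))),
                       list(x = inp), list(y = out))
  res <- mamdani_evaluate(rb, c(x = 1))
  expect_equal(unname(res[["y"]]), -0.25, tolerance = 1e-3)
})

test_that("a sign-symmetric rulebase yields zero at its symmetry point", {
  rb <- dda_magnitude_rulebase()
  out <- mamdani_evaluate(rb, c(miss_beyond = 0.5))
  expect_equal(unname(out[["range_pct"]]), unname(out[["strength_pct"]]),
               tolerance = 1e-9)
})

test_that("unfired rulebases return the declared zero default with a flag", {
  inp <- fuzzy_partition(list(A = mf_triangular(0, 0, 1),
                              B = mf_triangular(0, 1, 1)), c(0, 1))
  out <- inp
  # only rule requires B, but B has degree 0 at x = 0
  rb <- fuzzy_rulebase(list(list(if. = c(x = "B"), then. = c(y = "B"))),
                       list(x = inp), list(y = out))
  res <- mamdani_evaluate(rb, c(x = 0))
  expect_equal(unname(res[["y"]]), 0)
  expect_true(isTRUE(attr(res, "no_rule_fired")))
  expect_error(mamdani_evaluate(rb, c(z = 1)), "missing input")
})

test_that("Mamdani centroid agrees with the dense-grid integration oracle", {
  set.seed(31)
  for (trial in 1:12) {
    n_in <- sample(2:3, 1)
    n_out <- sample(2:4, 1)
    inp <- random_partition(n_in, c(0, 1))
    outp <- random_partition(n_out, support = sort(runif(2, -2, 2)))
    labs_in <- names(inp$sets); labs_out <- names(outp$sets)
    rules <- lapply(labs_in, function(li) {
      list(if. = c(x = li), then. = c(y = sample(labs_out, 1)))
    })
    rb <- fuzzy_rulebase(rules, list(x = inp), list(y = outp))
    for (x in runif(5)) {
      got <- unname(mamdani_evaluate(rb, c(x = x))[["y"]])
      want <- unname(oracle_mamdani(rb, c(x = x))[["y"]])
      rng <- diff(outp$support)
      expect_lt(abs(got - want), 1e-3 * rng)
    }
  }
})

test_that("invalid rulebases are rejected", {
  inp <- fuzzy_partition(list(L = mf_triangular(0, 0, 1),
                              H = mf_triangular(0, 1, 1)), c(0, 1))
  expect_error(fuzzy_rulebase(list(), list(x = inp), list(y = inp)),
               "at least one rule")
  expect_error(
    fuzzy_rulebase(list(list(if. = c(x = "nope"), then. = c(y = "L"))),
                   list(x = inp), list(y = inp)),
    "not in partition")
  expect_error(
    fuzzy_rulebase(list(list(if. = c(q = "L"), then. = c(y = "L"))),
                   list(x = inp), list(y = inp)),
    "unknown input variable")
})
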
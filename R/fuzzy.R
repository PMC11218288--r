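#' Triangular membership function
#'
#' A triangular fuzzy set with feet at `a` and `c` and peak at `b`.
#' Degenerate shapes (`a == b` or `b == c`) give half-open shoulders with a
#' vertical edge at the shared breakpoint, where the degree is taken as 1.
#'
#' @param a,b,c Breakpoints, non-decreasing, in the units of the variable
#'   the set partitions.
#' @return A `fuzzy_mf` object.
#' @seealso [mf_trapezoidal()], [evaluate_membership()]
#' @export
#' @examples
#' mf <- mf_triangular(3, 4, 5)
#' evaluate_membership(3.33, mf)
mf_triangular <- function(a, b, c) {
  new_mf("triangular", c(a = a, b = b, c = c))
}

#' Trapezoidal membership function
#'
#' Degree rises linearly from `a` to `b`, plateaus at 1 on `[b, c]`, and
#' falls linearly to 0 at `d`.
#'
#' @param a,b,c,d Breakpoints, non-decreasing.
#' @return A `fuzzy_mf` object.
#' @export
mf_trapezoidal <- function(a, b, c, d) {
  new_mf("trapezoidal", c(a = a, b = b, c = c, d = d))
}

new_mf <- function(kind, breakpoints) {
  if (any(!is.finite(breakpoints))) {
    stop("membership breakpoints must be finite numbers", call. = FALSE)
  }
  if (is.unsorted(breakpoints)) {
    stop("membership breakpoints must be non-decreasing", call. = FALSE)
  }
  structure(list(kind = kind, breakpoints = breakpoints), class = "fuzzy_mf")
}

#' @export
print.fuzzy_mf <- function(x, ...) {
  cat("<fuzzy_mf> ", x$kind, "(",
      paste(format(x$breakpoints, trim = TRUE), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Evaluate a membership function
#'
#' Piecewise-linear membership degree of `x` in the fuzzy set `mf`.
#' The degree is 1 on the peak or plateau, 0 outside the support, and
#' linear in between; it is exact at the breakpoints.
#'
#' @param x Numeric vector of crisp values.
#' @param mf A [mf_triangular()] or [mf_trapezoidal()] object.
#' @return Numeric vector of degrees in `[0, 1]`, same length as `x`.
#' @export
evaluate_membership <- function(x, mf) {
  stopifnot(inherits(mf, "fuzzy_mf"))
  bp <- mf$breakpoints
  if (mf$kind == "triangular") {
    lo <- bp[["a"]]; pk_l <- bp[["b"]]; pk_r <- bp[["b"]]; hi <- bp[["c"]]
  } else {
    lo <- bp[["a"]]; pk_l <- bp[["b"]]; pk_r <- bp[["c"]]; hi <- bp[["d"]]
  }
  up <- if (pk_l > lo) (x - lo) / (pk_l - lo) else rep(1, length(x))
  down <- if (hi > pk_r) (hi - x) / (hi - pk_r) else rep(1, length(x))
  deg <- pmin(up, down, 1)
  deg[x < lo | x > hi] <- 0
  # vertical edge: degree 1 exactly at a degenerate foot shared with the peak
  deg[x >= pk_l & x <= pk_r] <- 1
  pmin(pmax(deg, 0), 1)
}

#' Construct a fuzzy partition
#'
#' An ordered, labelled family of membership functions over a closed
#' support. Partitions used by the engine are Ruspini partitions: at every
#' point of the support the degrees across the family sum to 1, so each
#' degree can be read as the share of the value belonging to each
#' linguistic set.
#'
#' @param sets Named list of `fuzzy_mf` objects; names are the linguistic
#'   labels, in increasing order of the variable.
#' @param support Length-2 numeric, the closed interval the partition covers.
#' @param check_ruspini If `TRUE` (default), verify the sum-to-one property
#'   on a dense grid and error if it fails.
#' @return A `fuzzy_partition` object.
#' @export
#' @examples
#' p <- strength_partition()
#' fuzzify(3.33, p)
fuzzy_partition <- function(sets, support, check_ruspini = TRUE) {
  if (length(sets) == 0) stop("partition needs at least one set", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(names(sets) == "")) {
    stop("partition sets must have unique non-empty labels", call. = FALSE)
  }
  stopifnot(length(support) == 2, support[1] < support[2])
  part <- structure(list(sets = sets, support = as.numeric(support),
                         cache = new.env(parent = emptyenv())),
                    class = "fuzzy_partition")
  if (check_ruspini) {
    grid <- seq(support[1], support[2], length.out = 257)
    tot <- rowSums(vapply(sets, function(mf) evaluate_membership(grid, mf),
                          numeric(length(grid))))
    if (any(abs(tot - 1) > 1e-8)) {
      stop("degrees do not sum to 1 over the support (not a Ruspini partition)",
           call. = FALSE)
    }
  }
  part
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat("<fuzzy_partition> ", length(x$sets), " sets {",
      paste(names(x$sets), collapse = ", "), "} on [",
      x$support[1], ", ", x$support[2], "]\n", sep = "")
  invisible(x)
}

#' Fuzzify a crisp value
#'
#' Membership degrees of `x` in every set of a partition. Values outside
#' the support are clamped to its ends; hit rates, fractions and clinical
#' grades are already bounded, so clamping only guards float drift.
#'
#' @param x A single crisp value.
#' @param partition A [fuzzy_partition()].
#' @return Named numeric vector of degrees, one per set, summing to 1.
#' @export
fuzzify <- function(x, partition) {
  stopifnot(inherits(partition, "fuzzy_partition"), length(x) == 1, is.finite(x))
  x <- min(max(x, partition$support[1]), partition$support[2])
  vapply(partition$sets, function(mf) evaluate_membership(x, mf), numeric(1))
}

#' Membership-weighted defuzzification
#'
#' Aggregates per-set crisp values by their membership degrees:
#' `sum(degree * value) / sum(degree)`. This is how the engine turns the
#' strength-partition memberships into an initial target size or speed.
#'
#' @param degrees Named degrees, e.g. from [fuzzify()].
#' @param crisp_values Named numeric with the same labels: the nominal
#'   crisp output attached to each set.
#' @return A single number, always within the range of `crisp_values`.
#' @export
weighted_defuzzify <- function(degrees, crisp_values) {
  if (!setequal(names(degrees), names(crisp_values))) {
    stop("degrees and crisp_values must share the same labels", call. = FALSE)
  }
  crisp_values <- crisp_values[names(degrees)]
  tot <- sum(degrees)
  if (tot <= 0) stop("no fuzzy set is activated (all degrees zero)", call. = FALSE)
  sum(degrees * crisp_values) / tot
}

#' Construct a fuzzy rule base
#'
#' @param rules List of rules; each rule is a list with elements `if.` (named
#'   character: input variable -> linguistic label) and `then.` (named
#'   character: output variable -> linguistic label).
#' @param input_partitions,output_partitions Named lists of
#'   [fuzzy_partition()] objects, one per variable.
#' @return A `fuzzy_rulebase` object.
#' @export
fuzzy_rulebase <- function(rules, input_partitions, output_partitions) {
  if (length(rules) == 0) stop("rule base needs at least one rule", call. = FALSE)
  for (r in rules) {
    if (is.null(r$if.) || is.null(r$then.)) {
      stop("each rule needs `if.` and `then.` components", call. = FALSE)
    }
    for (v in names(r$if.)) {
      p <- input_partitions[[v]]
      if (is.null(p)) stop("unknown input variable: ", v, call. = FALSE)
      if (!r$if.[[v]] %in% names(p$sets)) {
        stop("label '", r$if.[[v]], "' not in partition of ", v, call. = FALSE)
      }
    }
    for (v in names(r$then.)) {
      p <- output_partitions[[v]]
      if (is.null(p)) stop("unknown output variable: ", v, call. = FALSE)
      if (!r$then.[[v]] %in% names(p$sets)) {
        stop("label '", r$then.[[v]], "' not in partition of ", v, call. = FALSE)
      }
    }
  }
  structure(list(rules = rules,
                 input_partitions = input_partitions,
                 output_partitions = output_partitions),
            class = "fuzzy_rulebase")
}

#' Mamdani fuzzy inference
#'
#' Standard Mamdani evaluation: each rule fires at the minimum of its
#' antecedent degrees, its consequent set is clipped (min-implication) at
#' that strength, clipped sets are max-aggregated per output variable, and
#' the aggregated shape is defuzzified by its centroid on a fixed
#' 2001-point discretization of the output support. Deterministic for
#' fixed inputs.
#'
#' If no rule fires with positive degree the declared default (0) is
#' returned for every output and the result carries attribute
#' `no_rule_fired = TRUE`.
#'
#' @param rulebase A [fuzzy_rulebase()].
#' @param inputs Named numeric, one crisp value per input variable.
#' @param grid_n Number of discretization points for the centroid.
#' @return Named numeric of crisp outputs, one per output variable.
#' @export
mamdani_evaluate <- function(rulebase, inputs, grid_n = 2001) {
  stopifnot(inherits(rulebase, "fuzzy_rulebase"))
  in_parts <- rulebase$input_partitions
  missing_vars <- setdiff(names(in_parts), names(inputs))
  if (length(missing_vars)) {
    stop("missing input variables: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  memberships <- lapply(names(in_parts), function(v) fuzzify(inputs[[v]], in_parts[[v]]))
  names(memberships) <- names(in_parts)

  out_parts <- rulebase$output_partitions
  # firing strength per rule, then per-output aggregated envelope on the grid
  out <- vapply(names(out_parts), function(v) {
    p <- out_parts[[v]]
    grid <- grid_membership(p, "..grid..", grid_n)
    envelope <- numeric(grid_n)
    for (r in rulebase$rules) {
      if (is.null(r$then.[[v]])) next
      w <- min(vapply(names(r$if.), function(iv) memberships[[iv]][[r$if.[[iv]]]],
                      numeric(1)))
      if (w <= 0) next
      clipped <- pmin(w, grid_membership(p, r$then.[[v]], grid_n))
      envelope <- pmax(envelope, clipped)
    }
    if (sum(envelope) <= 0) return(NA_real_)
    # trapezoidal quadrature: half-weight the support ends
    w <- rep(1, grid_n); w[c(1, grid_n)] <- 0.5
    sum(grid * envelope * w) / sum(envelope * w)
  }, numeric(1))

  if (anyNA(out)) {
    out[is.na(out)] <- 0
    attr(out, "no_rule_fired") <- TRUE
  }
  out
}

# Memoized membership degrees of one set on the partition's centroid grid
# (key "..grid.." stores the grid itself). Partitions are immutable after
# construction, so the cache is safe to share between copies.
grid_membership <- function(partition, label, grid_n) {
  key <- paste0(label, "@", grid_n)
  cache <- partition$cache
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  val <- cache[[key]]
  if (is.null(val)) {
    grid <- seq(partition$support[1], partition$support[2],
                length.out = grid_n)
    val <- if (label == "..grid..") grid
           else evaluate_membership(grid, partition$sets[[label]])
    cache[[key]] <- val
  }
  val
}
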
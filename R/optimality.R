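# Dominance, exhaustive optimal-mode search, and optimality maps.
#
# A mode dominates another on a landscape when its growth rate is at least
# as large; the optimal mode attains the maximum growth rate over the whole
# (pure) strategy space. Mixed modes never beat the best pure mode, so
# exhaustive search over pure modes suffices.

#' Does one mode dominate another?
#'
#' @param mode_a,mode_b `"pure_mode"` objects admissible on the landscape.
#' @param landscape A `"fitness_landscape"`.
#' @param tol Numerical slack on the comparison.
#' @return `TRUE` iff `lambda1(mode_a) >= lambda1(mode_b) - tol`.
#' @export
dominates <- function(mode_a, mode_b, landscape, tol = 1e-12) {
  growth_rate(mode_a, landscape)$lambda1 >=
    growth_rate(mode_b, landscape)$lambda1 - tol
}

#' Optimal pure fragmentation mode on a landscape
#'
#' Exhaustively evaluates every pure mode admissible under the cost regime
#' up to the landscape's maximal group size and returns the one with the
#' largest growth rate. Ties (within relative tolerance) are broken by the
#' deterministic mode enumeration order.
#'
#' @param landscape A `"fitness_landscape"`.
#' @param cost Cost regime.
#' @param method `"eigen"` (dense eigensolve per mode) or
#'   `"characteristic"` (vectorised renewal-equation solver; much faster for
#'   large strategy spaces, numerically equivalent).
#' @param tie_tol Relative tolerance within which modes count as tied.
#' @return List with `mode` (the winner), `lambda1`, `ties` (list of all
#'   modes within tolerance of the maximum, winner included) and `lambdas`
#'   (growth rates of every mode, named by mode id).
#' @examples
#' optimal_mode(fitness_landscape(c(1, 2, 1.4)))$mode  # 4:2+2
#' @export
optimal_mode <- function(landscape, cost = "costless",
                         method = c("eigen", "characteristic"),
                         tie_tol = 1e-9) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  method <- match.arg(method)
  cost <- match_cost(cost)
  modes <- enumerate_pure_modes(landscape$n, cost)
  lambdas <- if (method == "eigen") {
    vapply(modes, function(m) growth_rate(m, landscape)$lambda1, 0)
  } else {
    lambda1_batch(prepare_mode_batch(modes, landscape$n - 1L),
                  landscape$b, landscape$d)
  }
  names(lambdas) <- vapply(modes, format_mode, "")
  best <- max(lambdas)
  tied <- which(lambdas >= best - tie_tol * max(1, abs(best)))
  winner <- tied[1]
  list(mode = modes[[winner]], lambda1 = lambdas[[winner]],
       ties = modes[tied], lambdas = lambdas)
}

#' Map of optimal life cycles over a two-parameter landscape family
#'
#' Runs the exhaustive optimal-mode search on every cell of a 2-D parameter
#' grid. Four families are built in:
#' \describe{
#'   \item{`fecundity-n4`}{`b = (1, axis1, axis2)`, `d = 0`, `n = 4`; axes
#'     default to 101 values in (0, 4].}
#'   \item{`survival-n4`}{`b = 1`, death differences `d2 - d1 = axis1`,
#'     `d3 - d1 = axis2`, shifted so `min(d) = 0`; axes default to 101
#'     values in [-2, 2].}
#'   \item{`monotonic-fecundity`, `monotonic-survival`}{the monotonic
#'     benefit family of [monotonic_landscape()]; `axis1` is `alpha`
#'     (default 101 log-spaced values in [0.01, 100]) and `axis2` is `M`
#'     (default 101 log-spaced values in [0.02, 50]); `n` defaults to 20
#'     (costless) or 21 (cost regimes).}
#' }
#'
#' @param family One of the four family names above.
#' @param cost Cost regime.
#' @param axis1,axis2 Optional numeric grids overriding the defaults.
#' @param n Maximal group size (monotonic families only).
#' @return Object of class `"optimality_map"`: a data frame with columns
#'   `axis1`, `axis2`, `winner` (mode id string), `lambda1`, and attributes
#'   `family`, `cost`, `n`, `axis_names`.
#' @export
optimality_map <- function(family = c("fecundity-n4", "survival-n4",
                                      "monotonic-fecundity",
                                      "monotonic-survival"),
                           cost = "costless", axis1 = NULL, axis2 = NULL,
                           n = NULL) {
  family <- match.arg(family)
  cost <- match_cost(cost)
  if (family %in% c("fecundity-n4", "survival-n4")) {
    n <- 4L
    if (is.null(axis1))
      axis1 <- if (family == "fecundity-n4") seq(0.04, 4, length.out = 101)
               else seq(-2, 2, length.out = 101)
    if (is.null(axis2)) axis2 <- axis1
    axis_names <- if (family == "fecundity-n4") c("b2_over_b1", "b3_over_b1")
                  else c("d2_minus_d1", "d3_minus_d1")
    make_landscape <- if (family == "fecundity-n4") {
      function(a1, a2) fitness_landscape(b = c(1, a1, a2))
    } else {
      function(a1, a2) {
        d <- c(0, a1, a2)
        fitness_landscape(b = rep(1, 3), d = d - min(d))
      }
    }
  } else {
    if (is.null(n)) n <- if (cost == "costless") 20L else 21L
    if (is.null(axis1)) axis1 <- exp(seq(log(0.01), log(100), length.out = 101))
    if (is.null(axis2)) axis2 <- exp(seq(log(0.02), log(50), length.out = 101))
    axis_names <- c("alpha", "M")
    kind <- if (family == "monotonic-fecundity") "fecundity" else "survival"
    make_landscape <- function(a1, a2) monotonic_landscape(n, M = a2, alpha = a1,
                                                           kind = kind)
  }
  if (any(diff(axis1) <= 0) || any(diff(axis2) <= 0))
    stop("axis grids must be strictly increasing")
  modes <- enumerate_pure_modes(n, cost)
  prep <- prepare_mode_batch(modes, n - 1L)
  ids <- vapply(modes, format_mode, "")
  grid <- expand.grid(axis1 = axis1, axis2 = axis2, KEEP.OUT.ATTRS = FALSE)
  winner <- character(nrow(grid))
  lambda <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    L <- make_landscape(grid$axis1[r], grid$axis2[r])
    lam <- lambda1_batch(prep, L$b, L$d)
    best <- max(lam)
    idx <- which(lam >= best - 1e-9 * max(1, abs(best)))[1]
    winner[r] <- ids[idx]
    lambda[r] <- lam[idx]
  }
  out <- data.frame(axis1 = grid$axis1, axis2 = grid$axis2,
                    winner = winner, lambda1 = lambda)
  structure(out, family = family, cost = cost, n = n, axis_names = axis_names,
            class = c("optimality_map", "data.frame"))
}

#' @export
print.optimality_map <- function(x, ...) {
  cat("optimality map:", attr(x, "family"), "| cost:", attr(x, "cost"),
      "| n =", attr(x, "n"), "\n")
  cat("axes:", paste(attr(x, "axis_names"), collapse = " x "),
      sprintf("(%d x %d cells)\n", length(unique(x$axis1)),
              length(unique(x$axis2))))
  tab <- sort(table(x$winner), decreasing = TRUE)
  cat("winners:\n")
  print(tab)
  invisible(x)
}

#' Boundary between the optimality regions of two modes
#'
#' Finds, by bisection, the parameter value at which the growth rates of
#' two modes cross along a one-parameter path of landscapes.
#'
#' @param mode_a,mode_b `"pure_mode"` objects.
#' @param landscape_fn Function mapping a scalar parameter to a
#'   `"fitness_landscape"`.
#' @param lower,upper Bracket; `lambda1(a) - lambda1(b)` must change sign
#'   over it.
#' @param tol Absolute tolerance on the parameter.
#' @return The crossing parameter value.
#' @examples
#' path <- function(b2) fitness_landscape(c(1, b2, 1.4))
#' region_boundary(parse_mode("2:1+1"), parse_mode("4:3+1"), path, 0.05, 1)
#' @export
region_boundary <- function(mode_a, mode_b, landscape_fn, lower, upper,
                            tol = 1e-6) {
  f <- function(t) {
    L <- landscape_fn(t)
    growth_rate(mode_a, L)$lambda1 - growth_rate(mode_b, L)$lambda1
  }
  flo <- f(lower); fhi <- f(upper)
  if (flo == 0) return(lower)
  if (fhi == 0) return(upper)
  if (sign(flo) == sign(fhi))
    stop("growth-rate difference does not change sign over [", lower, ", ",
         upper, "]")
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) {
      lower <- mid; flo <- fm
    } else {
      upper <- mid
    }
  }
  (lower + upper) / 2
}
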
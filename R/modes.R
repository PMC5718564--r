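# Fragmentation modes: the life-cycle strategy space.
#
# A pure mode is "grow to trigger size l, then always split according to one
# pattern kappa". A mixed mode assigns, at every size transition, a
# probability to staying together and to each admissible pattern. Three cost
# regimes restrict which (trigger, pattern) pairs are admissible:
#   costless      sum(kappa) = l         (no cells die)
#   proportional  sum(kappa) = l - (parts - 1)   (one cell per break point)
#   fixed         sum(kappa) = l - 1     (exactly one cell per event)

.cost_regimes <- c("costless", "proportional", "fixed")

#' Match a fragmentation cost regime
#'
#' @param cost One of `"costless"` (alias `"none"`), `"proportional"`,
#'   `"fixed"`; partial matching allowed.
#' @return The canonical regime name.
#' @export
match_cost <- function(cost = .cost_regimes) {
  if (identical(cost, .cost_regimes)) return("costless")
  if (length(cost) != 1 || !is.character(cost)) stop("cost must be a single string")
  if (cost == "none") return("costless")
  match.arg(cost, .cost_regimes)
}

#' Construct a pure fragmentation mode
#'
#' @param trigger_size Group size `l` at which fragmentation happens (the
#'   group grows from `l - 1` to `l` and immediately splits).
#' @param pattern A `"partition"` giving the offspring group sizes *after*
#'   any fragmentation cost has been paid.
#' @param cost Cost regime, see [match_cost()].
#' @param n Optional maximal group size; if given, `trigger_size <= n` is
#'   enforced.
#' @return Object of class `"pure_mode"`: list with elements `trigger_size`,
#'   `pattern`, `cost`.
#' @examples
#' pure_mode(4, new_partition(c(2, 1, 1)))
#' @export
pure_mode <- function(trigger_size, pattern, cost = "costless", n = NULL) {
  cost <- match_cost(cost)
  l <- check_count(trigger_size, "trigger_size")
  if (l < 2) stop("trigger_size must be at least 2")
  if (!inherits(pattern, "partition")) pattern <- new_partition(pattern)
  np <- length(pattern)
  if (np < 2) stop("a fragmentation pattern must have at least 2 parts")
  tot <- sum(pattern)
  need <- switch(cost,
    costless = l,
    proportional = l - (np - 1L),
    fixed = l - 1L
  )
  if (tot != need)
    stop("pattern ", format_partition(pattern), " has total ", tot,
         " but the ", cost, " regime at trigger size ", l, " requires ", need)
  if (max(pattern) > l - 1L)
    stop("every offspring group must be strictly smaller than the parent")
  if (!is.null(n) && l > n)
    stop("trigger_size ", l, " exceeds the maximal group size n = ", n)
  structure(list(trigger_size = l, pattern = pattern, cost = cost),
            class = "pure_mode")
}

#' @export
format.pure_mode <- function(x, ...)
  paste0(x$trigger_size, ":", format_partition(x$pattern))

#' @export
print.pure_mode <- function(x, ...) {
  cat("pure fragmentation mode ", format(x), " (", x$cost, ")\n", sep = "")
  invisible(x)
}

#' Serialise / parse pure modes as "l:pattern"
#'
#' @param mode A `"pure_mode"`.
#' @return `format_mode()`: a string such as `"4:2+1+1"`.
#' @export
format_mode <- function(mode) format(mode)

#' @rdname format_mode
#' @param x String `"l:pattern"`.
#' @param cost Cost regime the mode is validated against.
#' @export
parse_mode <- function(x, cost = "costless") {
  bits <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(bits) != 2) stop("expected \"l:pattern\", got ", sQuote(x))
  pure_mode(as.integer(bits[1]), parse_partition(bits[2]), cost = cost)
}

#' Admissible fragmentation patterns at a given trigger size
#'
#' All patterns a group fragmenting at size `trigger` may produce under the
#' chosen cost regime. Patterns are ordered deterministically: by offspring
#' total ascending (relevant under proportional cost, where different part
#' counts imply different totals), then reverse-lexicographically.
#'
#' @param trigger Trigger size `l >= 2`.
#' @param cost Cost regime.
#' @return List of `"partition"` objects (possibly empty).
#' @export
admissible_patterns <- function(trigger, cost = "costless") {
  cost <- match_cost(cost)
  l <- check_count(trigger, "trigger")
  if (l < 2) stop("trigger must be at least 2")
  switch(cost,
    costless = enumerate_partitions(l, min_parts = 2L),
    proportional = {
      out <- list()
      for (m in seq_len(l - 1L)) {
        for (k in enumerate_partitions(m, min_parts = 2L))
          if (m + length(k) - 1L == l) out[[length(out) + 1L]] <- k
      }
      out
    },
    fixed = if (l >= 3) enumerate_partitions(l - 1L, min_parts = 2L) else list()
  )
}

#' Enumerate all pure fragmentation modes up to a maximal group size
#'
#' Modes are ordered by trigger size ascending, then by the deterministic
#' pattern order of [admissible_patterns()].
#'
#' @param n Maximal group size (`n >= 2` costless, `n >= 3` under a cost
#'   regime, where fragmenting at size 2 would leave a single offspring).
#' @param cost Cost regime.
#' @return List of `"pure_mode"` objects.
#' @examples
#' length(enumerate_pure_modes(10))  # 128
#' @export
enumerate_pure_modes <- function(n, cost = "costless") {
  cost <- match_cost(cost)
  n <- check_count(n, "n")
  min_n <- if (cost == "costless") 2L else 3L
  if (n < min_n)
    stop("the ", cost, " regime requires a maximal group size of at least ", min_n)
  out <- list()
  for (l in 2:n) {
    for (k in admissible_patterns(l, cost))
      out[[length(out) + 1L]] <- pure_mode(l, k, cost = cost, n = n)
  }
  out
}

#' Count pure fragmentation modes (costless regime)
#'
#' Evaluates `sum_{l=2..n} (count_partitions(l) - 1)` exactly, without
#' enumeration.
#'
#' @param n Maximal group size, `n >= 2`.
#' @return Number of pure costless modes.
#' @examples
#' count_pure_modes(10)  # 128
#' count_pure_modes(50)  # 1295920
#' @export
count_pure_modes <- function(n) {
  n <- check_count(n, "n")
  if (n < 2) stop("n must be at least 2")
  sum(vapply(2:n, count_partitions, 0)) - (n - 1)
}

#' Fraction of pure modes that are binary, as an exact fraction
#'
#' The number of binary partitions of `l` is `floor(l/2)`; the returned value
#' is `sum_{l=2..n} floor(l/2)` over `sum_{l=2..n} (zeta_l - 1)` in lowest
#' terms. Only binary modes can be optimal under costless fragmentation, so
#' this measures how restrictive the optimality result is.
#'
#' @param n Maximal group size, `n >= 2` (costless regime).
#' @return Object of class `"fraction"`, a list with integer-valued `num` and
#'   `den`; use [as.numeric()] for the decimal value.
#' @examples
#' binary_fraction(10)  # 25/128
#' @export
binary_fraction <- function(n) {
  n <- check_count(n, "n")
  if (n < 2) stop("n must be at least 2")
  num <- sum(floor((2:n) / 2))
  den <- count_pure_modes(n)
  g <- gcd_scalar(num, den)
  structure(list(num = num / g, den = den / g), class = "fraction")
}

gcd_scalar <- function(a, b) if (b == 0) a else gcd_scalar(b, a %% b)

#' @export
format.fraction <- function(x, ...) paste0(x$num, "/", x$den)

#' @export
print.fraction <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.double.fraction <- function(x, ...) x$num / x$den

## ---- mixed modes -----------------------------------------------------------

#' Construct a mixed fragmentation mode
#'
#' A mixed mode specifies, for every transition from size `i` to `i + 1`
#' (`i = 1..n-1`), the probability `stay` of staying together and a
#' probability for each admissible fragmentation pattern of size `i + 1`.
#' Groups may never exceed the maximal size, so the transition into size `n`
#' must have `stay = 0`.
#'
#' @param n Maximal group size.
#' @param transitions List of length `n - 1`; element `i` is a list with
#'   `stay` (probability), `patterns` (list of `"partition"`), `probs`
#'   (numeric, same length).
#' @param cost Cost regime the patterns are validated against.
#' @return Object of class `"mixed_mode"`.
#' @export
mixed_mode <- function(n, transitions, cost = "costless") {
  cost <- match_cost(cost)
  n <- check_count(n, "n")
  if (n < 2) stop("n must be at least 2")
  if (length(transitions) != n - 1)
    stop("need one transition per size step: expected ", n - 1, ", got ",
         length(transitions))
  for (i in seq_len(n - 1)) {
    tr <- transitions[[i]]
    s <- i + 1L
    tot <- tr$stay + sum(tr$probs)
    if (length(tr$patterns) != length(tr$probs))
      stop("transition into size ", s, ": patterns and probs differ in length")
    if (abs(tot - 1) > 1e-12)
      stop("transition into size ", s, ": probabilities sum to ", tot, ", not 1")
    if (any(c(tr$stay, tr$probs) < 0) || any(c(tr$stay, tr$probs) > 1))
      stop("transition into size ", s, ": probabilities outside [0, 1]")
    if (i == n - 1 && tr$stay != 0)
      stop("the transition into the maximal size n must have stay probability 0")
    for (k in tr$patterns) pure_mode(s, k, cost = cost)  # validates admissibility
  }
  structure(list(n = n, cost = cost, transitions = transitions),
            class = "mixed_mode")
}

#' @export
print.mixed_mode <- function(x, ...) {
  cat("mixed fragmentation mode, n =", x$n, paste0("(", x$cost, ")"), "\n")
  print(mixed_mode_table(x))
  invisible(x)
}

#' Tabulate a mixed mode as (transition, target, probability)
#'
#' @param mode A `"mixed_mode"`.
#' @return Data frame with columns `size` (size being grown into), `target`
#'   (`"stay"` or a pattern string), `probability`.
#' @export
mixed_mode_table <- function(mode) {
  rows <- lapply(seq_along(mode$transitions), function(i) {
    tr <- mode$transitions[[i]]
    data.frame(
      size = i + 1L,
      target = c("stay", vapply(tr$patterns, format_partition, "")),
      probability = c(tr$stay, tr$probs)
    )
  })
  do.call(rbind, rows)
}

#' Sample a random mixed fragmentation mode
#'
#' Emulates the random strategies of the mixed-mode dominance experiment:
#' at every transition below the top, the probability of growing without
#' splitting is Uniform(0, 1) and the remaining mass is split among the
#' admissible patterns proportionally to independent Exp(1) draws. At the
#' transition into the maximal size the stay probability is 0 and all mass
#' is distributed among patterns.
#'
#' @param n Maximal group size.
#' @param cost Cost regime.
#' @param seed Optional integer seed for reproducibility.
#' @return A `"mixed_mode"`.
#' @export
sample_mixed_mode <- function(n, cost = "costless", seed = NULL) {
  cost <- match_cost(cost)
  n <- check_count(n, "n")
  if (!is.null(seed)) set.seed(seed)
  transitions <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    s <- i + 1L
    pats <- admissible_patterns(s, cost)
    top <- (i == n - 1)
    if (length(pats) == 0) {
      if (top)
        stop("no admissible pattern at the maximal size; n too small for the ",
             cost, " regime")
      transitions[[i]] <- list(stay = 1, patterns = list(), probs = numeric(0))
      next
    }
    stay <- if (top) 0 else stats::runif(1)
    w <- stats::rexp(length(pats))
    transitions[[i]] <- list(stay = stay, patterns = pats,
                             probs = (1 - stay) * w / sum(w))
  }
  mixed_mode(n, transitions, cost = cost)
}

#' Embed a pure mode as a degenerate mixed mode
#'
#' Below the trigger size the group stays together with probability 1; at
#' the trigger transition it fragments according to the mode's pattern with
#' probability 1. Size classes above the trigger are unreachable; to satisfy
#' the mixed-mode invariants the top transition still assigns all mass to
#' its first admissible pattern.
#'
#' @param mode A `"pure_mode"`.
#' @param n Maximal group size of the embedding (`>= mode$trigger_size`).
#' @return A `"mixed_mode"` with the same growth rate as `mode`.
#' @export
pure_as_mixed <- function(mode, n) {
  stopifnot(inherits(mode, "pure_mode"))
  n <- check_count(n, "n")
  l <- mode$trigger_size
  if (n < l) stop("n must be at least the trigger size ", l)
  transitions <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    s <- i + 1L
    if (s == l) {
      transitions[[i]] <- list(stay = 0, patterns = list(mode$pattern), probs = 1)
    } else if (s < l || s < n) {
      transitions[[i]] <- list(stay = 1, patterns = list(), probs = numeric(0))
    } else {  # unreachable top transition of a wider embedding
      pats <- admissible_patterns(s, mode$cost)
      transitions[[i]] <- list(stay = 0, patterns = pats[1],
                               probs = 1)
    }
  }
  mixed_mode(n, transitions, cost = mode$cost)
}
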
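# Fitness landscapes: size-dependent birth and death rates.
#
# b_i is the per-cell division rate in a group of i cells (groups of size i
# grow at rate i * b_i); d_i is the per-group death rate. Both are indexed by
# group size i = 1..n-1, the sizes that can persist in the population.

#' Construct a fitness landscape
#'
#' @param b Numeric vector of per-cell birth rates `b_1..b_{n-1}` (1/time),
#'   all positive.
#' @param d Numeric vector of per-group death rates (1/time), all
#'   non-negative; defaults to zero (a fecundity landscape).
#' @return Object of class `"fitness_landscape"`: list with `n` (maximal
#'   group size, `length(b) + 1`), `b`, `d`.
#' @examples
#' fitness_landscape(b = c(1, 2, 1.4))
#' @export
fitness_landscape <- function(b, d = rep(0, length(b))) {
  b <- as.numeric(b); d <- as.numeric(d)
  if (length(b) < 1) stop("b must have at least one entry")
  if (length(d) != length(b))
    stop("b and d must have equal length (sizes 1..n-1): ",
         length(b), " vs ", length(d))
  if (any(!is.finite(b)) || any(b <= 0)) stop("all birth rates must be positive")
  if (any(!is.finite(d)) || any(d < 0)) stop("all death rates must be non-negative")
  structure(list(n = length(b) + 1L, b = b, d = d), class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat("fitness landscape, n =", x$n, "\n")
  print(data.frame(size = seq_len(x$n - 1L), b = x$b, d = x$d), row.names = FALSE)
  invisible(x)
}

#' Monotonic group-size benefit sequence
#'
#' The benefit of being in a group of size `i` is
#' `g_i = ((i - 1) / (n - 2))^alpha`, for `i = 1..n-1`: zero for solitary
#' cells, one at the largest persistent size. The exponent `alpha` is the
#' degree of complementarity between cells: `alpha < 1` gives diminishing
#' returns (concave benefits), `alpha = 1` linear, `alpha > 1` synergy
#' (convex benefits).
#'
#' @param n Maximal group size, `n >= 3`.
#' @param alpha Positive exponent.
#' @return Numeric vector `g_1..g_{n-1}`, strictly increasing from 0 to 1.
#' @export
benefit_sequence <- function(n, alpha) {
  n <- check_count(n, "n")
  if (n < 3) stop("the benefit sequence needs n >= 3 (denominator n - 2)")
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a positive number")
  ((0:(n - 2L)) / (n - 2L))^alpha
}

#' Monotonic fecundity or survival landscape
#'
#' Fecundity landscapes reward size through births, `b_i = 1 + M * g_i` with
#' `d_i = 0`; survival landscapes reward size through deaths,
#' `d_i = M * (1 - g_i)` with `b_i = 1`. `M > 0` is the maximum benefit and
#' `g_i` the benefit sequence of [benefit_sequence()].
#'
#' @param n Maximal group size, `n >= 3`.
#' @param M Maximum benefit, positive.
#' @param alpha Degree of complementarity, positive.
#' @param kind `"fecundity"` or `"survival"`.
#' @return A `"fitness_landscape"`.
#' @examples
#' monotonic_landscape(20, M = 1, alpha = 1, kind = "fecundity")
#' @export
monotonic_landscape <- function(n, M, alpha, kind = c("fecundity", "survival")) {
  kind <- match.arg(kind)
  if (length(M) != 1 || !is.finite(M) || M <= 0) stop("M must be a positive number")
  g <- benefit_sequence(n, alpha)
  if (kind == "fecundity") {
    fitness_landscape(b = 1 + M * g)
  } else {
    fitness_landscape(b = rep(1, n - 1), d = M * (1 - g))
  }
}

#' Normalise a landscape to b1 = 1 and min(d) = 0
#'
#' Growth rates transform predictably under a joint rescaling of time and a
#' uniform shift of all death rates, so any landscape can be reduced to the
#' canonical form `b1 = 1`, `min(d) = 0` without loss of generality. For any
#' mode, `lambda1(L) = scale * lambda1(L') - shift`.
#'
#' @param L A `"fitness_landscape"`.
#' @return List with `landscape` (the normalised landscape), `scale`
#'   (`b_1`) and `shift` (`min(d)`).
#' @export
normalize_landscape <- function(L) {
  stopifnot(inherits(L, "fitness_landscape"))
  scale <- L$b[1]
  shift <- min(L$d)
  list(landscape = fitness_landscape(L$b / scale, (L$d - shift) / scale),
       scale = scale, shift = shift)
}
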
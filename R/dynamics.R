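# Demographic dynamics: projection matrices and long-term growth rates.
#
# Each fragmentation mode, together with a fitness landscape, defines a set
# of linear reactions: groups of size i die at rate d_i, grow to size i + 1
# at rate i * b_i, and at the trigger size the growth event is fused with an
# immediate fragmentation. The resulting linear ODE system xdot = A x has an
# essentially non-negative projection matrix A whose leading eigenvalue
# lambda_1 is the long-term population growth rate (the fitness of the mode).

#' Projection matrix of a fragmentation mode
#'
#' For a pure mode triggered at size `l` the matrix acts on abundances of
#' sizes `1..l-1`: diagonal `-(i b_i + d_i)`, subdiagonal `i b_i` (growth),
#' and last column `(l-1) b_{l-1} pi_i(kappa)` (fragmentation products),
#' where `pi_i(kappa)` counts offspring groups of size `i`. For a mixed mode
#' the matrix acts on sizes `1..n-1` and the growth flux `i b_i` out of each
#' size splits between staying together and every admissible pattern
#' according to the mode's probabilities.
#'
#' @param mode A `"pure_mode"` or `"mixed_mode"`.
#' @param landscape A `"fitness_landscape"`; must be large enough for the
#'   mode (`trigger_size <= n` for pure modes, equal `n` for mixed modes).
#' @return A dense numeric matrix with size labels on rows and columns.
#' @examples
#' L <- fitness_landscape(c(1, 2, 1.4))
#' projection_matrix(parse_mode("4:2+1+1"), L)
#' @export
projection_matrix <- function(mode, landscape) UseMethod("projection_matrix")

#' @export
projection_matrix.pure_mode <- function(mode, landscape) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  l <- mode$trigger_size
  if (l > landscape$n)
    stop("mode triggers at size ", l, " but the landscape only has n = ",
         landscape$n)
  b <- landscape$b; d <- landscape$d
  L <- l - 1L
  A <- matrix(0, L, L, dimnames = list(seq_len(L), seq_len(L)))
  i <- seq_len(L)
  A[cbind(i, i)] <- -(i * b[i] + d[i])
  if (L >= 2) {
    i <- seq_len(L - 1L)
    A[cbind(i + 1L, i)] <- i * b[i]
  }
  A[, L] <- A[, L] + L * b[L] * multiplicity_vector(mode$pattern, L)
  A
}

#' @export
projection_matrix.mixed_mode <- function(mode, landscape) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  if (landscape$n != mode$n)
    stop("mixed mode has n = ", mode$n, " but landscape has n = ", landscape$n)
  b <- landscape$b; d <- landscape$d
  dim <- mode$n - 1L
  A <- matrix(0, dim, dim, dimnames = list(seq_len(dim), seq_len(dim)))
  for (i in seq_len(dim)) {
    tr <- mode$transitions[[i]]
    A[i, i] <- A[i, i] - (i * b[i] + d[i])
    flux <- i * b[i]
    if (i < dim) A[i + 1L, i] <- A[i + 1L, i] + flux * tr$stay
    for (k in seq_along(tr$patterns))
      A[, i] <- A[, i] +
        flux * tr$probs[k] * multiplicity_vector(tr$patterns[[k]], dim)
  }
  A
}

#' Long-term growth rate and stable size distribution
#'
#' Computes the leading eigenvalue `lambda1` of the projection matrix (the
#' eigenvalue of maximal real part; real for essentially non-negative
#' matrices), the stable size distribution `w` (right eigenvector, clamped
#' to non-negative values and normalised to sum 1) and the reproductive
#' values `v` (left eigenvector, scaled so `sum(v * w) = 1`).
#'
#' @param x A projection matrix, `"pure_mode"` or `"mixed_mode"`.
#' @param landscape Required when `x` is a mode.
#' @param tol_imag Tolerance on the imaginary residual of the leading
#'   eigenpair; a violation signals a matrix-construction bug and raises an
#'   error.
#' @param ... Passed on between methods.
#' @return Object of class `"growth_result"`: list with `lambda1`, `w`, `v`,
#'   and the matrix `A`.
#' @examples
#' L <- fitness_landscape(c(1, 15/8))
#' growth_rate(parse_mode("3:2+1"), L)$lambda1  # 1.5
#' @export
growth_rate <- function(x, ...) UseMethod("growth_rate")

#' @rdname growth_rate
#' @export
growth_rate.pure_mode <- function(x, landscape, ...)
  growth_rate(projection_matrix(x, landscape), ...)

#' @rdname growth_rate
#' @export
growth_rate.mixed_mode <- function(x, landscape, ...)
  growth_rate(projection_matrix(x, landscape), ...)

#' @rdname growth_rate
#' @export
growth_rate.matrix <- function(x, tol_imag = 1e-9, ...) {
  A <- x
  if (nrow(A) != ncol(A)) stop("projection matrix must be square")
  off <- A; diag(off) <- 0
  if (any(off < 0)) stop("projection matrix must be essentially non-negative")
  lead <- function(M) {
    e <- eigen(M)
    idx <- order(-Re(e$values), abs(Im(e$values)))[1]
    lam <- e$values[idx]
    scale <- max(1, abs(Re(lam)))
    if (abs(Im(lam)) > tol_imag * scale)
      stop("leading eigenvalue has imaginary part ", Im(lam),
           "; the matrix is not a valid projection matrix")
    vec <- e$vectors[, idx]
    if (max(abs(Im(vec))) > 1e-6 * max(abs(vec)))
      stop("leading eigenvector has a non-negligible imaginary part")
    vec <- Re(vec)
    if (sum(vec) < 0) vec <- -vec
    vec[abs(vec) < 1e-12 * max(abs(vec))] <- 0
    if (any(vec < -1e-8 * max(abs(vec))))
      stop("leading eigenvector is not sign-definite; ",
           "Perron structure violated (matrix-construction bug?)")
    vec[vec < 0] <- 0
    list(lambda = Re(lam), vec = vec)
  }
  right <- lead(A)
  left <- lead(t(A))
  w <- right$vec / sum(right$vec)
  v <- left$vec
  vw <- sum(v * w)
  if (vw > 0) v <- v / vw
  structure(list(lambda1 = right$lambda, w = w, v = v, A = A),
            class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  cat("growth rate lambda1 =", format(x$lambda1, digits = 10), "\n")
  cat("stable size distribution w:", format(x$w, digits = 4), "\n")
  invisible(x)
}

#' Closed-form growth rates for the three pure modes at n = 3
#'
#' For maximal group size 3 the pure modes are binary fission `1+1`, the
#' unicellular propagule mode `2+1` and ternary fission `1+1+1`; their
#' growth rates have closed radical forms in `b1, b2, d1, d2`. Used as an
#' independent oracle for the eigenvalue route.
#'
#' @param mode_name One of `"1+1"`, `"2+1"`, `"1+1+1"`.
#' @param landscape A `"fitness_landscape"` with `n = 3`.
#' @return The growth rate as a number.
#' @export
closed_form_n3 <- function(mode_name = c("1+1", "2+1", "1+1+1"), landscape) {
  mode_name <- match.arg(mode_name)
  stopifnot(inherits(landscape, "fitness_landscape"))
  if (landscape$n != 3) stop("closed forms require a landscape with n = 3")
  b1 <- landscape$b[1]; b2 <- landscape$b[2]
  d1 <- landscape$d[1]; d2 <- landscape$d[2]
  switch(mode_name,
    "1+1" = b1 - d1,
    "2+1" = (-(b1 + d1 + d2) + sqrt((b1 + d1 - d2)^2 + 8 * b1 * b2)) / 2,
    "1+1+1" = (-(b1 + 2 * b2 + d1 + d2) +
               sqrt(b1^2 + 2 * b1 * (10 * b2 + d1 - d2) +
                    (2 * b2 - d1 + d2)^2)) / 2
  )
}

#' Closed-form growth rate of the 1+1 / 2+1 mixture
#'
#' The mixed mode that fragments according to `2+1` with probability `q`
#' (staying together at size 2 and splitting at size 3) and according to
#' `1+1` with probability `1 - q` has the closed-form growth rate
#' `[b1(1-2q) - (d1+d2) + sqrt((b1(1-2q) - d1 + d2)^2 + 8 q b1 b2)] / 2`,
#' which interpolates between the two pure-mode rates and reduces to them at
#' `q = 0` and `q = 1`.
#'
#' @param q Mixing probability in `[0, 1]`.
#' @param landscape A `"fitness_landscape"` with `n = 3`.
#' @return The growth rate as a number.
#' @export
mixture_growth_rate_11_21 <- function(q, landscape) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  if (landscape$n != 3) stop("this mixture lives on a landscape with n = 3")
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  b1 <- landscape$b[1]; b2 <- landscape$b[2]
  d1 <- landscape$d[1]; d2 <- landscape$d[2]
  (b1 * (1 - 2 * q) - (d1 + d2) +
    sqrt((b1 * (1 - 2 * q) - d1 + d2)^2 + 8 * q * b1 * b2)) / 2
}

#' Build the 1+1 / 2+1 mixture as a mixed mode
#'
#' @param q Probability of following `2+1` (staying at size 2).
#' @return A `"mixed_mode"` with `n = 3`.
#' @export
mixture_mode_11_21 <- function(q) {
  mixed_mode(3, list(
    list(stay = q, patterns = list(new_partition(c(1, 1))), probs = 1 - q),
    list(stay = 0, patterns = list(new_partition(c(2, 1))), probs = 1)
  ))
}

#' ODE-integration oracle for the growth rate
#'
#' Integrates `xdot = A x` with a stiff-capable solver and estimates the
#' growth rate as the slope of `log(total abundance)` over the final quarter
#' of the trajectory. Integration proceeds in renormalised chunks (the state
#' is rescaled to sum 1 after each chunk and the log-scale accumulated), so
#' neither overflow nor underflow can occur. The horizon is doubled until
#' the slope estimate stabilises. This route is independent of the
#' eigenvalue computation and serves as a model-level cross-check.
#'
#' @param A Projection matrix.
#' @param t_max Initial integration horizon (time units).
#' @param x0 Initial abundances; defaults to all ones.
#' @param slope_tol Convergence tolerance between successive horizon
#'   doublings.
#' @param max_doublings Give up (with an error) after this many doublings.
#' @return Estimated growth rate (1/time).
#' @export
ode_growth_rate <- function(A, t_max = 50, x0 = NULL, slope_tol = 1e-6,
                            max_doublings = 6) {
  if (is.null(x0)) x0 <- rep(1, nrow(A))
  if (any(x0 <= 0)) stop("x0 must be positive")
  deriv <- function(t, y, parms) list(as.vector(A %*% y))
  slope_at <- function(horizon) {
    n_chunks <- 8L
    pts_per_chunk <- 25L
    times <- numeric(0); logtot <- numeric(0)
    y <- x0; logscale <- log(sum(x0)); y <- y / sum(y)
    for (ch in seq_len(n_chunks)) {
      tt <- seq((ch - 1) * horizon / n_chunks, ch * horizon / n_chunks,
                length.out = pts_per_chunk + 1L)
      sol <- deSolve::ode(y = y, times = tt, func = deriv, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
      tot <- rowSums(sol[, -1, drop = FALSE])
      if (any(!is.finite(tot)) || any(tot <= 0))
        stop("ODE oracle: trajectory lost positivity")
      times <- c(times, tt[-1])
      logtot <- c(logtot, logscale + log(tot[-1]))
      y <- as.numeric(sol[nrow(sol), -1])
      logscale <- logscale + log(sum(y))
      y <- y / sum(y)
    }
    keep <- times >= 0.75 * horizon
    unname(stats::coef(stats::lm(logtot[keep] ~ times[keep]))[2])
  }
  prev <- slope_at(t_max)
  for (dbl in seq_len(max_doublings)) {
    t_max <- 2 * t_max
    cur <- slope_at(t_max)
    if (abs(cur - prev) < slope_tol) return(cur)
    prev <- cur
  }
  stop("ODE oracle did not converge after ", max_doublings,
       " horizon doublings; last estimates ", prev)
}

## ---- fast batch solver -----------------------------------------------------

# Internal: precompute the structure of a list of pure modes for the batch
# characteristic-equation solver. ns = number of persistent sizes (n - 1).
prepare_mode_batch <- function(modes, ns) {
  nm <- length(modes)
  P <- matrix(0, nm, ns)
  Lv <- integer(nm); minpart <- integer(nm)
  for (m in seq_len(nm)) {
    k <- modes[[m]]$pattern
    P[m, ] <- multiplicity_vector(k, ns)
    Lv[m] <- modes[[m]]$trigger_size - 1L
    minpart[m] <- min(k)
  }
  list(P = P, Lv = Lv, minpart = minpart, nm = nm, ns = ns,
       Lidx = cbind(seq_len(nm), Lv))
}

# Internal: leading eigenvalues for many pure modes on one landscape, via the
# renewal (Euler-Lotka type) characteristic equation
#   sum_i pi_i(kappa) prod_{j=i..L} [ j b_j / (lambda + j b_j + d_j) ] = 1 ,
# solved by simultaneous bisection across modes. An offspring group of size i
# must grow through sizes i..L (hazard lambda + j b_j + d_j against success
# rate j b_j at each stage) before it fragments itself; the root is the
# Perron root of the recurrent block of the projection matrix. Size classes
# below the smallest offspring size are transient feeders with eigenvalues
# -(i b_i + d_i); the leading eigenvalue is the maximum of the two.
lambda1_batch <- function(prep, b, d, iters = 58L) {
  nm <- prep$nm; ns <- prep$ns
  rate <- seq_len(ns) * b
  RD <- matrix(rate + d, nm, ns, byrow = TRUE)
  RATE <- matrix(rate, nm, ns, byrow = TRUE)
  pole <- -(rate + d)
  lo <- vapply(seq_len(nm), function(m) max(pole[prep$minpart[m]:prep$Lv[m]]), 0)
  hi <- rep(2 * max(0, rate) + 1, nm)
  P <- prep$P; Lidx <- prep$Lidx
  gfun <- function(lam) {
    C <- RATE / (RD + lam)      # lam recycles down rows (column-major)
    if (ns >= 2) for (j in 2:ns) C[, j] <- C[, j] * C[, j - 1L]
    g <- C[Lidx] * rowSums(P / cbind(1, C[, -ns, drop = FALSE])) - 1
    g
  }
  # ensure the upper bracket is above every root (lambda1 <= max_i b_i for
  # costless modes; the guard covers degenerate landscapes)
  for (guard in 1:4) {
    bad <- gfun(hi) > 0
    if (!any(bad, na.rm = TRUE)) break
    hi[bad] <- 2 * hi[bad] + 1
  }
  for (it in seq_len(iters)) {
    mid <- (lo + hi) / 2
    g <- gfun(mid)
    up <- is.nan(g) | g > 0   # NaN only next to a pole, where g -> +Inf
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
  }
  root <- (lo + hi) / 2
  trans <- rep(-Inf, nm)
  for (m in seq_len(nm)) {
    mp <- prep$minpart[m]
    if (mp > 1L) {
      i <- seq_len(mp - 1L)
      trans[m] <- max(-(i * b[i] + d[i]))
    }
  }
  pmax(root, trans)
}

#' Growth rate via the renewal characteristic equation
#'
#' Computes the leading eigenvalue of a pure mode's projection matrix by
#' root-finding on the scalar renewal equation instead of a dense
#' eigensolve. Exposed mainly so the two routes can be compared; the
#' optimality-map scans use the (vectorised) equivalent of this function for
#' speed.
#'
#' @param mode A `"pure_mode"`.
#' @param landscape A `"fitness_landscape"`.
#' @return The growth rate as a number.
#' @export
growth_rate_characteristic <- function(mode, landscape) {
  stopifnot(inherits(mode, "pure_mode"), inherits(landscape, "fitness_landscape"))
  if (mode$trigger_size > landscape$n)
    stop("mode triggers at size ", mode$trigger_size,
         " but the landscape only has n = ", landscape$n)
  prep <- prepare_mode_batch(list(mode), landscape$n - 1L)
  lambda1_batch(prep, landscape$b, landscape$d)
}
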
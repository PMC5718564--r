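# Shared fixtures: small landscapes used across the suite.

# n = 3 fecundity landscape with growth rates 1, 3/2, 5/4 for the three modes
worked_landscape_n3 <- function() fitness_landscape(b = c(1, 15/8))

# n = 4 fecundity landscape on which 2+2 is the overall optimum
bicellular_landscape_n4 <- function() fitness_landscape(b = c(1, 2, 1.4))

# random landscape with positive births and (optionally) positive deaths
random_landscape <- function(n, bmax = 3, with_death = TRUE) {
  b <- runif(n - 1, 0.05, bmax)
  d <- if (with_death) runif(n - 1, 0, bmax) else rep(0, n - 1)
  fitness_landscape(b, d)
}

mode_ids <- function(modes) vapply(modes, format_mode, "")
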
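---
title: "Growth and optimality of group fragmentation life cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth and optimality of group fragmentation life cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragmodes)
```

## The model

Many simple multicellular organisms — colonial bacteria, snowflake yeast,
filamentous cyanobacteria, volvocine algae — reproduce by fragmentation: cells
divide but stay attached, the group grows, and at some point it breaks into
smaller groups. `fragmodes` implements a matrix population model of this
process and asks which fragmentation schedule maximises long-term population
growth.

A *fitness landscape* assigns to every group size $i = 1, \dots, n-1$ (groups
never reach the maximal size $n$) a per-cell birth rate $b_i$ and a per-group
death rate $d_i$. Groups of size $i$ therefore grow at rate $i\,b_i$ and die
at rate $d_i$. A *pure fragmentation mode* is a deterministic life cycle:
grow until a trigger size $\ell$ is reached, then always split according to a
fixed fragmentation pattern — an integer partition $\kappa \vdash \ell$ whose
parts are the offspring group sizes. The growth step into size $\ell$ and the
split are a single atomic event: there is no transient class of size $\ell$.
Writing $\pi_i(\kappa)$ for the number of parts of $\kappa$ equal to $i$, the
reactions are

* death: $X_i \to \emptyset$ at rate $d_i$,
* growth: $X_i \to X_{i+1}$ at rate $i\,b_i$ for $i < \ell - 1$,
* growth-plus-fragmentation:
  $X_{\ell-1} \to \sum_i \pi_i(\kappa)\, X_i$ at rate $(\ell-1)\,b_{\ell-1}$.

These linear reactions give $\dot{\mathbf x} = A \mathbf x$ with an
essentially non-negative projection matrix $A$ (`projection_matrix()`).
By Perron–Frobenius theory $A$ has a real leading eigenvalue $\lambda_1$ —
the long-term population growth rate, which we take as the fitness of the
mode — with non-negative right eigenvector $w$ (the stable distribution of
group sizes) and left eigenvector $v$ (reproductive values). `growth_rate()`
returns all three.

*Mixed modes* are probabilistic strategies: at each transition from size $i$
to $i+1$ the group stays together with probability $q_{i+1}$ or fragments
according to pattern $\kappa \vdash i+1$ with probability $q_\kappa$. Pure
modes are the degenerate corners of this simplex (`pure_as_mixed()`).

## Fragmentation costs

Three regimes restrict which (trigger, pattern) pairs are admissible. With
$\pi$ parts in the pattern:

| regime | constraint | interpretation |
|---|---|---|
| `costless` | $\sum \kappa = \ell$ | no cells die at fragmentation |
| `proportional` | $\sum \kappa = \ell - (\pi - 1)$ | one cell dies per break point (filament breakage) |
| `fixed` | $\sum \kappa = \ell - 1$ | exactly one cell dies per event (tree-like clusters) |

A fragmentation must produce at least two offspring groups, and every
offspring must be strictly smaller than the parent. Under either cost regime
the smallest legal trigger is $\ell = 3$ (fragmenting a pair would leave a
single offspring), which is why `enumerate_pure_modes()` demands $n \ge 3$
there. At $n = 4$ this yields exactly `{3:1+1, 4:2+1}` under proportional
costs and additionally `4:1+1+1` under fixed costs.

## Landscape families

Two one-factor families cover the usual questions: *fecundity landscapes*
($d \equiv 0$, only births vary) and *survival landscapes* ($b \equiv 1$,
only deaths vary). For systematic scans, `monotonic_landscape()` builds the
monotonic benefit family
$$ g_i = \left( \frac{i-1}{n-2} \right)^{\alpha}, \qquad
   b_i = 1 + M g_i \ (\text{fecundity}) \quad\text{or}\quad
   d_i = M (1 - g_i) \ (\text{survival}), $$
where $M > 0$ is the maximum benefit of group living and $\alpha > 0$ the
degree of complementarity between cells: $\alpha < 1$ means diminishing
returns (concave $g$), $\alpha > 1$ synergy (convex $g$). Under the cost
regimes we keep the same formula with the configured $n$ (21 by default for
costly maps, so that post-cost offspring sizes span 1..20).

Growth rates transform predictably under time rescaling
($\lambda_1(c\,b, c\,d) = c\,\lambda_1(b, d)$) and uniform death shifts
($\lambda_1(b, d + \delta) = \lambda_1(b, d) - \delta$), so any landscape can
be normalised to $b_1 = 1$, $\min d = 0$ (`normalize_landscape()`); the test
suite checks both invariances on random landscapes.

## Worked example: maximal size 3

```{r n3}
L <- fitness_landscape(b = c(1, 15/8))
sapply(c("2:1+1", "3:2+1", "3:1+1+1"),
       function(id) growth_rate(parse_mode(id), L)$lambda1)
```

The unicellular propagule mode 2+1 dominates both binary and ternary
fission on this landscape. The same three numbers come out of the closed
radical forms (`closed_form_n3()`), of ODE integration
(`ode_growth_rate()`), and — within Monte-Carlo error — of exact stochastic
simulation (`simulate_mode()`), which is how the test suite cross-validates
the matrix construction.

## Optimality search and maps

`optimal_mode()` evaluates every admissible pure mode exhaustively and
returns the argmax; restricting the search to pure modes is justified
because mixed modes are always dominated by a pure mode, a property the
test suite probes by sampling (`sample_mixed_mode()` draws stay
probabilities uniformly and splits the remaining mass among patterns
proportionally to Exp(1) draws, with stay probability forced to 0 at the
transition into $n$ so that the state space stays bounded).

`optimality_map()` repeats the search over a 2-D grid of landscapes. Two
routes to $\lambda_1$ are implemented:

* **dense eigensolve** (`growth_rate()`, the default) — the matrices have
  dimension at most $n - 1 \le 50$, so `eigen()` is cheap and robust;
* **renewal characteristic equation** (`growth_rate_characteristic()`, used
  internally by the map scans) — an offspring of size $i$ must grow through
  sizes $i, \dots, \ell-1$ before fragmenting, so $\lambda_1$ solves
  $\sum_i \pi_i(\kappa) \prod_{j=i}^{\ell-1} \frac{j b_j}{\lambda + j b_j + d_j} = 1$,
  which we solve by bisection simultaneously for thousands of modes
  (vectorised over the strategy set). Size classes below the smallest
  offspring size are transient feeders with eigenvalues $-(i b_i + d_i)$;
  the leading eigenvalue is the maximum of the renewal root and those.

The two routes agree to $10^{-9}$ on random modes and landscapes across all
three cost regimes (tested), and the map tests spot-check cells against the
eigen route.

```{r map, eval = FALSE}
mp <- optimality_map("monotonic-fecundity", cost = "costless",
                     axis1 = exp(seq(log(0.01), log(100), length.out = 21)),
                     axis2 = exp(seq(log(0.02), log(50), length.out = 21)))
table(mp$winner)
```

On monotonic fecundity landscapes every winner is binary; equal binary
fragmentation (10+10 at $n = 20$) wins everywhere under diminishing returns,
and the unicellular propagule strategy (19+1) only appears under synergy.
Under survival benefits 19+1 extends into the diminishing-returns half of
the map. Fixed-cost maps contain nonbinary winners such as multiple fission.

`region_boundary()` locates the crossing of two modes' growth rates along a
one-parameter landscape path by bisection (default parameter tolerance
$10^{-6}$). On the path $b = (1, b_2, 1.4)$, $d = 0$ at $n = 4$ the optimal
mode switches 1+1 → 3+1 → 2+2 → 2+1 at $b_2 \approx 0.45, 1.11, 3.52$.

## Numerical choices

* **Leading eigenvalue extraction.** Full spectrum of the small dense
  matrix; pick the maximal real part, tie-breaking by smallest imaginary
  magnitude; an imaginary residual above $10^{-9}$ (relative) raises an
  error, since essentially non-negative matrices must have a real leading
  root — such a failure signals a matrix-construction bug, not a numerical
  accident.
* **Eigenvector signs.** $w$ is flipped to non-negative orientation, entries
  below $10^{-12}$ (relative) are clamped to zero, and genuinely mixed signs
  raise an error. Reducible matrices (patterns with $\pi_1 = 0$, e.g. 2+2)
  legitimately yield $w$ with explicit zeros; $w$ is normalised over all
  entries.
* **Ties in optimality search.** Modes within relative $10^{-9}$ of the
  maximum count as tied; the winner is the first in the deterministic mode
  order (trigger size ascending, patterns in reverse-lexicographic order).
  Boundary cells of a map may flip winner at this resolution; that is
  expected and harmless.
* **ODE oracle.** `deSolve::ode` with `rtol = 1e-10`, integrating in eight
  renormalised chunks (the state is rescaled to sum 1 after each chunk and
  the log accumulated) so that long horizons can neither overflow nor
  underflow; the horizon doubles until the fitted slope stabilises.
* **Mixture closed form.** The two-mode mixture of 1+1 and 2+1 admits a
  closed-form growth rate; we use the radical form that reduces exactly to
  the two pure-mode rates at $q = 0$ and $q = 1$, and verify it against the
  matrix eigenvalue on random landscapes.
* **Exact combinatorics.** Partition counts use Euler's pentagonal-number
  recurrence with memoisation; the counts involved (up to $n = 50$,
  1,295,920 strategies) are integers well below the $2^{53}$ exactness limit
  of doubles. `binary_fraction()` returns an exact reduced fraction.

## What the stochastic oracle does and does not show

`simulate_mode()` is a direct (exact) Gillespie simulation of the reaction
system — linear propensities, no tau-leaping — and
`estimate_growth_rate()` fits the slope of log total group count after a
20% burn-in. Its standard error comes from per-bin increments of the log
count rather than OLS residuals, because consecutive log-counts are heavily
autocorrelated and the naive OLS standard error would overstate precision.
Agreement of these fitted rates with $\lambda_1$ validates the projection
matrix as the large-population limit of the stochastic model. It does not
probe finite-population effects (extinction risk, demographic noise at
small counts): trajectories start from many groups (default 1000) precisely
to suppress those, and runs that go extinct are reported as non-estimable
rather than silently dropped.

## Problem sizes used in the checks

The packaged tests run the published combinatorial counts exactly (including
$n = 50$ by recurrence, with full enumeration cross-checked up to $n = 20$),
the mixed-mode dominance experiment with $10^4$ sampled strategies at
$n = 4$, dominance property sweeps over a few hundred random landscapes at
$n \le 6$, Gillespie runs capped at $5 \times 10^4$ groups, and monotonic
optimality maps on $21 \times 21$ log-spaced grids over
$\alpha \in [0.01, 100]$, $M \in [0.02, 50]$. These sizes are the package's
default validation scale; the underlying functions take arbitrary grids and
caps, so denser maps or larger ensembles are a matter of arguments, not
code.

## Limitations

* Density-independent dynamics only: fitness is the exponential growth rate
  of an unbounded population; no competition or resource limitation.
* Constant environments: with time-varying landscapes the dominance of pure
  modes need not hold, and none of the machinery here addresses stochastic
  environments.
* One cell type: no mutation, no division of labour, no within-group
  conflict.
* Optimality region boundaries are located numerically (bisection on a
  path, exhaustive search on grids); the package does not produce symbolic
  boundary curves.
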
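test_that("projection matrices encode the reaction system", {
  L <- fitness_landscape(b = c(1.1, 0.9, 1.3), d = c(0.2, 0.1, 0.4))
  b <- L$b; d <- L$d
  A <- projection_matrix(parse_mode("4:2+1+1"), L)
  # reaction at the top: X3 -> X2 + 2 X1 at rate 3 b3
  expect_equal(A[1, 3], 3 * b[3] * 2)
  expect_equal(A[2, 3], 3 * b[3] * 1)
  expect_equal(A[3, 3], -(3 * b[3] + d[3]) + 0)
  expect_equal(A[1, 1], -(b[1] + d[1]))
  expect_equal(A[2, 1], b[1])
  expect_equal(A[3, 2], 2 * b[2])
  expect_equal(A[1, 2], 0)
  # 1+1 at trigger 2 reduces to the scalar b1 - d1
  A11 <- projection_matrix(parse_mode("2:1+1"), L)
  expect_equal(dim(A11), c(1L, 1L))
  expect_equal(A11[1, 1], b[1] - d[1])
  # 2+2 produces no unicells: size-1 class receives no influx
  A22 <- projection_matrix(parse_mode("4:2+2"), L)
  expect_equal(A22[1, 3], 0)
  expect_equal(A22[2, 3], 2 * 3 * b[3])
  expect_error(projection_matrix(parse_mode("4:2+2"), worked_landscape_n3()),
               "only has n")
})

test_that("closed forms for n = 3 agree with the eigenvalue route", {
  L <- worked_landscape_n3()
  expect_equal(closed_form_n3("1+1", L), 1)
  expect_equal(closed_form_n3("2+1", L), 1.5)
  expect_equal(closed_form_n3("1+1+1", L), 1.25)
  set.seed(23)
  for (rep in 1:20) {
    L <- random_landscape(3)
    for (nm in c("1+1", "2+1", "1+1+1")) {
      mode <- parse_mode(switch(nm, "1+1" = "2:1+1", "2+1" = "3:2+1",
                                "1+1+1" = "3:1+1+1"))
      expect_equal(closed_form_n3(nm, L), growth_rate(mode, L)$lambda1,
                   tolerance = 1e-10)
    }
  }
  # the no-death equal-rate case reduces cleanly and matches the eigenvalue
  L <- fitness_landscape(b = c(0.8, 0.8))
  expect_equal(closed_form_n3("1+1+1", L),
               growth_rate(parse_mode("3:1+1+1"), L)$lambda1, tolerance = 1e-10)
  expect_error(closed_form_n3("1+1", bicellular_landscape_n4()), "n = 3")
})

test_that("growth_rate returns a consistent eigensystem", {
  L <- bicellular_landscape_n4()
  for (id in c("4:2+1+1", "4:2+2", "3:2+1")) {
    gr <- growth_rate(parse_mode(id), L)
    expect_true(all(gr$w >= 0))
    expect_equal(sum(gr$w), 1)
    expect_lt(max(abs(gr$A %*% gr$w - gr$lambda1 * gr$w)),
              1e-8 * max(1, abs(gr$lambda1)))
    expect_equal(sum(gr$v * gr$w), 1)
  }
  # reducible case: 2+2 never produces unicells, so w has an explicit zero
  gr <- growth_rate(parse_mode("4:2+2"), L)
  expect_equal(gr$w[1], 0)
  expect_true(all(gr$w[2:3] > 0))
  expect_error(growth_rate(matrix(c(1, -0.5, 2, 1), 2, 2)),
               "essentially non-negative")
})

test_that("the 1+1/2+1 mixture interpolates between its pure endpoints", {
  # closed form against the matrix eigenvalue, general landscapes
  set.seed(41)
  for (rep in 1:25) {
    L <- random_landscape(3)
    q <- runif(1)
    expect_equal(growth_rate(mixture_mode_11_21(q), L)$lambda1,
                 mixture_growth_rate_11_21(q, L), tolerance = 1e-10)
  }
  # endpoints are the pure modes
  L <- random_landscape(3)
  expect_equal(mixture_growth_rate_11_21(0, L), closed_form_n3("1+1", L),
               tolerance = 1e-12)
  expect_equal(mixture_growth_rate_11_21(1, L), closed_form_n3("2+1", L),
               tolerance = 1e-12)
  # sandwich: the mixture never beats both pure modes (100 random landscapes)
  set.seed(43)
  for (rep in 1:100) {
    L <- random_landscape(3)
    q <- runif(1)
    lam <- mixture_growth_rate_11_21(q, L)
    l11 <- closed_form_n3("1+1", L); l21 <- closed_form_n3("2+1", L)
    expect_gte(lam, min(l11, l21) - 1e-10)
    expect_lte(lam, max(l11, l21) + 1e-10)
  }
})

test_that("mixed-mode matrices reduce to the pure construction and reject bad probabilities", {
  L <- worked_landscape_n3()
  expect_equal(growth_rate(pure_as_mixed(parse_mode("3:2+1"), 3), L)$lambda1,
               growth_rate(parse_mode("3:2+1"), L)$lambda1, tolerance = 1e-12)
  expect_error(
    mixed_mode(3, list(
      list(stay = 0.5, patterns = list(new_partition(c(1, 1))), probs = 0.4),
      list(stay = 0, patterns = list(new_partition(c(2, 1))), probs = 1)
    )),
    "sum to"
  )
  expect_error(
    mixed_mode(3, list(
      list(stay = 0, patterns = list(new_partition(c(1, 1))), probs = 1),
      list(stay = 0.2, patterns = list(new_partition(c(2, 1))), probs = 0.8)
    )),
    "maximal size"
  )
})

test_that("n = 3 dominance conditions follow the birth/death differences", {
  set.seed(47)
  for (rep in 1:300) {
    L <- random_landscape(3)
    gap <- (L$b[1] - L$b[2]) - (L$d[1] - L$d[2])
    if (abs(gap) < 1e-6) next
    l11 <- closed_form_n3("1+1", L)
    l21 <- closed_form_n3("2+1", L)
    l111 <- closed_form_n3("1+1+1", L)
    if (gap > 0) expect_gte(l11, l111 - 1e-10) else expect_gte(l21, l111 - 1e-10)
  }
})

test_that("the characteristic-equation solver matches dense eigensolving", {
  set.seed(53)
  for (cost in c("costless", "proportional", "fixed")) {
    for (rep in 1:4) {
      n <- sample(4:8, 1)
      L <- random_landscape(n)
      for (m in enumerate_pure_modes(n, cost)) {
        expect_equal(growth_rate_characteristic(m, L),
                     growth_rate(m, L)$lambda1,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("the ODE oracle recovers growth rates independently", {
  expect_equal(ode_growth_rate(matrix(0.3, 1, 1)), 0.3, tolerance = 1e-6)
  L <- worked_landscape_n3()
  expect_equal(ode_growth_rate(projection_matrix(parse_mode("3:2+1"), L)),
               1.5, tolerance = 1e-4)
  L4 <- bicellular_landscape_n4()
  m22 <- parse_mode("4:2+2")
  expect_equal(ode_growth_rate(projection_matrix(m22, L4)),
               growth_rate(m22, L4)$lambda1, tolerance = 1e-4)
})
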
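test_that("costless enumeration matches the closed-form count and has no duplicates", {
  expect_length(enumerate_pure_modes(10), 128)
  expect_identical(count_pure_modes(10), 128)
  expect_identical(count_pure_modes(2), 1)
  expect_identical(count_pure_modes(50), 1295920)
  for (n in 2:8) {
    ids <- mode_ids(enumerate_pure_modes(n))
    expect_equal(length(ids), count_pure_modes(n))
    expect_equal(anyDuplicated(ids), 0L)
  }
})

test_that("cost regimes restrict admissible (trigger, pattern) pairs correctly", {
  expect_setequal(mode_ids(enumerate_pure_modes(4, "proportional")),
                  c("3:1+1", "4:2+1"))
  expect_setequal(mode_ids(enumerate_pure_modes(4, "fixed")),
                  c("3:1+1", "4:2+1", "4:1+1+1"))
  # every enumerated mode satisfies its regime's sum constraint
  for (cost in c("costless", "proportional", "fixed")) {
    for (m in enumerate_pure_modes(8, cost)) {
      l <- m$trigger_size; np <- length(m$pattern); tot <- sum(m$pattern)
      expected <- switch(cost, costless = l, proportional = l - (np - 1),
                         fixed = l - 1)
      expect_equal(tot, expected)
      expect_lt(max(m$pattern), l)
      expect_gte(np, 2)
    }
  }
  expect_error(enumerate_pure_modes(1), "at least 2")
  expect_error(enumerate_pure_modes(2, "proportional"), "proportional")
  expect_error(enumerate_pure_modes(2, "fixed"), "fixed")
})

test_that("binary fraction is exact and matches the known values", {
  expect_equal(format(binary_fraction(3)), "2/3")
  expect_equal(format(binary_fraction(4)), "4/7")
  expect_equal(format(binary_fraction(10)), "25/128")
  bf50 <- binary_fraction(50)
  expect_equal(bf50$num * 1295920, 625 * bf50$den)  # equals 625/1295920
  expect_equal(as.numeric(binary_fraction(4)), 4 / 7)
})

test_that("pure mode constructor enforces admissibility", {
  expect_error(pure_mode(4, new_partition(c(2, 1)), cost = "costless"), "total")
  expect_error(pure_mode(4, new_partition(c(3, 1)), cost = "fixed"), "total")
  expect_error(pure_mode(2, new_partition(c(2, 1))), "total|smaller")
  expect_error(pure_mode(3, new_partition(c(2, 1)), n = 2), "total|exceeds")
  expect_error(pure_mode(4, new_partition(4)), "at least 2 parts")
  m <- parse_mode("4:2+1+1")
  expect_equal(m$trigger_size, 4L)
  expect_equal(format_mode(m), "4:2+1+1")
})

test_that("sampled mixed modes satisfy the probability invariants and are reproducible", {
  for (cost in c("costless", "fixed")) {
    mm <- sample_mixed_mode(6, cost, seed = 11)
    for (i in seq_along(mm$transitions)) {
      tr <- mm$transitions[[i]]
      expect_equal(tr$stay + sum(tr$probs), 1, tolerance = 1e-12)
      expect_true(all(c(tr$stay, tr$probs) >= 0))
    }
    expect_equal(mm$transitions[[5]]$stay, 0)  # top transition
  }
  m1 <- sample_mixed_mode(5, seed = 99)
  m2 <- sample_mixed_mode(5, seed = 99)
  expect_identical(mixed_mode_table(m1), mixed_mode_table(m2))
  # n = 2: the single transition must put all mass on 1+1
  m <- sample_mixed_mode(2, seed = 1)
  expect_equal(m$transitions[[1]]$stay, 0)
  expect_equal(m$transitions[[1]]$probs, 1)
  expect_equal(format_partition(m$transitions[[1]]$patterns[[1]]), "1+1")
})

test_that("stay probabilities below the top are Uniform(0, 1) on average", {
  set.seed(202)
  stays <- replicate(4000, {
    mm <- sample_mixed_mode(4)
    c(mm$transitions[[1]]$stay, mm$transitions[[2]]$stay)
  })
  expect_gt(mean(stays), 0.48)
  expect_lt(mean(stays), 0.52)
})

test_that("a pure mode embeds as a degenerate mixed mode with the same growth rate", {
  m <- parse_mode("4:2+1+1")
  mm <- pure_as_mixed(m, 4)
  expect_equal(mm$transitions[[1]]$stay, 1)  # q_2 = 1
  expect_equal(mm$transitions[[2]]$stay, 1)  # q_3 = 1
  expect_equal(mm$transitions[[3]]$stay, 0)
  expect_equal(mm$transitions[[3]]$probs, 1) # q_{2+1+1} = 1
  m11 <- pure_as_mixed(parse_mode("2:1+1"), 2)
  expect_equal(m11$transitions[[1]]$probs, 1)
  set.seed(5)
  L <- bicellular_landscape_n4()
  for (m in enumerate_pure_modes(4)) {
    expect_equal(growth_rate(pure_as_mixed(m, 4), L)$lambda1,
                 growth_rate(m, L)$lambda1, tolerance = 1e-10)
  }
})
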
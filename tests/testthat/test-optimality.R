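test_that("dominance follows the growth-rate order", {
  L <- worked_landscape_n3()
  expect_true(dominates(parse_mode("3:2+1"), parse_mode("3:1+1+1"), L))
  expect_false(dominates(parse_mode("3:1+1+1"), parse_mode("3:2+1"), L))
  expect_true(dominates(parse_mode("3:2+1"), parse_mode("3:2+1"), L))  # reflexive
  L4 <- bicellular_landscape_n4()
  for (m in enumerate_pure_modes(4))
    expect_true(dominates(parse_mode("4:2+2"), m, L4))
})

test_that("exhaustive search finds the known optima", {
  res <- optimal_mode(bicellular_landscape_n4())
  expect_equal(format_mode(res$mode), "4:2+2")
  res <- optimal_mode(fitness_landscape(b = c(1, 0.1, 0.1)))
  expect_equal(format_mode(res$mode), "2:1+1")
  # harsh survival penalty on groups: fragment at the smallest possible size
  res <- optimal_mode(fitness_landscape(b = rep(1, 3), d = c(0, 5, 5)))
  expect_equal(res$mode$trigger_size, 2L)
  # both methods agree, including ties and winner, on random landscapes
  set.seed(61)
  for (rep in 1:10) {
    L <- random_landscape(6)
    a <- optimal_mode(L, method = "eigen")
    b <- optimal_mode(L, method = "characteristic")
    expect_equal(format_mode(a$mode), format_mode(b$mode))
    expect_equal(a$lambda1, b$lambda1, tolerance = 1e-9)
  }
})

test_that("binary modes dominate on random landscapes (costless and proportional)", {
  set.seed(67)
  for (cost in c("costless", "proportional")) {
    for (rep in 1:100) {
      n <- sample(3:6, 1)
      L <- fitness_landscape(b = runif(n - 1, 0.02, 3), d = runif(n - 1, 0, 3))
      modes <- enumerate_pure_modes(n, cost)
      lam <- vapply(modes, function(m) growth_rate(m, L)$lambda1, 0)
      binary <- vapply(modes, function(m) is_binary(m$pattern), NA)
      if (!any(binary) || all(binary)) next
      expect_lte(max(lam[!binary]), max(lam[binary]) + 1e-10)
    }
  }
})

test_that("sampled mixed modes never beat the best pure mode (n = 4)", {
  set.seed(71)
  for (rep in 1:10) {
    L <- random_landscape(4)
    best_pure <- optimal_mode(L)$lambda1
    lam_mixed <- replicate(100,
      growth_rate(sample_mixed_mode(4), L)$lambda1)
    expect_lte(max(lam_mixed), best_pure + 1e-10)
  }
})

test_that("the n = 4 fecundity map obeys the necessary optimality conditions", {
  grid <- seq(0.25, 4, length.out = 16)
  mp <- optimality_map("fecundity-n4", axis1 = grid, axis2 = grid)
  expect_s3_class(mp, "optimality_map")
  expect_equal(nrow(mp), 256)
  # 2+1 optimal requires pairs to be the most fertile; 2+2 requires unicells
  # to be the least fertile
  win21 <- mp$winner == "3:2+1"
  expect_true(all(mp$axis1[win21] > 1 & mp$axis1[win21] > mp$axis2[win21]))
  win22 <- mp$winner == "4:2+2"
  expect_true(all(mp$axis1[win22] > 1 & mp$axis2[win22] > 1))
  win31 <- mp$winner == "4:3+1"
  expect_true(all(mp$axis2[win31] > 1 & mp$axis2[win31] > mp$axis1[win31]))
  # the reference cell of the bicellular landscape
  cell <- mp[which.min(abs(mp$axis1 - 2) + abs(mp$axis2 - 1.4)), ]
  expect_equal(cell$winner, "4:2+2")
  # winners attain the maximum over the full strategy set (spot-check)
  set.seed(73)
  for (r in sample(nrow(mp), 5)) {
    L <- fitness_landscape(c(1, mp$axis1[r], mp$axis2[r]))
    res <- optimal_mode(L)
    expect_equal(res$lambda1, mp$lambda1[r], tolerance = 1e-9)
  }
})

test_that("fixed-cost fragmentation admits optimal multiple fission at n = 4", {
  grid <- seq(0.25, 4, length.out = 12)
  mp <- optimality_map("fecundity-n4", cost = "fixed", axis1 = grid, axis2 = grid)
  expect_true("4:1+1+1" %in% mp$winner)
})

test_that("region boundaries are located by bisection and bad brackets fail", {
  path <- function(b2) fitness_landscape(c(1, b2, 1.4))
  x <- region_boundary(parse_mode("4:3+1"), parse_mode("4:2+2"), path, 0.5, 2)
  expect_equal(x, 1.11, tolerance = 0.005)
  expect_error(
    region_boundary(parse_mode("4:3+1"), parse_mode("4:2+2"), path, 2, 3),
    "does not change sign")
  expect_error(optimality_map("fecundity-n4", axis1 = c(2, 1), axis2 = c(1, 2)),
               "strictly increasing")
})
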
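test_that("base probabilities follow the p_S construction", {
  expect_equal(base_probabilities(0.25, 0),
               c(p_F = 0.25, p_S = 0.25, p_B = 0.25))
  expect_equal(base_probabilities(0.5, 1),
               c(p_F = 0.5, p_S = 0.25, p_B = 0))
  # direct evaluation: (0.125/3) + (0.4 * 0.125/6) = 0.05, p_B = 0.025
  p <- base_probabilities(0.875, 0.4)
  expect_equal(p[["p_S"]], 0.05)
  expect_equal(p[["p_B"]], 0.025)
  expect_error(base_probabilities(0, 0.5), "p_F")
  expect_error(base_probabilities(0.5, 1.2), "v")
})

test_that("movement parameter sets satisfy the probability identity", {
  set.seed(101)
  for (i in 1:50) {
    pr <- movement_params(runif(1, 0.01, 1), runif(1), runif(1))
    expect_equal(pr$p_F + pr$p_B + 2 * pr$p_S, 1, tolerance = 1e-12)
    expect_true(all(c(pr$p_F, pr$p_S, pr$p_B) >= 0))
  }
  expect_error(movement_params(0.5, 0.5, 1.5), "r")
})

test_that("habitat switching scales preferences by r", {
  land <- uniform_crop_landscape(9, 9)
  pr <- movement_params(0.5, 0.4, 0.3)   # p = (0.5, 0.2, 0.2) F/S each side, B = 0.1
  ctx <- neighbour_context(land, 4, 4, 1)
  # all neighbours share the habitat: identity branch, r plays no role
  expect_equal(adjusted_preferences(pr, ctx),
               c(m_F = 0.5, m_B = 0.1, m_L = 0.2, m_R = 0.2))

  # forward cell differs, r = 0.5 halves only that preference
  land2 <- land
  land2$habitat[5, 6] <- 1L   # cell east of (4,4)
  ctx2 <- neighbour_context(land2, 4, 4, 1)  # heading E: forward = (5,4)
  pr2 <- movement_params(0.5, 0.4, 0.5)
  expect_equal(adjusted_preferences(pr2, ctx2),
               c(m_F = 0.25, m_B = 0.1, m_L = 0.2, m_R = 0.2))

  # r = 0 with every neighbour in the other habitat blocks all moves
  land3 <- land
  land3$habitat[5, 5] <- 1L
  pr0 <- movement_params(0.5, 0.4, 0)
  ctx3 <- neighbour_context(land3, 4, 4, 0)
  expect_equal(unname(adjusted_preferences(pr0, ctx3)), rep(0, 4))
})

test_that("off-grid directions get zero preference", {
  land <- uniform_crop_landscape(5, 5)
  pr <- movement_params(0.5, 0.4, 1)
  ctx <- neighbour_context(land, 0, 0, 3)  # heading W at the corner
  m <- adjusted_preferences(pr, ctx)
  expect_equal(m[["m_F"]], 0)  # west is off-grid
  expect_equal(m[["m_R"]], 0)  # right of W is N, also off-grid at the corner
  expect_gt(m[["m_B"]], 0)     # east is inside
  expect_gt(m[["m_L"]], 0)     # left of W is S, inside
})

test_that("step probabilities normalise preferences", {
  a <- step_probabilities(c(0.25, 0.1, 0.2, 0.2))
  expect_equal(unname(a), c(1 / 3, 2 / 15, 4 / 15, 4 / 15))
  pr <- movement_params(0.6, 0.2, 1)
  m <- c(pr$p_F, pr$p_B, pr$p_S, pr$p_S)
  expect_equal(unname(step_probabilities(m)), m)  # already sums to 1
  expect_equal(sum(step_probabilities(c(0, 0, 0, 0))), 0)  # sentinel
  expect_error(step_probabilities(c(-0.1, 0.2, 0.2, 0.2)), "non-negative")
})

test_that("a fully forward-biased walker moves straight", {
  land <- uniform_crop_landscape(21, 21)
  pr <- movement_params(1, 0, 1)
  st <- list(x = 10L, y = 10L, heading = 1L)
  for (i in 1:5) {
    res <- step(st, land, pr)
    expect_true(res$moved)
    expect_equal(res$state$x, st$x + 1L)
    expect_equal(res$state$heading, 1L)
    st <- res$state
  }
})

test_that("a blocked specialist moves to the only reachable wild cell", {
  land <- uniform_crop_landscape(9, 9)
  land$habitat[5, 5] <- 1L  # walker cell (4,4)
  land$habitat[5, 6] <- 1L  # east neighbour wild
  pr <- movement_params(0.5, 0.4, 0)
  res <- step(list(x = 4L, y = 4L, heading = 1L), land, pr)
  expect_true(res$moved)
  expect_equal(c(res$state$x, res$state$y), c(5L, 4L))
  expect_false(res$switched)
})

test_that("empirical step frequencies match the computed probabilities", {
  land <- uniform_crop_landscape(9, 9)
  land$habitat[5, 6] <- 1L  # east of centre wild
  pr <- movement_params(0.5, 0.4, 0.5)
  ctx <- neighbour_context(land, 4, 4, 1)
  a <- step_probabilities(adjusted_preferences(pr, ctx))
  set.seed(111)
  moves <- replicate(10000, {
    res <- step(list(x = 4L, y = 4L, heading = 1L), land, pr)
    paste(res$state$x, res$state$y)
  })
  # map relative directions (heading E) to target cells F,B,L,R
  targets <- c("5 4", "3 4", "4 3", "4 5")
  counts <- table(factor(moves, levels = targets))
  gof <- chisq.test(as.vector(counts), p = unname(a))
  expect_gt(gof$p.value, 0.01)
})

test_that("compiled and R step-by-step walks agree draw for draw", {
  set.seed(121)
  for (i in 1:5) {
    land <- generate_landscape(40, 40, 6)
    nest <- place_nest(land)
    pr <- movement_params(runif(1, 0.3, 0.9), runif(1), runif(1))
    s <- sample.int(1e6, 1)
    set.seed(s)
    cxx <- simulate_walk(land, nest, pr, T = 200, keep_path = TRUE)
    set.seed(s)
    ref <- r_reference_walk(land, nest, pr, T = 200)
    expect_equal(cxx$path$x, ref$x)
    expect_equal(cxx$path$y, ref$y)
    expect_equal(cxx$max_distance, ref$max_distance)
    expect_equal(cxx$n_switches, ref$n_switches)
    expect_equal(cxx$prop_wild, ref$prop_wild)
  }
})

test_that("straight-line walks reach distance T without switching", {
  land <- uniform_wild_landscape(121, 121)
  tr <- simulate_walk(land, c(60, 60), movement_params(1, 0, 1), T = 50)
  expect_equal(tr$max_distance, 50)
  expect_equal(tr$n_switches, 0)
  expect_equal(tr$prop_wild, 1)
})

test_that("specialists with r = 0 never leave the nest habitat", {
  set.seed(131)
  for (i in 1:10) {
    land <- generate_landscape(60, 60, 8)
    nest <- place_nest(land)
    pr <- movement_params(runif(1, 0.3, 1), runif(1), 0)
    tr <- simulate_walk(land, nest, pr, T = 500, keep_path = TRUE)
    expect_equal(tr$prop_wild, 1)
    expect_equal(tr$n_switches, 0)
    expect_true(all(tr$path$habitat == 1L))
  }
})

test_that("habitat-neutral walks (r = 1) use the base probabilities", {
  set.seed(141)
  land <- generate_landscape(30, 30, 5)
  pr <- movement_params(0.6, 0.3, 1)
  base <- c(pr$p_F, pr$p_B, pr$p_S, pr$p_S)
  for (i in 1:50) {
    x <- sample(1:28, 1); y <- sample(1:28, 1)  # interior cells only
    ctx <- neighbour_context(land, x, y, sample(0:3, 1))
    a <- step_probabilities(adjusted_preferences(pr, ctx))
    expect_equal(unname(a), base)
  }
})

test_that("max distance never exceeds the number of timesteps", {
  set.seed(151)
  for (i in 1:10) {
    land <- generate_landscape(50, 50, 6)
    nest <- place_nest(land)
    pr <- movement_params(runif(1, 0.3, 1), runif(1), runif(1))
    tr <- simulate_walk(land, nest, pr, T = 120)
    expect_lte(tr$max_distance, 120)
  }
})

test_that("mean squared displacement matches the simple-random-walk form", {
  # uniform habitat, p_F = p_S = p_B = 1/4: E[d^2] = T on the unit lattice
  land <- uniform_crop_landscape(301, 301)
  pr <- movement_params(0.25, 0, 1)
  set.seed(161)
  d2 <- replicate(4000, {
    tr <- simulate_walk(land, c(150, 150), pr, T = 100)
    (tr$final_x - 150)^2 + (tr$final_y - 150)^2
  })
  expect_equal(mean(d2), 100, tolerance = 0.05)
})

test_that("walks reject invalid nests and T", {
  land <- uniform_crop_landscape(10, 10)
  pr <- movement_params(0.5, 0.5, 0.5)
  expect_error(simulate_walk(land, c(10, 3), pr, T = 10), "nest")
  expect_error(simulate_walk(land, c(2, 2), pr, T = 0), "T")
})
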
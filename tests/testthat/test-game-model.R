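test_that("expected payoffs use the self-interaction-excluded convention", {
  g <- switchingGame(N = 50, b = 0.5, c = 0.9, beta = 0.5)
  # all-mutant limit: pi_A(N) = a
  expect_equal(unname(expectedPayoffs(50, g, "+1")$piA), 1)
  # neutral game: all payoffs equal 1
  gn <- gameSpec(matrix(1, 1, 4), beta = 0.5, N = 10)
  po <- expectedPayoffs(3, gn, 1L)
  expect_equal(unname(po$piA), 1)
  expect_equal(unname(po$piB), 1)
  expect_error(expectedPayoffs(51, g, "+1"), "0..N")
  # payoff difference changes sign between i = 17 and i = 18 at N = 50
  d <- vapply(17:18, function(i) {
    p <- expectedPayoffs(i, g, "+1"); unname(p$piA - p$piB)
  }, numeric(1))
  expect_gt(d[1], 0)
  expect_lt(d[2], 0)
})

test_that("exponential fitness mapping behaves at the anchors", {
  expect_equal(payoffFitness(2.3, 0), 1)
  expect_equal(payoffFitness(0, 1.7), 1)
  expect_equal(payoffFitness(1, 0.5), exp(0.5))
  expect_error(payoffFitness(1, -0.1), "beta")
})

test_that("Moran transitions match an independent straight-from-formula evaluation", {
  g <- switchingGame(N = 50, b = 0.5, c = 0.9, beta = 0.5)
  m <- moranModel(g)
  # independent recomputation at a handful of states
  for (s in 1:2) {
    sgn <- c(1, -1)[s]
    a <- 1; b <- 1 + sgn * 0.5; cc <- 1 + sgn * 0.9; d <- 1
    for (i in c(1, 7, 25, 49)) {
      N <- 50
      piA <- (a * (i - 1) + b * (N - i)) / (N - 1)
      piB <- (cc * i + d * (N - i - 1)) / (N - 1)
      fA <- exp(0.5 * piA); fB <- exp(0.5 * piB)
      expect_equal(m@tPlus[s, i + 1],
                   (i * fA / (i * fA + (N - i) * fB)) * (N - i) / N,
                   tolerance = 1e-14)
      expect_equal(m@tMinus[s, i + 1],
                   ((N - i) * fB / (i * fA + (N - i) * fB)) * i / N,
                   tolerance = 1e-14)
    }
  }
  # absorbing boundaries
  expect_true(all(m@tPlus[, c(1, 51)] == 0))
  expect_true(all(m@tMinus[, c(1, 51)] == 0))
})

test_that("neutral selection gives symmetric, environment-independent transitions", {
  g <- switchingGame(N = 30, b = 0.4, c = 0.7, beta = 0)
  m <- moranModel(g)
  i <- 0:30
  expect_close(m@tPlus[1, ], i * (30 - i) / 30^2, 1e-14)
  expect_equal(m@tPlus[1, ], m@tPlus[2, ])
  expect_equal(m@tPlus[1, ], m@tMinus[1, ])
})

test_that("transition tables are valid probabilities for randomized games", {
  set.seed(21)
  for (rep in 1:60) {
    N <- sample(2:200, 1)
    po <- matrix(runif(8, 0, 3), 2, 4)
    g <- gameSpec(po, beta = runif(1, 0, 2), N = N)
    m <- moranModel(g)
    expect_true(all(m@tPlus >= 0) && all(m@tMinus >= 0))
    expect_true(all(m@tPlus + m@tMinus <= 1 + 1e-12))
  }
})

test_that("mutation opens the boundaries with escape probability exactly u", {
  u <- 0.02
  g <- switchingGame(N = 50, b = 0.5, c = 0.9, beta = 0.5, u = u)
  m <- moranModel(g)
  expect_false(m@absorbing)
  expect_equal(m@tPlus[, 1], c(u, u))
  expect_equal(m@tMinus[, 51], c(u, u))
  expect_equal(m@tMinus[, 1], c(0, 0))
  # continuity at u = 0: the mutation formulas reduce to the plain process
  g0 <- switchingGame(N = 50, b = 0.5, c = 0.9, beta = 0.5, u = 0)
  m0 <- moranModel(g0)
  gu <- switchingGame(N = 50, b = 0.5, c = 0.9, beta = 0.5, u = 1e-12)
  mu_ <- moranModel(gu)
  expect_close(m0@tPlus[, 2:50], mu_@tPlus[, 2:50], 1e-10)
})

test_that("gradient of selection has the coexistence/coordination sign structure", {
  g <- switchingGame(N = 100, b = 0.5, c = 0.9, beta = 1)
  m <- moranModel(g)
  gp <- gradientOfSelection(m, "+1")[2:100]
  gm <- gradientOfSelection(m, "-1")[2:100]
  # sign(T+ - T-) = sign(sigma (piA - piB)) by monotonicity of exp
  for (i in c(1, 20, 50, 99)) {
    p <- expectedPayoffs(i, g, "+1")
    expect_equal(sign(gp[as.character(i)]),
                 sign(unname(p$piA - p$piB)), ignore_attr = TRUE)
    expect_equal(sign(gm[as.character(i)]),
                 -sign(unname(p$piA - p$piB)), ignore_attr = TRUE)
  }
  # single sign change, at the same interior point in both environments
  flipP <- which(diff(sign(gp)) != 0)
  flipM <- which(diff(sign(gm)) != 0)
  expect_length(flipP, 1)
  expect_equal(flipP, flipM)
  # neutral game: zero gradient
  mn <- moranModel(switchingGame(N = 20, b = 0.3, c = 0.3, beta = 0))
  expect_close(gradientOfSelection(mn, "+1"), rep(0, 21), 1e-15)
})

test_that("selection-balance point matches the printed value and the gradient flip", {
  g <- switchingGame(N = 50, b = 0.5, c = 0.9, beta = 0.5)
  bp <- selectionBalancePoint(g, "+1")
  expect_equal(bp$iStarInt, 18L)
  expect_equal(bp$iStarReal, 50 * 0.5 / 1.4, tolerance = 1e-12)
  expect_equal(bp$leadingOrderFraction, 0.5 / 1.4, tolerance = 1e-12)
  expect_equal(selectionBalancePoint(g, "-1")$iStarInt, 18L)
  # b = c puts the leading-order point at 1/2
  expect_equal(selectionBalancePoint(
    switchingGame(40, 0.3, 0.3, 1), "+1")$leadingOrderFraction, 0.5)
  # agreement with the sign flip of the gradient at integer resolution
  m <- moranModel(g)
  gp <- gradientOfSelection(m, "+1")[2:50]
  flip <- which(diff(sign(gp)) != 0)  # between interior i = flip and flip+1
  expect_true(bp$iStarInt %in% c(flip, flip + 1L))
  # dominance game has no interior balance point
  gd <- gameSpec(rbind(c(2, 1.5, 0.5, 1)), beta = 1, N = 20)
  expect_error(selectionBalancePoint(gd, 1L), "dominance")
})
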
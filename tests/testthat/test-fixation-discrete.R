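test_that("step kernel factorizes population move and environment switch", {
  set.seed(31)
  m <- rand_absorbing_model(5, 2)
  ch <- rand_discrete_chain(2)
  K <- stepKernel(m, ch)
  expect_close(Matrix::rowSums(K@kernel), rep(1, 12), 1e-14)
  # agreement with the independent dense construction
  P <- oracle_joint_matrix(m@tPlus, m@tMinus, envSwitchMatrix(ch))
  expect_close(as.matrix(K@kernel), unname(P), 1e-14)
  # single environment reduces to a tridiagonal chain
  m1 <- rand_absorbing_model(6, 1)
  K1 <- as.matrix(stepKernel(m1, envChainDiscrete(matrix(1, 1, 1)))@kernel)
  expect_true(all(K1[abs(row(K1) - col(K1)) > 1] == 0))
  # boundary rows: population part is frozen, only the environment moves
  Kb <- as.matrix(K@kernel)
  expect_equal(sum(Kb[1, c(1, 7)]), 1)  # state (i=0, s=1) only reaches i=0
})

test_that("direct solvers match the dense fundamental-matrix oracles", {
  set.seed(32)
  worst <- c(phi = 0, t = 0, tau = 0)
  for (rep in 1:60) {
    N <- sample(4:12, 1); om <- sample(1:3, 1)
    m <- rand_absorbing_model(N, om)
    ch <- rand_discrete_chain(om)
    sol <- solveFixation(m, ch)
    or <- oracle_fixation_discrete(m@tPlus, m@tMinus, envSwitchMatrix(ch))
    worst["phi"] <- max(worst["phi"], max(abs(sol@phi - or$phi)))
    worst["t"] <- max(worst["t"], max(abs(sol@tUncond - or$t)))
    worst["tau"] <- max(worst["tau"], max(abs(sol@tCond - or$tau), na.rm = TRUE))
  }
  expect_lt(worst["phi"], 1e-9)
  expect_lt(worst["t"], 1e-9)
  expect_lt(worst["tau"], 1e-9)
})

test_that("single-environment solutions recover the classical closed forms", {
  set.seed(33)
  m <- rand_absorbing_model(10, 1)
  idc <- envChainDiscrete(matrix(1, 1, 1))
  phi <- fixationProbabilities(m, idc)$phi[, 1]
  expect_close(phi, oracle_single_env_phi(m@tPlus[1, ], m@tMinus[1, ]), 1e-10)
  # N=2 neutral: absorption is a fair coin per effective event, mean 2 steps
  one <- birthDeathModel(matrix(c(0, 0.25, 0), 1), matrix(c(0, 0.25, 0), 1))
  expect_equal(unconditionalTimes(one, idc)$tUncond[2, 1], 2, tolerance = 1e-12)
  expect_equal(fixationProbabilities(one, idc)$phi[2, 1], 0.5, tolerance = 1e-12)
})

test_that("boundary conditions and monotonicity of phi hold for random models", {
  set.seed(34)
  for (rep in 1:25) {
    N <- sample(4:14, 1); om <- sample(1:3, 1)
    m <- rand_absorbing_model(N, om)
    ch <- rand_discrete_chain(om)
    sol <- solveFixation(m, ch)
    expect_equal(unname(sol@phi[1, ]), rep(0, om))
    expect_equal(unname(sol@phi[N + 1, ]), rep(1, om))
    expect_true(all(diff(sol@phi) > -1e-12))      # non-decreasing in i
    expect_true(all(sol@tUncond >= -1e-12))
    expect_true(all(sol@tCond[-1, ] >= -1e-12))
    expect_equal(unname(sol@tCond[N + 1, ]), rep(0, om))
    expect_true(all(is.na(sol@tCond[1, ])))
  }
})

test_that("environment relabeling permutes all outputs exactly", {
  set.seed(35)
  m <- rand_absorbing_model(8, 3)
  ch <- rand_discrete_chain(3)
  p <- c(3L, 1L, 2L)
  mP <- birthDeathModel(m@tPlus[p, ], m@tMinus[p, ], absorbing = TRUE)
  chP <- envChainDiscrete(envSwitchMatrix(ch)[p, p])
  a <- solveFixation(m, ch)
  b <- solveFixation(mP, chP)
  expect_close(a@phi[, p], b@phi, 1e-12)
  expect_close(a@tUncond[, p], b@tUncond, 1e-10)
})

test_that("a frozen environment reduces each slice to its own one-environment model", {
  set.seed(36)
  m <- rand_absorbing_model(9, 2)
  sol <- solveFixation(m, envChainDiscrete(diag(2)))
  idc <- envChainDiscrete(matrix(1, 1, 1))
  for (s in 1:2) {
    m1 <- birthDeathModel(m@tPlus[s, , drop = FALSE], m@tMinus[s, , drop = FALSE])
    s1 <- solveFixation(m1, idc)
    expect_close(sol@phi[, s], s1@phi[, 1], 1e-10)
    expect_close(sol@tUncond[, s], s1@tUncond[, 1], 1e-9)
  }
})

test_that("the recursion solver reproduces the direct solution", {
  set.seed(37)
  # random small models; the forward recursion is a shooting method, so the
  # cross-check stays in the moderate-switching regime where it is
  # well-conditioned (strong coupling amplifies roundoff exponentially,
  # which is why the direct solver is the primary path)
  for (rep in 1:20) {
    N <- sample(4:10, 1); om <- sample(1:3, 1)
    m <- rand_absorbing_model(N, om)
    mu <- diag(om) * 0.8 + 0.2 * envSwitchMatrix(rand_discrete_chain(om))
    ch <- envChainDiscrete(unname(mu))
    a <- solveFixation(m, ch, method = "direct")
    b <- solveFixation(m, ch, method = "recursion")
    expect_close(a@phi, b@phi, 1e-8)
    expect_close(a@tUncond, b@tUncond, 1e-7)
    expect_close(a@tCond[-1, ], b@tCond[-1, ], 1e-7)
  }
  # the headline two-environment game across the slow-to-moderate switching
  # grid (the shooting recursion is only well-conditioned there at N = 50)
  g <- switchingGame(N = 50, b = 0.5, c = 0.9, beta = 0.5)
  m <- moranModel(g)
  for (pp in c(1e-4, 1e-3, 1e-2)) {
    ch <- twoEnvChain(pp, 0.01)
    a <- solveFixation(m, ch, method = "direct")
    b <- solveFixation(m, ch, method = "recursion")
    expect_close(a@phi, b@phi, 1e-8)
  }
  # strong coupling at large N is detected and redirected, as is a singular
  # switching matrix
  expect_error(solveFixation(m, twoEnvChain(0.3, 0.3), method = "recursion"),
               "direct solver")
  expect_error(solveFixation(m, twoEnvChain(0.5, 0.5), method = "recursion"),
               "direct solver")
})

test_that("mutation models are rejected by the fixation solvers", {
  m <- moranModel(switchingGame(N = 10, b = 0.5, c = 0.9, beta = 0.5, u = 0.01))
  expect_error(fixationProbabilities(m, twoEnvChain(0.1, 0.1)), "absorbing")
})

test_that("times can be reported in generations", {
  g <- switchingGame(N = 20, b = 0.5, c = 0.9, beta = 0.5)
  sol <- solveFixation(moranModel(g), twoEnvChain(0.05, 0.05))
  expect_equal(fixationTimes(sol, units = "generations"),
               fixationTimes(sol, units = "steps") / 20)
})
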
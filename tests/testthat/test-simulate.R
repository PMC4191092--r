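test_that("identical seeds give bit-identical trajectories", {
  m <- moranModel(switchingGame(N = 30, b = 0.5, c = 0.9, beta = 0.5))
  ch <- twoEnvChain(1e-2, 1e-3)
  a <- simulateTrajectory(m, ch, i0 = 1, sigma0 = "+1", maxTime = 1e5, seed = 99)
  b <- simulateTrajectory(m, ch, i0 = 1, sigma0 = "+1", maxTime = 1e5, seed = 99)
  expect_identical(a@pop, b@pop)
  expect_identical(a@env, b@env)
  expect_identical(a@absorbTime, b@absorbTime)
})

test_that("starting at an absorbing boundary absorbs immediately", {
  m <- moranModel(switchingGame(N = 10, b = 0.5, c = 0.9, beta = 0.5))
  tr <- simulateTrajectory(m, twoEnvChain(0.1, 0.1), i0 = 0, sigma0 = "-1",
                           maxTime = 100, seed = 1)
  expect_true(tr@absorbed)
  expect_equal(tr@absorbTime, 0)
  expect_equal(tr@absorbState, 0L)
})

test_that("empirical one-step frequencies match the step kernel row", {
  set.seed(71)
  m <- rand_absorbing_model(6, 2)
  ch <- rand_discrete_chain(2)
  nDraws <- 2e5
  cts <- oneStepCounts(m, ch, i0 = 3, sigma0 = 1L, nDraws = nDraws, seed = 72)
  mu <- envSwitchMatrix(ch)
  probs <- rbind(m@tMinus[1, 4] * mu[1, ],
                 (1 - m@tPlus[1, 4] - m@tMinus[1, 4]) * mu[1, ],
                 m@tPlus[1, 4] * mu[1, ])
  # each joint cell within 4 binomial standard errors
  se <- sqrt(probs * (1 - probs) / nDraws)
  expect_true(all(abs(cts / nDraws - probs) <= 4 * se + 1e-12))
})

test_that("ensemble fixation estimates agree with the exact solver", {
  # neutral: phi = 1/N
  mN <- moranModel(switchingGame(N = 50, b = 0.5, c = 0.9, beta = 0))
  est <- estimateFixation(mN, twoEnvChain(0.02, 0.05), i0 = 1, sigma0 = "+1",
                          nRuns = 2e4, seed = 73)
  expect_lt(abs(est@phiHat - 0.02), 3 * est@phiSE)
  # selected two-environment model at N = 20: phi and conditional time
  m <- moranModel(switchingGame(N = 20, b = 0.5, c = 0.9, beta = 0.5))
  ch <- twoEnvChain(5e-3, 1e-2)
  sol <- solveFixation(m, ch)
  est2 <- estimateFixation(m, ch, i0 = 1, sigma0 = "-1", nRuns = 2e4, seed = 74)
  expect_equal(est2@nUnabsorbed, 0L)
  expect_lt(abs(est2@phiHat - sol@phi[2, 2]), 3 * est2@phiSE)
  expect_lt(abs(est2@tauHat - sol@tCond[2, 2]), 3 * est2@tauSE)
})

test_that("the simulated environment marginal matches the stationary occupancy", {
  # mutation keeps the run alive for the full horizon
  m <- moranModel(switchingGame(N = 12, b = 0.5, c = 0.9, beta = 0.5, u = 0.02))
  ch <- twoEnvChain(0.02, 0.01)
  tr <- simulateTrajectory(m, ch, i0 = 6, sigma0 = "stationary",
                           maxTime = 2e5, seed = 75)
  # long-run environment occupancy from the trajectory itself
  occ <- mean(tr@env == 1L)
  expect_lt(abs(occ - 1 / 3), 0.05)
})

test_that("Gillespie simulation matches the continuous-time solver", {
  set.seed(76)
  m <- rand_ct_model(8, 2)
  ch <- rand_ct_chain(2)
  sol <- solveFixation(m, ch)
  est <- estimateFixation(m, ch, i0 = 2, sigma0 = 1L, nRuns = 2e4,
                          maxTime = 1e7, seed = 77)
  expect_lt(abs(est@phiHat - sol@phi[3, 1]), 3 * est@phiSE)
  expect_lt(abs(est@tHat - sol@tUncond[3, 1]), 3 * est@tSE)
  # zero switching rates: pure birth-death Gillespie still absorbs
  ch0 <- envChainContinuous(matrix(0, 1, 1), labels = "e1")
  m1 <- rand_ct_model(6, 1)
  tr <- simulateTrajectory(m1, ch0, i0 = 3, sigma0 = 1L, maxTime = 1e6, seed = 78)
  expect_true(tr@absorbed)
})

test_that("ensemble distributions converge to the exact stationary solution", {
  m <- moranModel(switchingGame(N = 20, b = 0.5, c = 0.9, beta = 0.5, u = 0.05))
  ch <- twoEnvChain(0.05, 0.05)
  ex <- stationaryExact(m, ch)
  d <- vapply(c(500, 5000), function(n) {
    ed <- ensembleDistribution(m, ch, nRuns = n, generations = 200,
                               i0 = 10, seed = 79)
    timeAveragedDistance(ed$Q, ex$rhoMarginal)
  }, numeric(1))
  expect_lt(d[2], d[1])     # shrinks with ensemble size
  expect_lt(d[2], 0.03)
  # frozen environment: close to the single-environment product form
  ed <- ensembleDistribution(m, envChainDiscrete(diag(2)), nRuns = 3000,
                             generations = 200, i0 = 10, sigma0 = "+1",
                             seed = 80)
  expect_lt(timeAveragedDistance(ed$Q, stationarySingleEnv(m, "+1")), 0.03)
})
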
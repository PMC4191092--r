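fig5_model <- function(N = 50) {
  moranModel(switchingGame(N = N, b = 0.5, c = 0.9, beta = 0.5, u = 0.02))
}

test_that("exact joint stationary distribution is a unit-residual eigenvector", {
  m <- fig5_model()
  ex <- stationaryExact(m, twoEnvChain(1e-3, 1e-3))
  expect_true(all(ex$rhoJoint >= 0))
  expect_equal(sum(ex$rhoJoint), 1, tolerance = 1e-12)
  expect_lt(ex$residual, 1e-10)
  expect_close(rowSums(ex$rhoJoint), ex$rhoMarginal, 1e-14)
  expect_error(stationaryExact(moranModel(switchingGame(10, 0.5, 0.9, 0.5)),
                               twoEnvChain(0.1, 0.1)), "u > 0")
})

test_that("frozen environments reproduce the product form through the eigen route", {
  m <- fig5_model(30)
  ex <- stationaryExact(m, envChainDiscrete(diag(2)))
  for (s in 1:2) {
    slice <- ex$rhoJoint[, s] / sum(ex$rhoJoint[, s])
    expect_close(slice, stationarySingleEnv(m, s), 1e-10)
  }
})

test_that("single-environment product form matches an eigen cross-check", {
  set.seed(61)
  # random non-absorbing model
  tp <- matrix(runif(12, 0.05, 0.4), 1)
  tm <- matrix(runif(12, 0.05, 0.4), 1)
  tp[12] <- 0; tm[1] <- 0  # i = N cannot go up, i = 0 cannot go down
  m <- birthDeathModel(tp, tm, absorbing = FALSE)
  rho <- stationarySingleEnv(m, 1L)
  K <- stepKernel(m, envChainDiscrete(matrix(1, 1, 1)))@kernel
  expect_close(as.numeric(rho %*% K), rho, 1e-12)
  # symmetric neutral model with mutation: symmetric distribution
  ms <- moranModel(switchingGame(N = 20, b = 0.5, c = 0.5, beta = 0, u = 0.05))
  rs <- stationarySingleEnv(ms, "+1")
  expect_close(rs, rev(rs), 1e-12)
})

test_that("coordination environment is strongly peaked near fixation", {
  m <- fig5_model()
  rho <- stationarySingleEnv(m, "-1")
  expect_gt(which.max(rho) - 1, 45)
})

test_that("exact solution at the headline parameters is trimodal", {
  m <- fig5_model()
  ex <- stationaryExact(m, twoEnvChain(1e-3, 1e-3))
  rho <- ex$rhoMarginal
  modes <- which(diff(sign(diff(rho))) == -2)  # interior local maxima
  modes <- as.integer(names(rho)[modes + 1L])
  peaks <- rho[c(1, length(rho))] > rho[c(2, length(rho) - 1)]
  allModes <- sort(unique(c(modes, c(0, 50)[peaks])))
  expect_true(any(allModes <= 2))                  # near extinction
  expect_true(any(abs(allModes - 18) <= 2))        # near the balance point
  expect_true(any(allModes >= 48))                 # near fixation
})

test_that("averaged distribution is the occupancy-weighted mixture", {
  m <- fig5_model(30)
  rhoS <- cbind(stationarySingleEnv(m, "+1"), stationarySingleEnv(m, "-1"))
  # equal switching: exactly in between
  avg <- stationaryAveraged(rhoS, c(0.5, 0.5))
  expect_close(avg, 0.5 * rhoS[, 1] + 0.5 * rhoS[, 2], 1e-14)
  # weight 1 on one environment returns it
  expect_close(stationaryAveraged(rhoS, c(1, 0)), rhoS[, 1], 1e-14)
  # p+ = 1e-3, p- = 1e-4: mixture dominated by the -1 environment
  w <- stationaryOccupancy(twoEnvChain(1e-3, 1e-4))
  avg2 <- stationaryAveraged(rhoS, w)
  expect_close(avg2, (1 / 11) * rhoS[, 1] + (10 / 11) * rhoS[, 2], 1e-12)
  expect_error(stationaryAveraged(rhoS, c(0.7, 0.7)), "sum to 1")
})

test_that("effective stationary distribution: eigen cross-check and flat centre", {
  m <- fig5_model()
  rhoE <- stationaryEffective(m, 1e-3, 1e-3)
  # eigen cross-check of the product form on the effective chain
  eff <- effectiveModel(m, 1e-3, 1e-3)
  K <- stepKernel(birthDeathModel(matrix(eff@tPlusEff, 1),
                                  matrix(eff@tMinusEff, 1),
                                  absorbing = FALSE),
                  envChainDiscrete(matrix(1, 1, 1)))@kernel
  expect_close(as.numeric(rhoE %*% K), rhoE, 1e-12)
  # near-neutral effective game at p+ = p-: centre above the boundary values
  centre <- rhoE[18:34]
  expect_gt(min(centre), rhoE[[1]])
  expect_gt(min(centre), rhoE[[51]])
})

test_that("distribution distance is the L2 norm with guard rails", {
  q <- c(1, rep(0, 10)); r <- c(rep(0, 10), 1)
  expect_equal(distributionDistance(q, q), 0)
  expect_equal(distributionDistance(q, r), sqrt(2))
  expect_equal(distributionDistance(q, r, norm = "l1"), 2)
  expect_error(distributionDistance(q * 2, r), "normalized")
  # time averaging uses only the second half of the series
  qs <- cbind(q, q, r, r)  # halves differ
  expect_equal(timeAveragedDistance(qs, r), 0)
  expect_equal(timeAveragedDistance(qs, q), sqrt(2))
})

test_that("environment relabeling leaves the marginal invariant", {
  m <- fig5_model(24)
  ex <- stationaryExact(m, twoEnvChain(2e-3, 5e-4))
  mP <- birthDeathModel(m@tPlus[2:1, ], m@tMinus[2:1, ], absorbing = FALSE)
  chP <- envChainDiscrete(envSwitchMatrix(twoEnvChain(2e-3, 5e-4))[2:1, 2:1])
  exP <- stationaryExact(mP, chP)
  expect_close(ex$rhoMarginal, exP$rhoMarginal, 1e-12)
  expect_close(ex$rhoJoint[, 2:1], exP$rhoJoint, 1e-12)
})

test_that("disparate switching rates collapse every description onto one environment", {
  m <- fig5_model()
  ss <- stationarySolution(m, 0.05, 1e-4)  # environment mostly -1
  ref <- ss@rhoSingle[, "-1"]
  expect_lt(distributionDistance(ss@rhoMarginal, ref), 0.05)
  expect_lt(distributionDistance(ss@rhoAvg, ref), 0.05)
  expect_lt(distributionDistance(ss@rhoEff, ref), 0.05)
})
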
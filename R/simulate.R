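.resolveSigma0 <- function(sigma0, chain, nRuns) {
  # returns 0-based environment indices, one per run
  if (identical(sigma0, "stationary")) {
    w <- stationaryOccupancy(chain)
    return(sample.int(length(w), nRuns, replace = TRUE, prob = w) - 1L)
  }
  rep(.envIndex(sigma0, chain@labels) - 1L, nRuns)
}

#' Simulate one trajectory of the joint process
#'
#' Discrete chains advance in elementary steps: the population moves using
#' the step-start environment's probabilities, then the environment switches
#' — exactly the factorization of the one-step kernel. Continuous chains use
#' the Gillespie algorithm with environment switches and birth-death events
#' as separate exponential-clock events.
#'
#' @param model a [BirthDeathModel][BirthDeathModel-class].
#' @param chain an [EnvChain][EnvChain-class] of matching convention.
#' @param i0 initial mutant count.
#' @param sigma0 initial environment (label, \eqn{\pm 1}, index, or
#'   `"stationary"` for a draw from the occupancy distribution).
#' @param maxTime step budget (discrete) or time horizon (continuous); for
#'   absorbing models the run stops at absorption, and exhausting the budget
#'   without absorbing is flagged, not an error.
#' @param seed optional integer seed (`set.seed`).
#' @param recordEvery thinning interval for the stored series.
#' @return A [Trajectory][Trajectory-class].
#' @examples
#' game <- switchingGame(N = 50, b = 0.5, c = 0.9, beta = 0.5)
#' tr <- simulateTrajectory(moranModel(game), twoEnvChain(1e-3, 1e-4),
#'                          i0 = 1, sigma0 = "+1", maxTime = 1e6, seed = 1)
#' @export
simulateTrajectory <- function(model, chain, i0, sigma0, maxTime,
                               seed = NULL, recordEvery = 1L) {
  if (!is.null(seed)) set.seed(seed)
  if (i0 < 0 || i0 > model@N) stop("i0 must lie in 0..N")
  s0 <- .resolveSigma0(sigma0, chain, 1L)
  if (is(chain, "EnvChainDiscrete")) {
    .checkPair(model, chain, "discrete")
    raw <- cpp_simulate_discrete(model@tPlus, model@tMinus, chain@mu,
                                 as.integer(i0), s0, maxTime,
                                 model@absorbing, as.integer(recordEvery))
    conv <- "discrete"
  } else {
    .checkPair(model, chain, "continuous")
    raw <- cpp_simulate_gillespie(model@tPlus, model@tMinus, chain@rates,
                                  as.integer(i0), s0, maxTime,
                                  model@absorbing, as.integer(recordEvery))
    conv <- "continuous"
  }
  new("Trajectory", time = raw$time, pop = as.integer(raw$pop),
      env = as.integer(raw$env), labels = chain@labels,
      absorbed = raw$absorbed,
      absorbState = if (raw$absorbed) as.integer(raw$final_pop) else NA_integer_,
      absorbTime = raw$absorb_time, timeConvention = conv)
}

#' Monte Carlo estimates of fixation statistics
#'
#' Runs an ensemble of independent realizations from `(i0, sigma0)` and
#' estimates the fixation probability \eqn{\hat\phi} (with binomial standard
#' error \eqn{\sqrt{\hat\phi(1-\hat\phi)/n}}), the mean unconditional
#' absorption time, and the mean fixation time conditioned on fixation
#' (averaged over fixed runs only, with sample standard errors).
#'
#' @inheritParams simulateTrajectory
#' @param nRuns number of realizations.
#' @param maxTime per-run step/time budget; unabsorbed runs are counted in
#'   `nUnabsorbed` and excluded from the time averages.
#' @return An [EnsembleEstimate][EnsembleEstimate-class].
#' @export
estimateFixation <- function(model, chain, i0 = 1L, sigma0, nRuns,
                             maxTime = 1e9, seed = NULL) {
  if (!model@absorbing) stop("fixation estimation requires u = 0")
  if (nRuns < 1) stop("nRuns must be positive")
  if (!is.null(seed)) set.seed(seed)
  s0 <- .resolveSigma0(sigma0, chain, as.integer(nRuns))
  if (is(chain, "EnvChainDiscrete")) {
    .checkPair(model, chain, "discrete")
    raw <- cpp_fixation_ensemble(model@tPlus, model@tMinus, chain@mu,
                                 as.integer(i0), s0, maxTime)
    times <- raw$steps
    conv <- "discrete"
  } else {
    .checkPair(model, chain, "continuous")
    raw <- cpp_fixation_ensemble_ct(model@tPlus, model@tMinus, chain@rates,
                                    as.integer(i0), s0, maxTime)
    times <- raw$times
    conv <- "continuous"
  }
  absorbed <- raw$absorbed
  fixed <- raw$fixed
  n <- as.integer(nRuns)
  phiHat <- mean(fixed)
  tAbs <- times[absorbed]
  tFix <- times[fixed]
  new("EnsembleEstimate",
      phiHat = phiHat,
      phiSE = sqrt(phiHat * (1 - phiHat) / n),
      tHat = mean(tAbs),
      tSE = if (length(tAbs) > 1) sd(tAbs) / sqrt(length(tAbs)) else NA_real_,
      tauHat = if (length(tFix)) mean(tFix) else NA_real_,
      tauSE = if (length(tFix) > 1) sd(tFix) / sqrt(length(tFix)) else NA_real_,
      nRuns = n, nFixed = sum(fixed), nUnabsorbed = sum(!absorbed),
      timeConvention = conv)
}

#' Ensemble time series of the population distribution
#'
#' Simulates `nRuns` independent realizations of a model with mutation for
#' `generations` generations (\eqn{N} steps each) and records the empirical
#' distribution \eqn{Q_i(t)} of the population over the ensemble at every
#' sampled time.
#'
#' @inheritParams simulateTrajectory
#' @param nRuns ensemble size.
#' @param generations total simulated time \eqn{T} in generations.
#' @param sampleEveryGenerations sampling interval in generations.
#' @return List with `Q` (\eqn{(N+1)\times n_t} column-stochastic matrix)
#'   and `timesGenerations`.
#' @seealso [timeAveragedDistance()] for scoring against stationary
#'   distributions (the first half of the series is discarded there).
#' @export
ensembleDistribution <- function(model, chain, nRuns, generations,
                                 i0, sigma0 = "stationary",
                                 sampleEveryGenerations = 1,
                                 seed = NULL) {
  .checkPair(model, chain, "discrete")
  if (model@absorbing)
    stop("ensemble distributions are for models with mutation (u > 0)")
  if (!is.null(seed)) set.seed(seed)
  s0 <- .resolveSigma0(sigma0, chain, as.integer(nRuns))
  N <- model@N
  every <- as.integer(round(sampleEveryGenerations * N))
  total <- generations * N
  counts <- cpp_ensemble_hist(model@tPlus, model@tMinus, chain@mu,
                              as.integer(i0), s0, total, every)
  Q <- counts / nRuns
  rownames(Q) <- 0:N
  list(Q = Q,
       timesGenerations = seq_len(ncol(Q)) * sampleEveryGenerations)
}

#' Empirical one-step frequencies from a fixed joint state
#'
#' Draws `nDraws` single steps of the discrete process from `(i0, sigma0)`
#' and tallies the joint outcome (population move, next environment); useful
#' for validating the simulator against the one-step kernel.
#'
#' @inheritParams simulateTrajectory
#' @param nDraws number of independent one-step draws.
#' @return `3 x Omega` matrix of counts; rows are moves `-1`, `0`, `+1`.
#' @export
oneStepCounts <- function(model, chain, i0, sigma0, nDraws, seed = NULL) {
  .checkPair(model, chain, "discrete")
  if (!is.null(seed)) set.seed(seed)
  s0 <- .resolveSigma0(sigma0, chain, 1L)
  cts <- cpp_one_step_counts(model@tPlus, model@tMinus, chain@mu,
                             as.integer(i0), s0, as.integer(nDraws))
  dimnames(cts) <- list(c("-1", "0", "+1"), chain@labels)
  cts
}

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory (%s time): %d samples", object@timeConvention,
              length(object@time)))
  if (object@absorbed)
    cat(sprintf("; absorbed at i = %d, time %.6g", object@absorbState,
                object@absorbTime))
  cat("\n")
})

setMethod("show", "EnsembleEstimate", function(object) {
  cat(sprintf("Ensemble estimate over %d runs (%s time)\n", object@nRuns,
              object@timeConvention))
  cat(sprintf("  phi-hat = %.5g (SE %.3g), fixed %d runs\n", object@phiHat,
              object@phiSE, object@nFixed))
  cat(sprintf("  mean unconditional time = %.6g (SE %.3g)\n", object@tHat,
              object@tSE))
  cat(sprintf("  mean conditional time   = %.6g (SE %.3g)\n", object@tauHat,
              object@tauSE))
  if (object@nUnabsorbed > 0)
    cat(sprintf("  WARNING: %d run(s) exhausted the budget unabsorbed\n",
                object@nUnabsorbed))
})
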
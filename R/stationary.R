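# product form rho_i proportional to prod_{j=1}^{i} T+_{j-1} / T-_j,
# accumulated in log space.
.productFormStationary <- function(tp, tm) {
  N <- length(tp) - 1L
  num <- tp[1:N]        # T+_{j-1}, j = 1..N
  den <- tm[2:(N + 1L)] # T-_j
  if (any(den <= 0))
    stop("zero death probability T- at a state needed by the product form")
  if (any(num <= 0))
    stop("zero birth probability T+ at a state needed by the product form")
  lw <- c(0, cumsum(log(num) - log(den)))
  w <- exp(lw - max(lw))
  rho <- w / sum(w)
  names(rho) <- 0:N
  rho
}

# left eigenvector at eigenvalue 1 of a (sparse) stochastic matrix, by a
# direct solve of (K^T - I) rho = 0 with the normalization sum(rho) = 1
# replacing one equation, plus iterative refinement.
.leftEigenOne <- function(K) {
  M <- nrow(K)
  A <- Matrix::t(K) - Matrix::Diagonal(M)
  A[M, ] <- 1
  b <- c(rep(0, M - 1L), 1)
  sol <- .solveRefine(A, b)
  rho <- pmax(sol$x, 0)
  rho <- rho / sum(rho)
  resid <- max(abs(as.numeric(rho %*% K) - rho))
  list(rho = rho, residual = resid)
}

#' Exact joint stationary distribution with mutation
#'
#' Finds the stationary probabilities \eqn{\rho_{i,\sigma}} of the joint
#' population-environment chain as the left eigenvector at eigenvalue 1 of
#' the one-step kernel, and the population marginal
#' \eqn{\rho_i = \sum_\sigma \rho_{i,\sigma}}. Requires mutation
#' (\eqn{u > 0}; no absorbing states). For a frozen environment (diagonal
#' \eqn{\mu}) the joint chain decomposes into independent blocks; each block
#' is then solved separately and the slices are combined with
#' `frozenWeights` (uniform by default). Other reducible chains are
#' rejected.
#'
#' @param model a non-absorbing discrete
#'   [BirthDeathModel][BirthDeathModel-class].
#' @param chain an [EnvChainDiscrete][EnvChain-class].
#' @param frozenWeights optional weights over environments used only when
#'   \eqn{\mu} is diagonal.
#' @return List with `rhoJoint` (\eqn{(N+1)\times\Omega}), `rhoMarginal`,
#'   and `residual` (\eqn{\|\rho^T R - \rho^T\|_\infty}).
#' @export
stationaryExact <- function(model, chain, frozenWeights = NULL) {
  .checkPair(model, chain, "discrete")
  if (model@absorbing)
    stop("stationary distribution requires mutation (u > 0)")
  N <- model@N; om <- model@omega
  mu <- chain@mu
  off <- mu; diag(off) <- 0
  if (om > 1L && all(off == 0)) {
    # frozen environment: solve each block's eigenvector separately
    w <- frozenWeights %||% rep(1 / om, om)
    rhoJoint <- matrix(0, N + 1L, om)
    resid <- 0
    for (s in seq_len(om)) {
      one <- birthDeathModel(model@tPlus[s, , drop = FALSE],
                             model@tMinus[s, , drop = FALSE],
                             absorbing = FALSE, timeConvention = "discrete")
      K <- stepKernel(one, envChainDiscrete(matrix(1, 1, 1)))@kernel
      eg <- .leftEigenOne(K)
      rhoJoint[, s] <- w[s] * eg$rho
      resid <- max(resid, eg$residual)
    }
  } else {
    if (om > 1L && !.isIrreducible(off))
      stop("environment chain is reducible; closed subset: {",
           paste(chain@labels[.closedSubset(off)], collapse = ", "), "}")
    K <- stepKernel(model, chain)@kernel
    eg <- .leftEigenOne(K)
    rhoJoint <- matrix(eg$rho, N + 1L, om)
    resid <- eg$residual
  }
  dimnames(rhoJoint) <- list(0:N, model@labels)
  list(rhoJoint = rhoJoint,
       rhoMarginal = setNames(rowSums(rhoJoint), 0:N),
       residual = resid)
}

#' Single-environment stationary distribution (product form)
#'
#' In a fixed environment \eqn{\sigma} the stationary distribution of the
#' one-step birth-death chain with mutation has the explicit product form
#' \deqn{\rho^{(\sigma)}_i \propto \prod_{j=1}^{i}
#'   \frac{T^+_{j-1,\sigma}}{T^-_{j,\sigma}}.}
#'
#' @inheritParams stationaryExact
#' @param sigma environment label or index.
#' @return Numeric stationary distribution over \eqn{i = 0,\dots,N}.
#' @export
stationarySingleEnv <- function(model, sigma) {
  if (model@absorbing)
    stop("stationary distribution requires mutation (u > 0)")
  s <- .envIndex(sigma, model@labels)
  .productFormStationary(model@tPlus[s, ], model@tMinus[s, ])
}

#' Slow-switching averaged stationary distribution
#'
#' If environmental states are long-lived, the population relaxes to the
#' current environment's stationary distribution between switches, so the
#' overall distribution is the occupancy-weighted mixture
#' \eqn{\bar\rho_i = \sum_\sigma \rho_\sigma\, \rho_i^{(\sigma)}}.
#'
#' @param rhoSingle \eqn{(N+1)\times\Omega} matrix whose columns are the
#'   single-environment distributions.
#' @param envWeights stationary environment occupancies, summing to 1.
#' @return Numeric distribution over \eqn{i}.
#' @export
stationaryAveraged <- function(rhoSingle, envWeights) {
  rhoSingle <- as.matrix(rhoSingle)
  if (abs(sum(envWeights) - 1) > 1e-10) stop("weights must sum to 1")
  if (ncol(rhoSingle) != length(envWeights))
    stop("one weight per environment required")
  rho <- as.numeric(rhoSingle %*% envWeights)
  names(rho) <- rownames(rhoSingle)
  rho
}

#' Fast-switching effective stationary distribution
#'
#' Product-form stationary distribution of the one-environment chain with
#' the occupancy-weighted effective transition probabilities (built from a
#' model with mutation).
#'
#' @param model a non-absorbing two-environment model.
#' @param pPlus,pMinus telegraph switching probabilities.
#' @return Numeric distribution over \eqn{i}.
#' @export
stationaryEffective <- function(model, pPlus, pMinus) {
  eff <- effectiveModel(model, pPlus = pPlus, pMinus = pMinus)
  effectiveStationary(eff)
}

#' Bundle all stationary solutions for a two-environment model
#'
#' Convenience wrapper computing the exact joint solution, the marginal, the
#' two single-environment product forms, the occupancy-weighted average and
#' the effective approximation in one object.
#'
#' @param model non-absorbing two-environment discrete model.
#' @param pPlus,pMinus telegraph switching probabilities (positive sum).
#' @return A [StationarySolution][StationarySolution-class].
#' @examples
#' m <- moranModel(switchingGame(N = 30, b = 0.5, c = 0.9,
#'                               beta = 0.5, u = 0.02))
#' s <- stationarySolution(m, 1e-3, 1e-3)
#' @export
stationarySolution <- function(model, pPlus, pMinus) {
  chain <- twoEnvChain(pPlus, pMinus)
  ex <- stationaryExact(model, chain)
  w <- stationaryOccupancy(chain)
  rhoSingle <- cbind(stationarySingleEnv(model, "+1"),
                     stationarySingleEnv(model, "-1"))
  colnames(rhoSingle) <- model@labels
  new("StationarySolution",
      rhoJoint = ex$rhoJoint, rhoMarginal = ex$rhoMarginal,
      rhoSingle = rhoSingle,
      rhoAvg = stationaryAveraged(rhoSingle, w),
      rhoEff = stationaryEffective(model, pPlus, pMinus),
      envWeights = w, labels = model@labels,
      diagnostics = list(eigenResidual = ex$residual))
}

#' Distance between two population distributions
#'
#' Euclidean (L2) distance over the population states,
#' \eqn{d = \sqrt{\sum_i (q_i - \rho_i)^2}} (or the L1 distance with
#' `norm = "l1"`), used to score a simulated instantaneous distribution
#' against a candidate stationary distribution.
#'
#' @param q,rho numeric distributions over \eqn{i = 0,\dots,N} (each must
#'   sum to 1).
#' @param norm `"l2"` (default) or `"l1"`.
#' @return Non-negative scalar.
#' @export
distributionDistance <- function(q, rho, norm = "l2") {
  norm <- match.arg(norm, c("l2", "l1"))
  if (length(q) != length(rho)) stop("distributions must have equal length")
  if (abs(sum(q) - 1) > 1e-6 || abs(sum(rho) - 1) > 1e-6)
    stop("inputs must be normalized distributions")
  if (norm == "l2") sqrt(sum((q - rho)^2)) else sum(abs(q - rho))
}

#' Time-averaged distance of an ensemble series to a reference
#'
#' Averages [distributionDistance()] over the second half of a time series
#' of instantaneous distributions: the first half is discarded to remove
#' remnants of the initial condition.
#'
#' @param qSeries \eqn{(N+1)\times n_t} matrix; column \eqn{k} is the
#'   empirical distribution at sample time \eqn{k}.
#' @param rho reference distribution.
#' @inheritParams distributionDistance
#' @return Scalar \eqn{\langle d\rangle}.
#' @export
timeAveragedDistance <- function(qSeries, rho, norm = "l2") {
  qSeries <- as.matrix(qSeries)
  nt <- ncol(qSeries)
  keep <- seq.int(floor(nt / 2) + 1L, nt)
  mean(vapply(keep, function(k) distributionDistance(qSeries[, k], rho, norm),
              numeric(1)))
}

setMethod("show", "StationarySolution", function(object) {
  N <- length(object@rhoMarginal) - 1L
  cat(sprintf("Stationary solution: N = %d, environments: %s\n",
              N, paste(object@labels, collapse = ", ")))
  cat(sprintf("environment occupancies: %s\n",
              paste(sprintf("%s: %.4g", object@labels, object@envWeights),
                    collapse = ", ")))
  cat(sprintf("eigen residual: %.3g\n",
              object@diagnostics$eigenResidual))
  cat("marginal mode at i =", which.max(object@rhoMarginal) - 1L, "\n")
})
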
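# Continuous time: environment switches (rates m) and birth-death events
# (rates T~+-) are separate events.  The stationary backward equations for
# each interior (i, s) read
#   (T+ + T- + sum_{s'!=s} m_{s,s'}) x_{i,s} =
#       T+ x_{i+1,s} + T- x_{i-1,s} + sum_{s'!=s} m_{s,s'} x_{i,s'} + g_{i,s}
# with g = 0 for phi, g = 1 for unconditional times, g = phi for theta.

.continuousInteriorOperator <- function(model, chain) {
  N <- model@N; om <- model@omega
  m <- chain@rates
  diag(m) <- 0
  mtot <- rowSums(m)
  nI <- N - 1L
  idx <- function(i, s) (s - 1L) * nI + i
  ii <- jj <- xx <- list()
  k <- 0L
  for (s in seq_len(om)) {
    tp <- model@tPlus[s, ]; tm <- model@tMinus[s, ]
    i <- seq_len(nI)
    exitRate <- tp[i + 1L] + tm[i + 1L] + mtot[s]
    if (any(exitRate <= 0))
      stop("zero total exit rate at an interior state")
    k <- k + 1L
    ii[[k]] <- idx(i, s); jj[[k]] <- idx(i, s); xx[[k]] <- exitRate
    if (nI >= 2L) {
      iu <- 1:(nI - 1L)
      k <- k + 1L
      ii[[k]] <- idx(iu, s); jj[[k]] <- idx(iu + 1L, s)
      xx[[k]] <- -tp[iu + 1L]
      id <- 2:nI
      k <- k + 1L
      ii[[k]] <- idx(id, s); jj[[k]] <- idx(id - 1L, s)
      xx[[k]] <- -tm[id + 1L]
    }
    for (sp in seq_len(om)) {
      if (sp == s || m[s, sp] == 0) next
      k <- k + 1L
      ii[[k]] <- idx(i, s); jj[[k]] <- idx(i, sp)
      xx[[k]] <- rep(-m[s, sp], nI)
    }
  }
  M <- nI * om
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(M, M))
}

#' Fixation probabilities in the continuous-time model
#'
#' Stationary limit of the backward master equation with separate
#' environment-switching and birth-death events; boundaries
#' \eqn{\phi_{0,\sigma} = 0}, \eqn{\phi_{N,\sigma} = 1}.
#'
#' @param model a continuous-convention
#'   [BirthDeathModel][BirthDeathModel-class] (absorbing).
#' @param chain an [EnvChainContinuous][EnvChain-class].
#' @return List with `phi` and `residual`.
#' @export
fixationProbabilitiesCT <- function(model, chain) {
  .checkPair(model, chain, "continuous")
  if (!model@absorbing) stop("fixation requires an absorbing model")
  N <- model@N; om <- model@omega
  A <- .continuousInteriorOperator(model, chain)
  b <- numeric((N - 1L) * om)
  for (s in seq_len(om)) b[(s - 1L) * (N - 1L) + (N - 1L)] <- model@tPlus[s, N]
  sol <- .solveRefine(A, b)
  phi <- .interiorToFull(sol$x, N, om, 0, 1)
  dimnames(phi) <- list(0:N, model@labels)
  list(phi = phi, residual = sol$residual)
}

#' Mean unconditional fixation times (continuous time)
#'
#' Same linear operator with inhomogeneity 1: time accrues as exponential
#' holding times with mean one over the total exit rate per visit. Units are
#' model time.
#'
#' @inheritParams fixationProbabilitiesCT
#' @return List with `tUncond` and `residual`.
#' @export
unconditionalTimesCT <- function(model, chain) {
  .checkPair(model, chain, "continuous")
  if (!model@absorbing) stop("fixation times require an absorbing model")
  N <- model@N; om <- model@omega
  A <- .continuousInteriorOperator(model, chain)
  b <- rep(1, (N - 1L) * om)
  sol <- .solveRefine(A, b)
  tU <- .interiorToFull(sol$x, N, om, 0, 0)
  dimnames(tU) <- list(0:N, model@labels)
  list(tUncond = tU, residual = sol$residual)
}

#' Mean conditional fixation times (continuous time)
#'
#' Applies the backward operator to \eqn{\theta = \phi\,\tau^A} with
#' inhomogeneity \eqn{\phi_{i,\sigma}}; \eqn{\tau^A = \theta/\phi}.
#'
#' @inheritParams fixationProbabilitiesCT
#' @param phi optional precomputed fixation probabilities.
#' @return List with `tCond`, `theta` and `residual`.
#' @export
conditionalTimesCT <- function(model, chain, phi = NULL) {
  .checkPair(model, chain, "continuous")
  if (!model@absorbing) stop("fixation times require an absorbing model")
  N <- model@N; om <- model@omega
  if (is.null(phi)) phi <- fixationProbabilitiesCT(model, chain)$phi
  if (any(phi[2:N, ] <= 0))
    stop("phi vanishes at an interior state; interior positivity violated")
  A <- .continuousInteriorOperator(model, chain)
  b <- as.vector(phi[2:N, ])
  sol <- .solveRefine(A, b)
  theta <- .interiorToFull(sol$x, N, om, 0, 0)
  tau <- theta / phi
  tau[1L, ] <- NA_real_
  dimnames(tau) <- list(0:N, model@labels)
  list(tCond = tau, theta = theta, residual = sol$residual)
}

#' @rdname solveFixation
#' @export
setMethod("solveFixation", signature("BirthDeathModel", "EnvChainContinuous"),
  function(model, chain, method = "direct") {
    f <- fixationProbabilitiesCT(model, chain)
    tu <- unconditionalTimesCT(model, chain)
    tc <- conditionalTimesCT(model, chain, phi = f$phi)
    new("FixationSolution", phi = f$phi, tUncond = tu$tUncond,
        tCond = tc$tCond, N = model@N, labels = model@labels,
        timeConvention = "continuous", method = "direct",
        diagnostics = list(residualPhi = f$residual,
                           residualT = tu$residual,
                           residualTheta = tc$residual))
  })
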
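# Joint states are ordered in environment-major blocks: index of (i, s) is
# (s - 1) * (N + 1) + i + 1, with i = 0..N and s = 1..Omega.

#' Assemble the joint one-step kernel
#'
#' \eqn{R_{(i,\sigma)\to(i\pm 1,\sigma')} = T^\pm_{i,\sigma}\,
#' \mu_{\sigma\to\sigma'}} and
#' \eqn{R_{(i,\sigma)\to(i,\sigma')} = (1 - T^+_{i,\sigma} -
#' T^-_{i,\sigma})\,\mu_{\sigma\to\sigma'}}: within one time step the
#' population moves using the step-start environment, then the environment
#' switches.
#'
#' @param model a discrete [BirthDeathModel][BirthDeathModel-class].
#' @param chain an [EnvChainDiscrete][EnvChain-class] with matching
#'   environment set.
#' @return A [StepKernel][StepKernel-class] holding a sparse row-stochastic
#'   matrix over the \eqn{(N+1)\Omega} joint states.
#' @export
stepKernel <- function(model, chain) {
  .checkPair(model, chain, "discrete")
  N <- model@N; om <- model@omega
  mu <- chain@mu
  n1 <- N + 1L
  ii <- jj <- xx <- vector("list", om * om)
  k <- 0L
  for (s in seq_len(om)) {
    tp <- model@tPlus[s, ]; tm <- model@tMinus[s, ]
    stay <- 1 - tp - tm
    from <- (s - 1L) * n1 + seq_len(n1)
    for (sp in seq_len(om)) {
      w <- mu[s, sp]
      if (w == 0) next
      to0 <- (sp - 1L) * n1
      k <- k + 1L
      ii[[k]] <- c(from, from[-n1], from[-1L])
      jj[[k]] <- c(to0 + seq_len(n1),      # stay in i
                   to0 + seq_len(n1)[-n1] + 1L,  # i -> i+1
                   to0 + seq_len(n1)[-1L] - 1L)  # i -> i-1
      xx[[k]] <- c(stay * w, tp[-n1] * w, tm[-1L] * w)
    }
  }
  M <- n1 * om
  kern <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                               x = unlist(xx), dims = c(M, M))
  new("StepKernel", kernel = kern, N = N, omega = om, labels = model@labels)
}

.checkPair <- function(model, chain, convention) {
  if (convention == "discrete" && !is(chain, "EnvChainDiscrete"))
    stop("a discrete-time model requires an EnvChainDiscrete")
  if (convention == "continuous" && !is(chain, "EnvChainContinuous"))
    stop("a continuous-time model requires an EnvChainContinuous")
  if (model@timeConvention != convention)
    stop(sprintf("model uses the %s time convention, expected %s",
                 model@timeConvention, convention))
  if (model@omega != chain@omega)
    stop("model and chain disagree on the number of environments")
  invisible(TRUE)
}

# Interior backward operator A and the solve A x = b for the discrete model.
# Unknowns are x[(i, s)] over interior i = 1..N-1, s = 1..Omega, ordered
# environment-major: idx = (s-1)*(N-1) + i.
.discreteInteriorOperator <- function(model, chain) {
  N <- model@N; om <- model@omega
  mu <- chain@mu
  nI <- N - 1L
  ii <- jj <- xx <- list()
  k <- 0L
  idx <- function(i, s) (s - 1L) * nI + i
  for (s in seq_len(om)) {
    tp <- model@tPlus[s, ]; tm <- model@tMinus[s, ]
    for (sp in seq_len(om)) {
      w <- mu[s, sp]
      if (w == 0) next
      i <- seq_len(nI)
      # stay term
      k <- k + 1L
      ii[[k]] <- idx(i, s); jj[[k]] <- idx(i, sp)
      xx[[k]] <- -w * (1 - tp[i + 1L] - tm[i + 1L])
      # up term (target interior only: i+1 <= N-1)
      iu <- seq_len(nI - 1L)
      if (length(iu)) {
        k <- k + 1L
        ii[[k]] <- idx(iu, s); jj[[k]] <- idx(iu + 1L, sp)
        xx[[k]] <- -w * tp[iu + 1L]
      }
      # down term (i-1 >= 1)
      if (nI >= 2L) {
        id <- 2:nI
        k <- k + 1L
        ii[[k]] <- idx(id, s); jj[[k]] <- idx(id - 1L, sp)
        xx[[k]] <- -w * tm[id + 1L]
      }
    }
  }
  M <- nI * om
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(M, M)) + Matrix::Diagonal(M)
  A
}

.solveRefine <- function(A, b) {
  x <- as.numeric(Matrix::solve(A, b))
  for (k in 1:2) {
    r <- b - as.numeric(A %*% x)
    if (max(abs(r)) < 1e-13) break
    x <- x + as.numeric(Matrix::solve(A, r))
  }
  list(x = x, residual = max(abs(b - as.numeric(A %*% x))))
}

.interiorToFull <- function(x, N, om, bound0, boundN) {
  m <- matrix(0, N + 1L, om)
  m[1L, ] <- bound0
  m[N + 1L, ] <- boundN
  m[2:N, ] <- matrix(x, N - 1L, om)
  m
}

#' Fixation probabilities in the discrete-time model
#'
#' Solves the first-step balance system
#' \deqn{\phi_{i,\sigma} = \sum_{\sigma'} \mu_{\sigma\to\sigma'}
#' \left[T^+_{i,\sigma}\phi_{i+1,\sigma'} + T^-_{i,\sigma}\phi_{i-1,\sigma'}
#' + (1 - T^+_{i,\sigma} - T^-_{i,\sigma})\,\phi_{i,\sigma'}\right]}
#' with \eqn{\phi_{0,\sigma} = 0}, \eqn{\phi_{N,\sigma} = 1}, as a sparse
#' linear solve over the interior joint states.
#'
#' @inheritParams stepKernel
#' @return List with `phi` (\eqn{(N+1)\times\Omega} matrix) and `residual`.
#' @export
fixationProbabilities <- function(model, chain) {
  .checkPair(model, chain, "discrete")
  if (!model@absorbing) stop("fixation requires an absorbing model (u = 0)")
  N <- model@N; om <- model@omega
  A <- .discreteInteriorOperator(model, chain)
  b <- numeric((N - 1L) * om)
  for (s in seq_len(om)) b[(s - 1L) * (N - 1L) + (N - 1L)] <- model@tPlus[s, N]
  sol <- .solveRefine(A, b)
  phi <- .interiorToFull(sol$x, N, om, 0, 1)
  colnames(phi) <- model@labels
  rownames(phi) <- 0:N
  list(phi = phi, residual = sol$residual)
}

#' Mean unconditional fixation times (discrete time)
#'
#' Solves \eqn{t_{i,\sigma} = 1 + \sum_{\sigma'} \mu_{\sigma\to\sigma'}
#' [T^+ t_{i+1,\sigma'} + T^- t_{i-1,\sigma'} + (1-T^+-T^-) t_{i,\sigma'}]}
#' with zero boundaries. Times are in elementary steps; one generation is
#' \eqn{N} steps.
#'
#' @inheritParams stepKernel
#' @return List with `tUncond` and `residual`.
#' @export
unconditionalTimes <- function(model, chain) {
  .checkPair(model, chain, "discrete")
  if (!model@absorbing) stop("fixation times require an absorbing model (u = 0)")
  N <- model@N; om <- model@omega
  A <- .discreteInteriorOperator(model, chain)
  b <- rep(1, (N - 1L) * om)
  sol <- .solveRefine(A, b)
  tU <- .interiorToFull(sol$x, N, om, 0, 0)
  colnames(tU) <- model@labels
  rownames(tU) <- 0:N
  list(tUncond = tU, residual = sol$residual)
}

#' Mean conditional fixation times (discrete time)
#'
#' Works with \eqn{\theta_{i,\sigma} = \phi_{i,\sigma}\tau^A_{i,\sigma}},
#' which obeys the same backward operator with inhomogeneity
#' \eqn{\phi_{i,\sigma}} and zero boundaries; \eqn{\tau^A = \theta/\phi}
#' wherever \eqn{\phi > 0}, with an `NA` marker at \eqn{i = 0}.
#'
#' @inheritParams stepKernel
#' @param phi optional precomputed fixation probability matrix.
#' @return List with `tCond`, `theta` and `residual`.
#' @export
conditionalTimes <- function(model, chain, phi = NULL) {
  .checkPair(model, chain, "discrete")
  if (!model@absorbing) stop("fixation times require an absorbing model (u = 0)")
  N <- model@N; om <- model@omega
  if (is.null(phi)) phi <- fixationProbabilities(model, chain)$phi
  if (any(phi[2:N, ] <= 0))
    stop("phi vanishes at an interior state; interior positivity violated")
  A <- .discreteInteriorOperator(model, chain)
  b <- as.vector(phi[2:N, ])
  sol <- .solveRefine(A, b)
  theta <- .interiorToFull(sol$x, N, om, 0, 0)
  tau <- theta / phi
  tau[1L, ] <- NA_real_  # fixation cannot occur from i = 0
  colnames(tau) <- model@labels
  rownames(tau) <- 0:N
  list(tCond = tau, theta = theta, residual = sol$residual)
}

#' Solve for fixation probabilities and mean times
#'
#' One-call solver returning a [FixationSolution][FixationSolution-class].
#' Dispatches on the chain: a discrete chain solves the per-step balance
#' equations (`method = "direct"`, sparse linear solves; or
#' `method = "recursion"`, the forward recursion in the increments of
#' \eqn{\mu\phi}, which requires \eqn{\mu} to be invertible and is retained
#' as an independent cross-check), a continuous chain solves the stationary
#' backward master equations with separate switching and birth-death events.
#'
#' @param model a [BirthDeathModel][BirthDeathModel-class] (absorbing).
#' @param chain an [EnvChain][EnvChain-class] matching the model's time
#'   convention.
#' @param method `"direct"` (default) or `"recursion"` (discrete only).
#' @return A [FixationSolution][FixationSolution-class].
#' @examples
#' game <- switchingGame(N = 20, b = 0.5, c = 0.9, beta = 0.5)
#' sol <- solveFixation(moranModel(game), twoEnvChain(0.01, 0.01))
#' fixationProb(sol)[2, ]   # single mutant, both starting environments
#' @rdname solveFixation
#' @export
setMethod("solveFixation", signature("BirthDeathModel", "EnvChainDiscrete"),
  function(model, chain, method = "direct") {
    method <- match.arg(method, c("direct", "recursion"))
    if (method == "recursion") return(.recursionSolver(model, chain))
    f <- fixationProbabilities(model, chain)
    tu <- unconditionalTimes(model, chain)
    tc <- conditionalTimes(model, chain, phi = f$phi)
    new("FixationSolution", phi = f$phi, tUncond = tu$tUncond,
        tCond = tc$tCond, N = model@N, labels = model@labels,
        timeConvention = "discrete", method = "direct",
        diagnostics = list(residualPhi = f$residual,
                           residualT = tu$residual,
                           residualTheta = tc$residual))
  })

# ---- recursion path ---------------------------------------------------------
# Write psi_i = mu phi_i (vector over environments).  The balance equation
# becomes, componentwise,
#   (mu^{-1} psi_i)_s = psi_{i,s} + T+_{i,s} (psi_{i+1,s} - psi_{i,s})
#                               - T-_{i,s} (psi_{i,s} - psi_{i-1,s}),
# so with upsilon_i = psi_i - psi_{i-1} (psi_0 = 0):
#   T+_{i,s} upsilon_{i+1,s} = T-_{i,s} upsilon_{i,s}
#                              + ((mu^{-1} - I) sum_{k<=i} upsilon_k)_s.
# upsilon_i depends linearly on upsilon_1; the boundary psi_N = 1 closes the
# system.  The time and conditional-time systems are the same recursion with
# inhomogeneities -1 and -phi_{i,s} and boundary sum zero.
.recursionCore <- function(model, chain, inhom, boundarySum) {
  N <- model@N; om <- model@omega
  muInv <- invertChain(chain)
  K <- muInv - diag(om)
  A <- vector("list", N)       # upsilon_i = A_i v1 + c_i
  cc <- vector("list", N)
  A[[1L]] <- diag(om)
  cc[[1L]] <- numeric(om)
  S <- A[[1L]]                  # running sum of A_k
  Sc <- cc[[1L]]
  for (i in seq_len(N - 1L)) {
    tp <- model@tPlus[, i + 1L]
    tm <- model@tMinus[, i + 1L]
    KA <- K %*% S
    Kc <- as.numeric(K %*% Sc)
    Anew <- (tm * A[[i]] + KA) / tp       # row scaling by 1/T+
    cnew <- (tm * cc[[i]] + Kc + inhom[i, ]) / tp
    A[[i + 1L]] <- Anew
    cc[[i + 1L]] <- cnew
    S <- S + Anew
    Sc <- Sc + cnew
  }
  # boundary: sum_i upsilon_i = boundarySum  =>  S v1 = boundarySum - Sc
  if (!all(is.finite(S)) || (om > 1L && kappa(S, exact = TRUE) > 1e12))
    stop("recursion closure is numerically rank-deficient (the forward ",
         "recursion amplifies its dominant mode exponentially at this N ",
         "and switching strength); use the direct solver")
  v1 <- solve(S, boundarySum - Sc)
  psi <- matrix(0, N + 1L, om)
  acc <- numeric(om)
  for (i in seq_len(N)) {
    acc <- acc + as.numeric(A[[i]] %*% v1) + cc[[i]]
    psi[i + 1L, ] <- acc
  }
  # recover the physical quantity: x_i = mu^{-1} psi_i
  x <- psi %*% base::t(muInv)
  x
}

.recursionSolver <- function(model, chain) {
  if (!model@absorbing) stop("fixation requires an absorbing model (u = 0)")
  N <- model@N; om <- model@omega
  zero <- matrix(0, N - 1L, om)
  phi <- .recursionCore(model, chain, inhom = zero, boundarySum = rep(1, om))
  phi[1L, ] <- 0; phi[N + 1L, ] <- 1
  tU <- .recursionCore(model, chain, inhom = matrix(-1, N - 1L, om),
                       boundarySum = rep(0, om))
  tU[1L, ] <- 0; tU[N + 1L, ] <- 0
  theta <- .recursionCore(model, chain, inhom = -phi[2:N, , drop = FALSE],
                          boundarySum = rep(0, om))
  theta[1L, ] <- 0; theta[N + 1L, ] <- 0
  tau <- theta / phi
  tau[1L, ] <- NA_real_
  dimnames(phi) <- dimnames(tU) <- dimnames(tau) <-
    list(0:N, model@labels)
  new("FixationSolution", phi = phi, tUncond = tU, tCond = tau,
      N = model@N, labels = model@labels, timeConvention = "discrete",
      method = "recursion", diagnostics = list())
}

#' Extract results from a fixation solution
#'
#' @param sol a [FixationSolution][FixationSolution-class].
#' @param units `"steps"` (elementary events; model time for continuous
#'   solutions) or `"generations"` (\eqn{N} steps).
#' @param conditional if `TRUE` return the mean times conditioned on
#'   fixation, otherwise the unconditional absorption times.
#' @return `fixationProb`: \eqn{(N+1)\times\Omega} matrix of
#'   \eqn{\phi_{i,\sigma}}; `fixationTimes`: matrix of mean times.
#' @export
fixationProb <- function(sol) sol@phi

#' @rdname fixationProb
#' @export
fixationTimes <- function(sol, conditional = FALSE, units = "steps") {
  units <- match.arg(units, c("steps", "generations"))
  m <- if (conditional) sol@tCond else sol@tUncond
  if (units == "generations") m <- m / sol@N
  m
}

setMethod("show", "FixationSolution", function(object) {
  cat(sprintf("Fixation solution (%s time, %s solver): N = %d, environments: %s\n",
              object@timeConvention, object@method, object@N,
              paste(object@labels, collapse = ", ")))
  cat("phi for a single mutant (i = 1):\n")
  print(object@phi[2L, ])
  if (length(object@diagnostics))
    cat(sprintf("max solver residual: %.3g\n",
                max(unlist(object@diagnostics))))
})
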
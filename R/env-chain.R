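#' Construct and validate a discrete-time environment chain
#'
#' @param mu square \eqn{\Omega\times\Omega} row-stochastic matrix of per-step
#'   switching probabilities \eqn{\mu_{\sigma\to\sigma'}}.
#' @param labels optional character state labels; defaults to `"+1","-1"` for
#'   \eqn{\Omega = 2} and `"e1","e2",...` otherwise.
#' @return An [EnvChainDiscrete][EnvChain-class] object.
#' @examples
#' envChainDiscrete(matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE))
#' @export
envChainDiscrete <- function(mu, labels = NULL) {
  mu <- as.matrix(mu)
  if (nrow(mu) != ncol(mu)) stop("mu must be a square matrix")
  om <- nrow(mu)
  labels <- labels %||% .defaultLabels(om)
  new("EnvChainDiscrete", omega = as.integer(om), labels = labels,
      mu = unname(mu))
}

#' Construct a continuous-time environment chain from switching rates
#'
#' @param rates \eqn{\Omega\times\Omega} matrix of non-negative switching
#'   rates \eqn{m_{\sigma\to\sigma'}}; the diagonal is ignored (the generator
#'   diagonal \eqn{-\sum_{\sigma'\ne\sigma} m_{\sigma\to\sigma'}} is implied).
#' @inheritParams envChainDiscrete
#' @return An [EnvChainContinuous][EnvChain-class] object.
#' @export
envChainContinuous <- function(rates, labels = NULL) {
  rates <- as.matrix(rates)
  if (nrow(rates) != ncol(rates)) stop("rates must be a square matrix")
  diag(rates) <- 0
  om <- nrow(rates)
  labels <- labels %||% .defaultLabels(om)
  new("EnvChainContinuous", omega = as.integer(om), labels = labels,
      rates = unname(rates))
}

#' Two-state telegraph environment chain
#'
#' Builds the canonical two-environment chain with states `+1` (first) and
#' `-1` (second): `pPlus` is the per-step probability of leaving the `+1`
#' state and `pMinus` of leaving the `-1` state.
#'
#' @param pPlus,pMinus switching probabilities in \eqn{[0,1]}.
#' @return An [EnvChainDiscrete][EnvChain-class] with
#'   \eqn{\mu = \begin{pmatrix}1-p_+ & p_+\\ p_- & 1-p_-\end{pmatrix}}.
#' @examples
#' twoEnvChain(1e-3, 1e-4)
#' @export
twoEnvChain <- function(pPlus, pMinus) {
  if (pPlus < 0 || pPlus > 1 || pMinus < 0 || pMinus > 1)
    stop("switching probabilities must lie in [0, 1]")
  envChainDiscrete(matrix(c(1 - pPlus, pPlus, pMinus, 1 - pMinus),
                          2, 2, byrow = TRUE),
                   labels = c("+1", "-1"))
}

.defaultLabels <- function(om) {
  if (om == 2L) c("+1", "-1") else paste0("e", seq_len(om))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Map a user-supplied environment identifier (label string, +/-1 numeric for
# two-state chains, or integer index) to a row index.
.envIndex <- function(sigma, labels) {
  om <- length(labels)
  if (is.character(sigma)) {
    k <- match(sigma, labels)
    if (is.na(k)) stop(sprintf("unknown environment label '%s'", sigma))
    return(k)
  }
  if (identical(labels, c("+1", "-1")) && sigma %in% c(1, -1))
    return(if (sigma == 1) 1L else 2L)
  k <- as.integer(sigma)
  if (k < 1L || k > om) stop("environment index out of range")
  k
}

#' Accessors for environment chains
#'
#' @param chain an [EnvChain][EnvChain-class] object.
#' @return `envSwitchMatrix` returns the discrete switching matrix
#'   \eqn{\mu}; `switchRates` the continuous rate matrix; `envLabels` the
#'   state labels; `nEnvironments` \eqn{\Omega}.
#' @name chain-accessors
#' @export
envSwitchMatrix <- function(chain) {
  stopifnot(is(chain, "EnvChainDiscrete"))
  structure(chain@mu, dimnames = list(chain@labels, chain@labels))
}

#' @rdname chain-accessors
#' @export
switchRates <- function(chain) {
  stopifnot(is(chain, "EnvChainContinuous"))
  structure(chain@rates, dimnames = list(chain@labels, chain@labels))
}

#' @rdname chain-accessors
#' @export
envLabels <- function(chain) chain@labels

#' @rdname chain-accessors
#' @export
nEnvironments <- function(chain) chain@omega

#' Invert the switching matrix of a discrete chain
#'
#' The recursion-based fixation solver needs \eqn{\mu^{-1}}. Near-singular
#' matrices (relative condition number above `1e12`, e.g. the two-environment
#' case \eqn{p_+ + p_- = 1} where the determinant \eqn{\Delta} vanishes) are
#' rejected with a pointer to the direct solver, which does not require
#' invertibility.
#'
#' @param chain an [EnvChainDiscrete][EnvChain-class].
#' @return The \eqn{\Omega\times\Omega} inverse of \eqn{\mu}.
#' @export
setGeneric("invertChain", function(chain) standardGeneric("invertChain"))

#' @rdname invertChain
#' @export
setMethod("invertChain", "EnvChainDiscrete", function(chain) {
  mu <- chain@mu
  if (kappa(mu, exact = TRUE) > 1e12)
    stop("switching matrix is singular (or near-singular); ",
         "the recursion solver cannot be used - use the direct solver ",
         "(solveFixation(..., method = 'direct'))")
  solve(mu)
})

# strong connectivity of the directed graph with edges where w > 0
.isIrreducible <- function(w) {
  om <- nrow(w)
  if (om == 1L) return(TRUE)
  adj <- (w > 0) | diag(om) > 0
  reach <- adj
  for (k in seq_len(om)) reach <- ((reach %*% adj) > 0) | reach
  all(reach) # every state reaches every other (and is reached: reach is full)
}

.closedSubset <- function(w) {
  # smallest closed set of environment states (for error messages)
  om <- nrow(w)
  adj <- (w > 0) | diag(om) > 0
  reach <- adj
  for (k in seq_len(om)) reach <- ((reach %*% adj) > 0) | reach
  sizes <- rowSums(reach)
  which(reach[which.min(sizes), ] > 0)
}

#' Stationary occupancy of the environment chain
#'
#' Fraction of time asymptotically spent in each environmental state: the
#' left eigenvector of \eqn{\mu} at eigenvalue 1 (discrete) or the null
#' vector of the rate generator (continuous), normalized to sum 1. For the
#' two-state telegraph chain this is
#' \eqn{\rho_{\sigma} = p_{-\sigma}/(p_+ + p_-)}.
#'
#' @param chain an [EnvChain][EnvChain-class]; must be irreducible.
#' @return Named non-negative numeric vector summing to 1.
#' @examples
#' stationaryOccupancy(twoEnvChain(1e-3, 1e-4))  # (1/11, 10/11)
#' @export
setGeneric("stationaryOccupancy",
           function(chain) standardGeneric("stationaryOccupancy"))

#' @rdname stationaryOccupancy
#' @export
setMethod("stationaryOccupancy", "EnvChainDiscrete", function(chain) {
  mu <- chain@mu
  om <- chain@omega
  if (om == 1L) return(setNames(1, chain@labels))
  off <- mu; diag(off) <- 0
  if (!.isIrreducible(off))
    stop("environment chain is reducible; closed subset of states: {",
         paste(chain@labels[.closedSubset(off)], collapse = ", "), "}")
  .stationaryLeft(mu, chain@labels)
})

#' @rdname stationaryOccupancy
#' @export
setMethod("stationaryOccupancy", "EnvChainContinuous", function(chain) {
  om <- chain@omega
  if (om == 1L) return(setNames(1, chain@labels))
  m <- chain@rates
  if (!.isIrreducible(m))
    stop("environment chain is reducible; closed subset of states: {",
         paste(chain@labels[.closedSubset(m)], collapse = ", "), "}")
  gen <- m
  diag(gen) <- 0
  diag(gen) <- -rowSums(gen)
  # rho G = 0 with sum(rho) = 1: replace last column equation
  A <- base::t(gen)
  A[om, ] <- 1
  b <- c(rep(0, om - 1L), 1)
  rho <- solve(A, b)
  setNames(pmax(rho, 0) / sum(pmax(rho, 0)), chain@labels)
})

.stationaryLeft <- function(mu, labels) {
  om <- nrow(mu)
  A <- base::t(mu) - diag(om)
  A[om, ] <- 1
  b <- c(rep(0, om - 1L), 1)
  rho <- solve(A, b)
  rho <- rho + solve(A, b - A %*% rho)  # one refinement pass
  setNames(as.numeric(pmax(rho, 0) / sum(pmax(rho, 0))), labels)
}

setMethod("show", "EnvChainDiscrete", function(object) {
  cat(sprintf("Discrete-time environment chain (%d states: %s)\n",
              object@omega, paste(object@labels, collapse = ", ")))
  print(envSwitchMatrix(object))
})

setMethod("show", "EnvChainContinuous", function(object) {
  cat(sprintf("Continuous-time environment chain (%d states: %s)\n",
              object@omega, paste(object@labels, collapse = ", ")))
  print(switchRates(object))
})
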
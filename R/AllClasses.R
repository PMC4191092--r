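#' @import methods
#' @importFrom stats rbinom sd setNames
#' @importFrom Matrix sparseMatrix Diagonal t solve
NULL

.TOL_STOCHASTIC <- 1e-12

#' Environment switching chains
#'
#' `EnvChain` is the virtual parent of the two representations of the
#' environmental dynamics: a discrete-time Markov chain over the \eqn{\Omega}
#' environmental states (slot `mu`, a row-stochastic matrix of per-step
#' switching probabilities \eqn{\mu_{\sigma\to\sigma'}}) or a continuous-time
#' chain (slot `rates`, non-negative off-diagonal switching rates
#' \eqn{m_{\sigma\to\sigma'}}; the generator diagonal
#' \eqn{-\sum_{\sigma'\neq\sigma} m_{\sigma\to\sigma'}} is implied).
#'
#' The environment evolves independently of the population state. For the
#' canonical two-environment case the states are labelled `"+1"` and `"-1"`,
#' in that order, so that the off-diagonal switching probabilities are
#' \eqn{p_+} (first row) and \eqn{p_-} (second row).
#'
#' @slot omega integer, number of environmental states \eqn{\Omega \ge 1}.
#' @slot labels character vector of state labels, length `omega`.
#' @slot mu (`EnvChainDiscrete`) \eqn{\Omega\times\Omega} row-stochastic
#'   matrix of per-step switching probabilities.
#' @slot rates (`EnvChainContinuous`) \eqn{\Omega\times\Omega} matrix of
#'   switching rates, diagonal ignored (treated as zero).
#'
#' @seealso [envChainDiscrete()], [twoEnvChain()], [envChainContinuous()],
#'   [stationaryOccupancy()], [invertChain()]
#' @name EnvChain-class
#' @aliases EnvChain EnvChainDiscrete-class EnvChainDiscrete
#'   EnvChainContinuous-class EnvChainContinuous
#' @exportClass EnvChain EnvChainDiscrete EnvChainContinuous
setClass("EnvChain", representation("VIRTUAL",
  omega = "integer",
  labels = "character"
))

setClass("EnvChainDiscrete", contains = "EnvChain",
  representation(mu = "matrix"),
  validity = function(object) {
    mu <- object@mu
    om <- object@omega
    if (nrow(mu) != om || ncol(mu) != om)
      return(sprintf("mu must be %d x %d", om, om))
    if (om < 1L) return("omega must be >= 1")
    if (length(object@labels) != om) return("labels length must equal omega")
    if (any(mu < 0) || any(mu > 1)) {
      bad <- which(mu < 0 | mu > 1, arr.ind = TRUE)[1, ]
      return(sprintf("entry (%d,%d) of mu is outside [0,1]", bad[1], bad[2]))
    }
    rs <- rowSums(mu)
    bad <- which(abs(rs - 1) > .TOL_STOCHASTIC)
    if (length(bad))
      return(sprintf("row %d of mu sums to %.12g, not 1 (not a stochastic matrix)",
                     bad[1], rs[bad[1]]))
    TRUE
  })

setClass("EnvChainContinuous", contains = "EnvChain",
  representation(rates = "matrix"),
  validity = function(object) {
    m <- object@rates
    om <- object@omega
    if (nrow(m) != om || ncol(m) != om)
      return(sprintf("rates must be %d x %d", om, om))
    if (length(object@labels) != om) return("labels length must equal omega")
    off <- m; diag(off) <- 0
    if (any(off < 0)) return("off-diagonal switching rates must be non-negative")
    if (om > 1L && all(off == 0))
      return("all switching rates are zero; use a single-environment model")
    TRUE
  })

#' Birth-death transition tables per environment
#'
#' Holds the one-step birth and death probabilities (discrete time) or rates
#' (continuous time) \eqn{T^\pm_{i,\sigma}} of a one-step process on
#' \eqn{i = 0,\dots,N}, one row per environmental state. Without mutation the
#' monomorphic states \eqn{i = 0} and \eqn{i = N} are absorbing (boundary
#' entries zero, interior entries strictly positive); with mutation the
#' boundaries leak back into the interior.
#'
#' @slot N integer population size.
#' @slot omega integer number of environments.
#' @slot labels character environment labels.
#' @slot tPlus,tMinus \eqn{\Omega\times(N+1)} matrices of \eqn{T^+_{i,\sigma}}
#'   and \eqn{T^-_{i,\sigma}}; column `j` is state `i = j - 1`.
#' @slot absorbing logical, whether `i = 0` and `i = N` are absorbing.
#' @slot timeConvention `"discrete"` (entries are probabilities with
#'   \eqn{T^+ + T^- \le 1}) or `"continuous"` (entries are rates).
#'
#' @seealso [birthDeathModel()], [moranModel()], [asContinuous()]
#' @name BirthDeathModel-class
#' @aliases BirthDeathModel
#' @exportClass BirthDeathModel
setClass("BirthDeathModel",
  representation(
    N = "integer",
    omega = "integer",
    labels = "character",
    tPlus = "matrix",
    tMinus = "matrix",
    absorbing = "logical",
    timeConvention = "character"
  ),
  validity = function(object) {
    N <- object@N; om <- object@omega
    if (N < 2L) return("N must be >= 2")
    for (nm in c("tPlus", "tMinus")) {
      m <- slot(object, nm)
      if (nrow(m) != om || ncol(m) != N + 1L)
        return(sprintf("%s must be %d x %d", nm, om, N + 1L))
      if (any(m < 0)) return(sprintf("%s has negative entries", nm))
    }
    if (!object@timeConvention %in% c("discrete", "continuous"))
      return("timeConvention must be 'discrete' or 'continuous'")
    if (object@timeConvention == "discrete" &&
        any(object@tPlus + object@tMinus > 1 + 1e-12))
      return("tPlus + tMinus exceeds 1 for some (i, sigma)")
    if (object@absorbing) {
      if (any(object@tPlus[, c(1L, N + 1L)] != 0) ||
          any(object@tMinus[, c(1L, N + 1L)] != 0))
        return("absorbing model must have zero boundary transition entries")
      interior <- 2:N
      if (any(object@tPlus[, interior, drop = FALSE] <= 0) ||
          any(object@tMinus[, interior, drop = FALSE] <= 0))
        return("absorbing model requires strictly positive interior T+ and T-")
    }
    TRUE
  })

#' Specification of a 2x2 evolutionary game per environment
#'
#' Per-environment payoff matrix entries \eqn{a_\sigma, b_\sigma, c_\sigma,
#' d_\sigma}, selection intensity \eqn{\beta}, mutation probability \eqn{u}
#' per birth event, and population size \eqn{N}. The switching-game
#' parametrization (slot `bc`) fixes \eqn{a_\sigma = d_\sigma = 1},
#' \eqn{b_\sigma = 1 + \sigma b}, \eqn{c_\sigma = 1 + \sigma c} over
#' \eqn{\sigma = \pm 1}: a coexistence game in the `+1` environment and a
#' coordination game in the `-1` environment when \eqn{b, c > 0}.
#'
#' @slot payoffs \eqn{\Omega\times 4} matrix with columns `a`, `b`, `c`, `d`.
#' @slot beta selection intensity \eqn{\beta \ge 0} of the exponential
#'   payoff-to-fitness mapping.
#' @slot u mutation probability per birth event, in \eqn{[0, 1)}.
#' @slot N integer population size.
#' @slot labels character environment labels.
#' @slot bc numeric length-2 `(b, c)` amplitudes when the switching-game
#'   parametrization is used, otherwise `NA`.
#'
#' @seealso [gameSpec()], [switchingGame()], [moranModel()]
#' @name GameSpec-class
#' @aliases GameSpec
#' @exportClass GameSpec
setClass("GameSpec",
  representation(
    payoffs = "matrix",
    beta = "numeric",
    u = "numeric",
    N = "integer",
    labels = "character",
    bc = "numeric"
  ),
  validity = function(object) {
    if (ncol(object@payoffs) != 4L) return("payoffs must have 4 columns (a,b,c,d)")
    if (nrow(object@payoffs) != length(object@labels))
      return("payoffs rows must match labels")
    if (object@beta < 0) return("beta must be >= 0")
    if (object@u < 0 || object@u >= 1) return("u must be in [0, 1)")
    if (object@N < 2L) return("N must be >= 2")
    TRUE
  })

#' Joint one-step kernel over population and environment
#'
#' Sparse row-stochastic matrix \eqn{R_{(i,\sigma)\to(j,\sigma')}} over the
#' \eqn{(N+1)\Omega} joint states: within one discrete step the population
#' moves using the step-start environment's birth-death probabilities and the
#' environment then switches with \eqn{\mu_{\sigma\to\sigma'}}. Rows/columns
#' are ordered in environment-major blocks of length \eqn{N+1}.
#'
#' @slot kernel sparse `dgCMatrix`.
#' @slot N,omega dimensions.
#' @slot labels environment labels.
#' @seealso [stepKernel()]
#' @name StepKernel-class
#' @aliases StepKernel
#' @exportClass StepKernel
setClass("StepKernel",
  representation(kernel = "ANY", N = "integer", omega = "integer",
                 labels = "character"),
  validity = function(object) {
    M <- (object@N + 1L) * object@omega
    if (nrow(object@kernel) != M || ncol(object@kernel) != M)
      return("kernel dimension mismatch")
    rs <- Matrix::rowSums(object@kernel)
    if (any(abs(rs - 1) > 1e-10)) return("kernel rows must sum to 1")
    TRUE
  })

#' Fixation probabilities and mean fixation times
#'
#' Solution container for the backward (first-step) systems: fixation
#' probabilities \eqn{\phi_{i,\sigma}}, mean unconditional fixation times
#' \eqn{t_{i,\sigma}}, and mean fixation times conditioned on absorption in
#' the all-mutant state \eqn{\tau^A_{i,\sigma}}. All arrays are
#' \eqn{(N+1)\times\Omega} with rows indexed by \eqn{i = 0,\dots,N}.
#' \eqn{\tau^A_{0,\sigma}} is `NA` (fixation cannot occur from extinction).
#' Times are in elementary steps (discrete) or model time (continuous);
#' [fixationTimes()] can report generations (\eqn{N} steps).
#'
#' @slot phi,tUncond,tCond numeric \eqn{(N+1)\times\Omega} matrices.
#' @slot N population size; @slot labels environment labels.
#' @slot timeConvention `"discrete"` or `"continuous"`.
#' @slot method solver used (`"direct"` or `"recursion"`).
#' @slot diagnostics list of solver residual norms.
#' @seealso [solveFixation()], [fixationProb()], [fixationTimes()]
#' @name FixationSolution-class
#' @aliases FixationSolution
#' @exportClass FixationSolution
setClass("FixationSolution",
  representation(
    phi = "matrix", tUncond = "matrix", tCond = "matrix",
    N = "integer", labels = "character",
    timeConvention = "character", method = "character",
    diagnostics = "list"
  ),
  validity = function(object) {
    N <- object@N
    if (any(object@phi < -1e-9) || any(object@phi > 1 + 1e-9))
      return("phi outside [0,1]")
    if (max(abs(object@phi[1L, ])) > 1e-9) return("phi at i=0 must be 0")
    if (max(abs(object@phi[N + 1L, ] - 1)) > 1e-9) return("phi at i=N must be 1")
    if (any(abs(object@tUncond[c(1L, N + 1L), ]) > 1e-9))
      return("unconditional times at boundaries must be 0")
    TRUE
  })

#' Effective one-environment birth-death model (fast switching)
#'
#' Occupancy-weighted averages \eqn{T^\pm_{i,\mathrm{eff}}} of the
#' per-environment transition probabilities, and the ratios
#' \eqn{\gamma_i = T^-_{i,\mathrm{eff}} / T^+_{i,\mathrm{eff}}} used by the
#' single-environment closed-form fixation formulas.
#'
#' @slot N population size.
#' @slot tPlusEff,tMinusEff numeric length \eqn{N+1}.
#' @slot gamma numeric length \eqn{N-1} (interior states \eqn{1..N-1}).
#' @slot absorbing logical.
#' @seealso [effectiveModel()], [closedFormFixation()], [closedFormTimes()]
#' @name EffectiveModel-class
#' @aliases EffectiveModel
#' @exportClass EffectiveModel
setClass("EffectiveModel",
  representation(N = "integer", tPlusEff = "numeric", tMinusEff = "numeric",
                 gamma = "numeric", absorbing = "logical"),
  validity = function(object) {
    N <- object@N
    if (length(object@tPlusEff) != N + 1L || length(object@tMinusEff) != N + 1L)
      return("effective tables must have length N+1")
    if (length(object@gamma) != N - 1L) return("gamma must have length N-1")
    if (any(object@gamma <= 0)) return("interior gamma must be positive")
    TRUE
  })

#' Mutation-selection stationary distributions
#'
#' Joint stationary probabilities \eqn{\rho_{i,\sigma}} of the population-
#' environment chain with mutation, the marginal \eqn{\rho_i}, the per-
#' environment product-form distributions \eqn{\rho_i^{(\sigma)}}, the
#' slow-switching weighted average \eqn{\bar\rho_i}, and the fast-switching
#' effective approximation \eqn{\rho_{i,\mathrm{eff}}}.
#'
#' @slot rhoJoint \eqn{(N+1)\times\Omega}; @slot rhoMarginal length \eqn{N+1}.
#' @slot rhoSingle \eqn{(N+1)\times\Omega}; @slot rhoAvg,rhoEff length \eqn{N+1}.
#' @slot envWeights stationary environment occupancies \eqn{\rho_\sigma}.
#' @slot diagnostics list (eigen residuals).
#' @seealso [stationaryExact()], [stationarySingleEnv()],
#'   [stationaryAveraged()], [stationaryEffective()]
#' @name StationarySolution-class
#' @aliases StationarySolution
#' @exportClass StationarySolution
setClass("StationarySolution",
  representation(
    rhoJoint = "matrix", rhoMarginal = "numeric", rhoSingle = "matrix",
    rhoAvg = "numeric", rhoEff = "numeric", envWeights = "numeric",
    labels = "character", diagnostics = "list"
  ))

#' A simulated trajectory of the joint process
#'
#' @slot time numeric sample times (steps or model time).
#' @slot pop integer mutant counts at the sample times.
#' @slot env integer environment indices (into `labels`).
#' @slot labels environment labels.
#' @slot absorbed logical; @slot absorbState integer final population state
#'   (`NA` if unabsorbed); @slot absorbTime numeric absorption time (`NA` if
#'   unabsorbed).
#' @slot timeConvention `"discrete"` or `"continuous"`.
#' @seealso [simulateTrajectory()]
#' @name Trajectory-class
#' @aliases Trajectory
#' @exportClass Trajectory
setClass("Trajectory",
  representation(time = "numeric", pop = "integer", env = "integer",
                 labels = "character", absorbed = "logical",
                 absorbState = "integer", absorbTime = "numeric",
                 timeConvention = "character"))

#' Ensemble estimates of fixation statistics
#'
#' Monte Carlo estimates: fixation probability \eqn{\hat\phi} with binomial
#' standard error, mean unconditional absorption time, and mean conditional
#' fixation time averaged over fixed runs only, with sample standard errors.
#'
#' @slot phiHat,phiSE,tHat,tSE,tauHat,tauSE numeric scalars.
#' @slot nRuns,nFixed,nUnabsorbed integer counters.
#' @slot timeConvention `"discrete"` or `"continuous"`.
#' @seealso [estimateFixation()]
#' @name EnsembleEstimate-class
#' @aliases EnsembleEstimate
#' @exportClass EnsembleEstimate
setClass("EnsembleEstimate",
  representation(phiHat = "numeric", phiSE = "numeric",
                 tHat = "numeric", tSE = "numeric",
                 tauHat = "numeric", tauSE = "numeric",
                 nRuns = "integer", nFixed = "integer",
                 nUnabsorbed = "integer", timeConvention = "character"))
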
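#' Effective transition probabilities for fast switching
#'
#' When the environment switches much faster than fixation occurs, the
#' population effectively sees occupancy-weighted transition probabilities.
#' For the two-state telegraph environment the asymptotic fraction of time
#' spent in state \eqn{\sigma} is \eqn{p_{-\sigma}/(p_+ + p_-)}, giving
#' \deqn{T^\pm_{i,\mathrm{eff}} = \frac{p_-\, T^\pm_{i,+1} +
#'   p_+\, T^\pm_{i,-1}}{p_+ + p_-}.}
#' Arbitrary-\eqn{\Omega} occupancy weights can be supplied through
#' `weights` with `extension = TRUE` (the same logic applied beyond the
#' two-state case).
#'
#' @param model a two-environment [BirthDeathModel][BirthDeathModel-class]
#'   (rows ordered `+1`, `-1`), unless `weights` is given.
#' @param pPlus,pMinus telegraph switching probabilities with
#'   \eqn{p_+ + p_- > 0}.
#' @param weights optional explicit occupancy weights over the environments
#'   (general \eqn{\Omega}); requires `extension = TRUE`.
#' @param extension set `TRUE` to acknowledge use of the general-\eqn{\Omega}
#'   weighting.
#' @return An [EffectiveModel][EffectiveModel-class].
#' @examples
#' m <- moranModel(switchingGame(N = 50, b = 0.5, c = 0.9, beta = 0.5))
#' effectiveModel(m, pPlus = 0.1, pMinus = 0.1)
#' @export
effectiveModel <- function(model, pPlus = NULL, pMinus = NULL,
                           weights = NULL, extension = FALSE) {
  if (is.null(weights)) {
    if (model@omega != 2L)
      stop("telegraph weighting requires exactly two environments; ",
           "supply `weights` with extension = TRUE for general Omega")
    if (is.null(pPlus) || is.null(pMinus)) stop("supply pPlus and pMinus")
    if (pPlus + pMinus <= 0)
      stop("pPlus + pMinus must be positive (no mixing between environments)")
    weights <- c(pMinus, pPlus) / (pPlus + pMinus)
  } else {
    if (!extension)
      stop("explicit weights are an extension beyond the two-state ",
           "telegraph theory; set extension = TRUE to use them")
    if (length(weights) != model@omega) stop("weights length must equal Omega")
    if (abs(sum(weights) - 1) > 1e-10) stop("weights must sum to 1")
  }
  tpe <- as.numeric(weights %*% model@tPlus)
  tme <- as.numeric(weights %*% model@tMinus)
  N <- model@N
  gam <- tme[2:N] / tpe[2:N]
  new("EffectiveModel", N = N, tPlusEff = tpe, tMinusEff = tme,
      gamma = gam, absorbing = model@absorbing)
}

# log-space cumulative products of gamma: L[k] = sum_{j<=k} log gamma_j,
# k = 0..N-1 with L[0] = 0.  Sums Sum_{k in ks} exp(L[k]) are evaluated with
# a common max shift so that exponential fitness at large N cannot overflow.
.gammaLogCum <- function(gamma) c(0, cumsum(log(gamma)))

.shiftedExp <- function(L) {
  m <- max(L)
  list(w = exp(L - m), shift = m)
}

#' Closed-form fixation probabilities of a one-environment chain
#'
#' The standard absorbing birth-death result evaluated on the effective
#' transition probabilities:
#' \deqn{\phi_i = \frac{1 + \sum_{k=1}^{i-1}\prod_{j=1}^{k}\gamma_j}
#'                     {1 + \sum_{k=1}^{N-1}\prod_{j=1}^{k}\gamma_j},
#'   \qquad \gamma_j = \frac{T^-_{j,\mathrm{eff}}}{T^+_{j,\mathrm{eff}}}.}
#' Products are accumulated in log space, so large \eqn{\gamma} (strong
#' selection, large \eqn{N}) cannot overflow.
#'
#' @param eff an [EffectiveModel][EffectiveModel-class] (absorbing).
#' @return Numeric vector \eqn{\phi_i}, \eqn{i = 0,\dots,N}.
#' @export
closedFormFixation <- function(eff) {
  if (!eff@absorbing) stop("closed-form fixation requires absorbing boundaries")
  N <- eff@N
  if (any(eff@tPlusEff[2:N] <= 0)) stop("zero interior effective T+")
  se <- .shiftedExp(.gammaLogCum(eff@gamma))
  cs <- cumsum(se$w)                  # partial sums of exp(L_0..L_k)
  phi <- c(0, cs) / cs[N]
  names(phi) <- 0:N
  phi
}

#' Closed-form mean fixation times of a one-environment chain
#'
#' Single-environment sums for the mean unconditional and conditional
#' fixation times of a single mutant,
#' \deqn{t_1 = \phi_1 \sum_{k=1}^{N-1}\sum_{l=1}^{k}
#'   \frac{1}{T^+_{l,\mathrm{eff}}}\prod_{m=l+1}^{k}\gamma_m, \qquad
#'   \tau^A_1 = \sum_{k=1}^{N-1}\sum_{l=1}^{k}
#'   \frac{\phi_l}{T^+_{l,\mathrm{eff}}}\prod_{m=l+1}^{k}\gamma_m,}
#' evaluated in log space. Entries for all starting states \eqn{i} are
#' reported; states beyond \eqn{i = 1} are completed through the exactly
#' equivalent first-step linear system of the same effective chain.
#'
#' @param eff an [EffectiveModel][EffectiveModel-class] (absorbing).
#' @return List with vectors `tUncond` and `tCond` over \eqn{i = 0,\dots,N}
#'   (times in steps; divide by \eqn{N} for generations).
#' @export
closedFormTimes <- function(eff) {
  if (!eff@absorbing) stop("closed-form times require absorbing boundaries")
  N <- eff@N
  tp <- eff@tPlusEff
  if (any(tp[2:N] <= 0)) stop("zero interior effective T+")
  phi <- closedFormFixation(eff)
  L <- .gammaLogCum(eff@gamma)        # L[k+1] = sum_{j<=k} log gamma_j
  # prod_{m=l+1}^{k} gamma_m = exp(L[k+1] - L[l+1])
  logInvTp <- -log(tp[2:N])
  t1 <- 0; tau1 <- 0
  for (k in seq_len(N - 1L)) {
    l <- seq_len(k)
    w <- exp(L[k + 1L] - L[l + 1L] + logInvTp[l])
    t1 <- t1 + sum(w)
    tau1 <- tau1 + sum(phi[l + 1L] * w)
  }
  t1 <- phi[2L] * t1
  # full vectors from the equivalent linear system (Omega = 1 direct solve)
  one <- birthDeathModel(matrix(tp, 1), matrix(eff@tMinusEff, 1),
                         absorbing = TRUE, timeConvention = "discrete")
  idChain <- envChainDiscrete(matrix(1, 1, 1), labels = "e1")
  tU <- unconditionalTimes(one, idChain)$tUncond[, 1L]
  tC <- conditionalTimes(one, idChain)$tCond[, 1L]
  # the two routes are algebraically identical; keep the headline sums
  tU[2L] <- unname(t1)
  tC[2L] <- unname(tau1)
  names(tU) <- names(tC) <- 0:N
  list(tUncond = tU, tCond = tC)
}

#' Product-form stationary distribution of an effective chain with mutation
#'
#' @param eff an [EffectiveModel][EffectiveModel-class] built from a model
#'   with mutation (non-absorbing boundaries).
#' @return Numeric stationary distribution over \eqn{i = 0,\dots,N}.
#' @seealso [stationaryEffective()]
#' @export
effectiveStationary <- function(eff) {
  if (eff@absorbing)
    stop("stationary distribution requires mutation (non-absorbing model)")
  .productFormStationary(eff@tPlusEff, eff@tMinusEff)
}

setMethod("show", "EffectiveModel", function(object) {
  cat(sprintf("Effective one-environment birth-death model: N = %d (%s)\n",
              object@N,
              if (object@absorbing) "absorbing" else "with mutation"))
})
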
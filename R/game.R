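#' Specify a 2x2 evolutionary game per environment
#'
#' @param payoffs \eqn{\Omega\times 4} matrix (or anything coercible) with
#'   columns `a`, `b`, `c`, `d`: the payoff to a mutant (type A) meeting a
#'   mutant (`a`), a mutant meeting a wild-type (`b`), a wild-type meeting a
#'   mutant (`c`), and a wild-type meeting a wild-type (`d`).
#' @param beta selection intensity \eqn{\beta \ge 0}; `beta = 0` is neutral.
#' @param u mutation probability per birth event, in \eqn{[0, 1)}.
#' @param N population size (\eqn{\ge 2}).
#' @param labels environment labels (default per [envChainDiscrete()]).
#' @return A [GameSpec][GameSpec-class].
#' @seealso [switchingGame()] for the canonical two-environment
#'   parametrization.
#' @export
gameSpec <- function(payoffs, beta, N, u = 0, labels = NULL) {
  payoffs <- as.matrix(payoffs)
  if (ncol(payoffs) != 4L) stop("payoffs must have 4 columns (a, b, c, d)")
  colnames(payoffs) <- c("a", "b", "c", "d")
  labels <- labels %||% .defaultLabels(nrow(payoffs))
  new("GameSpec", payoffs = payoffs, beta = beta, u = u, N = as.integer(N),
      labels = labels, bc = c(NA_real_, NA_real_))
}

#' The coexistence/coordination switching game
#'
#' Two-environment game with \eqn{a_\sigma = d_\sigma = 1},
#' \eqn{b_\sigma = 1 + \sigma b}, \eqn{c_\sigma = 1 + \sigma c} for
#' \eqn{\sigma = \pm 1}. With \eqn{b, c > 0} the `+1` environment is a
#' coexistence game (selection towards an interior balance point) and the
#' `-1` environment a coordination game (bistable selection away from it);
#' the balance point sits at the same state in both environments.
#'
#' @param N population size.
#' @param b,c positive payoff amplitudes.
#' @param beta selection intensity.
#' @param u mutation probability per birth event.
#' @return A [GameSpec][GameSpec-class] with slots `bc = c(b, c)`.
#' @examples
#' switchingGame(N = 50, b = 0.5, c = 0.9, beta = 0.5)
#' @export
switchingGame <- function(N, b, c, beta, u = 0) {
  payoffs <- rbind(c(1, 1 + b, 1 + c, 1),   # sigma = +1
                   c(1, 1 - b, 1 - c, 1))   # sigma = -1
  colnames(payoffs) <- c("a", "b", "c", "d")
  obj <- new("GameSpec", payoffs = payoffs, beta = beta, u = u,
             N = as.integer(N), labels = c("+1", "-1"), bc = c(b, c))
  obj
}

#' Expected payoffs of the two types
#'
#' Finite-population expected payoffs excluding self-interaction: with `i`
#' mutants among `N` individuals in environment \eqn{\sigma},
#' \deqn{\pi_A(i) = \frac{a_\sigma (i-1) + b_\sigma (N-i)}{N-1}, \qquad
#'       \pi_B(i) = \frac{c_\sigma i + d_\sigma (N-i-1)}{N-1}.}
#' \eqn{\pi_A} is meaningful for \eqn{i \ge 1} and \eqn{\pi_B} for
#' \eqn{i \le N-1}; at the opposite boundaries the formula values are
#' returned but carry zero weight in the update rule.
#'
#' @param i mutant count(s), each in \eqn{0,\dots,N}.
#' @param spec a [GameSpec][GameSpec-class].
#' @param sigma environment label, \eqn{\pm 1}, or index.
#' @return List with numeric components `piA` and `piB` (same length as `i`).
#' @export
expectedPayoffs <- function(i, spec, sigma) {
  s <- .envIndex(sigma, spec@labels)
  N <- spec@N
  if (any(i < 0 | i > N)) stop("i must lie in 0..N")
  p <- spec@payoffs[s, ]
  list(piA = (p["a"] * (i - 1) + p["b"] * (N - i)) / (N - 1),
       piB = (p["c"] * i + p["d"] * (N - i - 1)) / (N - 1))
}

#' Exponential payoff-to-fitness mapping
#'
#' \eqn{f = e^{\beta \pi}}: strictly positive and increasing in payoff, with
#' \eqn{\beta = 0} giving fitness 1 (neutral evolution).
#'
#' @param payoff numeric payoff(s).
#' @param beta selection intensity \eqn{\beta \ge 0}.
#' @return numeric fitness values.
#' @export
payoffFitness <- function(payoff, beta) {
  if (beta < 0) stop("beta must be >= 0")
  exp(beta * payoff)
}

# transition row for one environment; returns list(tPlus, tMinus) over i=0..N
.moranRow <- function(spec, s) {
  N <- spec@N
  i <- 0:N
  p <- spec@payoffs[s, ]
  piA <- (p[["a"]] * (i - 1) + p[["b"]] * (N - i)) / (N - 1)
  piB <- (p[["c"]] * i + p[["d"]] * (N - i - 1)) / (N - 1)
  fA <- payoffFitness(piA, spec@beta)
  fB <- payoffFitness(piB, spec@beta)
  D <- i * fA + (N - i) * fB
  u <- spec@u
  if (u == 0) {
    tp <- (i * fA / D) * (N - i) / N
    tm <- ((N - i) * fB / D) * i / N
    tp[c(1L, N + 1L)] <- 0
    tm[c(1L, N + 1L)] <- 0
  } else {
    tp <- ((N - i) / N) * ((1 - u) * i * fA + u * (N - i) * fB) / D
    tm <- (i / N) * ((1 - u) * (N - i) * fB + u * i * fA) / D
  }
  list(tPlus = tp, tMinus = tm)
}

#' Build the Moran birth-death tables for a game
#'
#' Frequency-dependent Moran process: one individual reproduces with
#' probability proportional to fitness and its offspring replaces a uniformly
#' chosen individual. Without mutation,
#' \deqn{T^+_{i,\sigma} = \frac{i f_A}{i f_A + (N-i) f_B}\,\frac{N-i}{N},
#' \qquad T^-_{i,\sigma} = \frac{(N-i) f_B}{i f_A + (N-i) f_B}\,\frac{i}{N},}
#' with absorbing boundaries. With mutation probability `u` the offspring
#' misreproduces with probability `u`:
#' \deqn{T^+_{i,\sigma} = \frac{N-i}{N}\,
#'   \frac{(1-u)\, i f_A + u\,(N-i) f_B}{i f_A + (N-i) f_B},}
#' and symmetrically for \eqn{T^-}; the boundaries then leak
#' (\eqn{T^+_{0,\sigma} = T^-_{N,\sigma} = u}) and no state is absorbing.
#'
#' @param spec a [GameSpec][GameSpec-class].
#' @return A [BirthDeathModel][BirthDeathModel-class] (discrete convention).
#' @examples
#' moranModel(switchingGame(N = 50, b = 0.5, c = 0.9, beta = 0.5))
#' @export
moranModel <- function(spec) {
  om <- length(spec@labels)
  N <- spec@N
  tp <- matrix(0, om, N + 1L)
  tm <- matrix(0, om, N + 1L)
  for (s in seq_len(om)) {
    row <- .moranRow(spec, s)
    tp[s, ] <- row$tPlus
    tm[s, ] <- row$tMinus
  }
  birthDeathModel(tPlus = tp, tMinus = tm, labels = spec@labels,
                  absorbing = spec@u == 0, timeConvention = "discrete")
}

#' Construct a birth-death model from explicit tables
#'
#' @param tPlus,tMinus \eqn{\Omega\times(N+1)} matrices of birth/death
#'   probabilities (discrete) or rates (continuous); column `j` is state
#'   `i = j - 1`.
#' @param absorbing whether `i = 0` and `i = N` are absorbing.
#' @param timeConvention `"discrete"` or `"continuous"`.
#' @param labels environment labels.
#' @return A [BirthDeathModel][BirthDeathModel-class].
#' @export
birthDeathModel <- function(tPlus, tMinus, absorbing = TRUE,
                            timeConvention = "discrete", labels = NULL) {
  tPlus <- as.matrix(tPlus); tMinus <- as.matrix(tMinus)
  om <- nrow(tPlus)
  N <- ncol(tPlus) - 1L
  labels <- labels %||% .defaultLabels(om)
  new("BirthDeathModel", N = as.integer(N), omega = as.integer(om),
      labels = labels, tPlus = unname(tPlus), tMinus = unname(tMinus),
      absorbing = absorbing, timeConvention = timeConvention)
}

#' Reinterpret discrete per-step probabilities as continuous rates
#'
#' The continuous-time theory takes birth-death rates as free inputs; this
#' helper maps a discrete model's per-step probabilities one-to-one onto
#' rates per unit time.
#'
#' @param model a discrete [BirthDeathModel][BirthDeathModel-class].
#' @param scale positive factor applied to all rates.
#' @return A continuous-convention model.
#' @export
asContinuous <- function(model, scale = 1) {
  stopifnot(model@timeConvention == "discrete", scale > 0)
  birthDeathModel(model@tPlus * scale, model@tMinus * scale,
                  absorbing = model@absorbing, timeConvention = "continuous",
                  labels = model@labels)
}

#' Accessors for birth-death models
#'
#' @param model a [BirthDeathModel][BirthDeathModel-class].
#' @param sigma environment label or index.
#' @return `transitionTable` returns a data frame with columns
#'   `sigma`, `i`, `t_plus`, `t_minus`; `popSize` returns \eqn{N}.
#' @name model-accessors
#' @export
transitionTable <- function(model) {
  om <- model@omega; N <- model@N
  data.frame(
    sigma = rep(model@labels, each = N + 1L),
    i = rep(0:N, om),
    t_plus = as.vector(base::t(model@tPlus)),
    t_minus = as.vector(base::t(model@tMinus))
  )
}

#' @rdname model-accessors
#' @export
popSize <- function(model) model@N

#' Gradient of selection
#'
#' Net expected per-step drift \eqn{T^+_{i,\sigma} - T^-_{i,\sigma}} of the
#' mutant count. For the coexistence game it is positive below the balance
#' point and negative above (selection towards the interior); the
#' coordination game shows the opposite pattern.
#'
#' @param model a [BirthDeathModel][BirthDeathModel-class].
#' @param sigma environment label or index.
#' @return Numeric vector over \eqn{i = 0,\dots,N}.
#' @export
gradientOfSelection <- function(model, sigma) {
  s <- .envIndex(sigma, model@labels)
  setNames(model@tPlus[s, ] - model@tMinus[s, ], 0:model@N)
}

#' Selection-balance point of a game
#'
#' Solves \eqn{\pi_A(i) = \pi_B(i)} for real \eqn{i}: the interior state at
#' which the gradient of selection changes sign. Returns the real root, its
#' nearest integer state (ties at `.5` round towards \eqn{N/2}), and — when
#' the switching-game amplitudes \eqn{(b, c)} are available — the
#' leading-order approximation \eqn{i^*/N \approx b/(b+c)}.
#'
#' @param spec a [GameSpec][GameSpec-class].
#' @param sigma environment label or index.
#' @return List with `iStarReal`, `iStarInt`, `leadingOrderFraction`
#'   (`NA` if the `(b, c)` parametrization is absent).
#' @examples
#' selectionBalancePoint(switchingGame(50, 0.5, 0.9, beta = 0.5), "+1")
#' @export
selectionBalancePoint <- function(spec, sigma) {
  s <- .envIndex(sigma, spec@labels)
  p <- spec@payoffs[s, ]
  N <- spec@N
  denom <- p[["a"]] - p[["b"]] - p[["c"]] + p[["d"]]
  if (denom == 0)
    stop("payoffs give a constant payoff difference; no balance point")
  iStar <- (p[["a"]] - p[["d"]] + N * (p[["d"]] - p[["b"]])) / denom
  if (iStar <= 0 || iStar >= N)
    stop("no interior balance point (dominance game): root at i = ",
         format(iStar))
  # interior sign change required (coexistence or coordination game)
  dPi <- function(i) (p[["a"]] * (i - 1) + p[["b"]] * (N - i) -
                      p[["c"]] * i - p[["d"]] * (N - i - 1)) / (N - 1)
  if (sign(dPi(1)) * sign(dPi(N - 1)) > 0)
    stop("payoff difference does not change sign on the interior ",
         "(dominance game)")
  frac <- iStar - floor(iStar)
  iInt <- if (frac == 0.5) {
    # round towards N/2
    cands <- c(floor(iStar), ceiling(iStar))
    cands[which.min(abs(cands - N / 2))]
  } else round(iStar)
  list(iStarReal = unname(iStar), iStarInt = as.integer(iInt),
       leadingOrderFraction = if (all(is.finite(spec@bc)))
         spec@bc[1] / (spec@bc[1] + spec@bc[2]) else NA_real_)
}

setMethod("show", "GameSpec", function(object) {
  cat(sprintf("2x2 evolutionary game: N = %d, beta = %g, u = %g\n",
              object@N, object@beta, object@u))
  if (all(is.finite(object@bc)))
    cat(sprintf("switching-game amplitudes: b = %g, c = %g\n",
                object@bc[1], object@bc[2]))
  po <- object@payoffs
  rownames(po) <- object@labels
  print(po)
})

setMethod("show", "BirthDeathModel", function(object) {
  cat(sprintf("Birth-death model: N = %d, %d environment(s) [%s], %s time, %s\n",
              object@N, object@omega, paste(object@labels, collapse = ", "),
              object@timeConvention,
              if (object@absorbing) "absorbing boundaries" else "with mutation"))
})
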
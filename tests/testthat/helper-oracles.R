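# Independent dense-chain oracles, built directly from first principles on
# the full joint state space (i = 0..N) x (s = 1..Omega).  These never call
# the package's solvers: hitting probabilities and times come from the
# fundamental matrix of the absorbing joint chain, conditional times from
# the Doob-transformed (conditioned) chain.

oracle_joint_matrix <- function(tp, tm, mu) {
  om <- nrow(tp); N <- ncol(tp) - 1L
  M <- (N + 1L) * om
  P <- matrix(0, M, M)
  idx <- function(i, s) (s - 1L) * (N + 1L) + i + 1L
  for (s in seq_len(om)) for (i in 0:N) for (sp in seq_len(om)) {
    up <- tp[s, i + 1L]; dn <- tm[s, i + 1L]
    if (i < N) P[idx(i, s), idx(i + 1L, sp)] <-
        P[idx(i, s), idx(i + 1L, sp)] + up * mu[s, sp]
    if (i > 0) P[idx(i, s), idx(i - 1L, sp)] <-
        P[idx(i, s), idx(i - 1L, sp)] + dn * mu[s, sp]
    P[idx(i, s), idx(i, sp)] <- P[idx(i, s), idx(i, sp)] +
      (1 - up - dn) * mu[s, sp]
  }
  P
}

.joint_index_sets <- function(N, om) {
  idx <- function(i, s) (s - 1L) * (N + 1L) + i + 1L
  list(
    transient = as.vector(vapply(seq_len(om), function(s) idx(1:(N - 1L), s),
                                 integer(N - 1L))),
    fixA = vapply(seq_len(om), function(s) idx(N, s), integer(1)),
    ext = vapply(seq_len(om), function(s) idx(0L, s), integer(1))
  )
}

# returns list(phi, t, tau), each (N+1) x Omega, from the dense joint chain
oracle_fixation_discrete <- function(tp, tm, mu) {
  om <- nrow(tp); N <- ncol(tp) - 1L
  P <- oracle_joint_matrix(tp, tm, mu)
  ix <- .joint_index_sets(N, om)
  Q <- P[ix$transient, ix$transient, drop = FALSE]
  IQ <- diag(nrow(Q)) - Q
  h <- solve(IQ, rowSums(P[ix$transient, ix$fixA, drop = FALSE]))
  tt <- solve(IQ, rep(1, nrow(Q)))
  # Doob transform: chain conditioned on hitting the all-mutant class
  Qc <- Q * outer(1 / h, h)
  tau <- solve(diag(nrow(Q)) - Qc, rep(1, nrow(Q)))
  shape <- function(x, b0, bN) {
    m <- matrix(0, N + 1L, om)
    m[2:N, ] <- matrix(x, N - 1L, om)
    m[1L, ] <- b0; m[N + 1L, ] <- bN
    m
  }
  list(phi = shape(h, 0, 1), t = shape(tt, 0, 0),
       tau = {m <- shape(tau, 0, 0); m[1L, ] <- NA; m})
}

# continuous time via the embedded jump chain with holding-time weights
oracle_fixation_ct <- function(rp, rm, mrates) {
  om <- nrow(rp); N <- ncol(rp) - 1L
  m <- mrates; diag(m) <- 0
  mtot <- rowSums(m)
  Mst <- (N + 1L) * om
  P <- matrix(0, Mst, Mst)
  hold <- numeric(Mst)
  idx <- function(i, s) (s - 1L) * (N + 1L) + i + 1L
  for (s in seq_len(om)) for (i in 0:N) {
    interiorPop <- i > 0 && i < N
    up <- if (interiorPop) rp[s, i + 1L] else 0
    dn <- if (interiorPop) rm[s, i + 1L] else 0
    r <- up + dn + mtot[s]
    hold[idx(i, s)] <- if (r > 0) 1 / r else Inf
    if (r == 0) next
    if (i < N) P[idx(i, s), idx(i + 1L, s)] <- up / r
    if (i > 0) P[idx(i, s), idx(i - 1L, s)] <- dn / r
    for (sp in seq_len(om)) if (sp != s && m[s, sp] > 0)
      P[idx(i, s), idx(i, sp)] <- m[s, sp] / r
  }
  ix <- .joint_index_sets(N, om)
  Q <- P[ix$transient, ix$transient, drop = FALSE]
  IQ <- diag(nrow(Q)) - Q
  h <- solve(IQ, rowSums(P[ix$transient, ix$fixA, drop = FALSE]))
  tt <- solve(IQ, hold[ix$transient])
  Qc <- Q * outer(1 / h, h)
  tau <- solve(diag(nrow(Q)) - Qc, hold[ix$transient])
  shape <- function(x, b0, bN) {
    mm <- matrix(0, N + 1L, om)
    mm[2:N, ] <- matrix(x, N - 1L, om)
    mm[1L, ] <- b0; mm[N + 1L, ] <- bN
    mm
  }
  list(phi = shape(h, 0, 1), t = shape(tt, 0, 0),
       tau = {mm <- shape(tau, 0, 0); mm[1L, ] <- NA; mm})
}

# single-environment closed forms (classical results), independent of the
# package's log-space implementation
oracle_single_env_phi <- function(tp, tm) {
  N <- length(tp) - 1L
  gam <- tm[2:N] / tp[2:N]
  cp <- cumprod(gam)
  S <- c(1, 1 + cumsum(cp))  # S_i = 1 + sum_{k=1}^{i-1} prod_{j<=k} gamma_j
  c(0, S / S[N])             # phi_0 = 0, phi_i = S_i / S_N
}

# ---- random fixtures --------------------------------------------------------

rand_absorbing_model <- function(N, om) {
  tp <- matrix(0, om, N + 1L)
  tm <- matrix(0, om, N + 1L)
  for (s in seq_len(om)) {
    a <- runif(N - 1L, 0.05, 0.45)
    b <- runif(N - 1L, 0.05, 0.45)
    tp[s, 2:N] <- a
    tm[s, 2:N] <- b
  }
  birthDeathModel(tp, tm, absorbing = TRUE, timeConvention = "discrete")
}

rand_discrete_chain <- function(om) {
  mu <- matrix(runif(om * om, 0.05, 1), om, om)
  mu <- mu / rowSums(mu)
  envChainDiscrete(mu)
}

rand_ct_model <- function(N, om) {
  tp <- matrix(0, om, N + 1L)
  tm <- matrix(0, om, N + 1L)
  tp[, 2:N] <- runif(om * (N - 1L), 0.1, 1)
  tm[, 2:N] <- runif(om * (N - 1L), 0.1, 1)
  birthDeathModel(tp, tm, absorbing = TRUE, timeConvention = "continuous")
}

rand_ct_chain <- function(om) {
  m <- matrix(runif(om * om, 0.05, 0.5), om, om)
  diag(m) <- 0
  envChainContinuous(m)
}

expect_close <- function(x, y, tol) {
  expect_lt(max(abs(x - y), na.rm = TRUE), tol)
}
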
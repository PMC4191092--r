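---
title: "Fixation and stationary dynamics in randomly switching environments"
author: "moranenv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation and stationary dynamics in randomly switching environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moranenv)
```

## The model

A population of fixed size $N$ contains $i$ mutants (type $A$) and $N - i$
wild-types (type $B$) and evolves by a one-step birth–death process: in each
elementary event $i$ can move to $i \pm 1$ or stay. The transition
probabilities $T^\pm_{i,\sigma}$ depend on the state $\sigma$ of an
*environment* that evolves independently of the population. In discrete time
the environment is a Markov chain with per-step switching probabilities
$\mu_{\sigma \to \sigma'}$ over $\Omega$ states; within one time step the
population first moves using the step-start environment's probabilities and
then the environment switches, so the joint one-step kernel factorizes as
$$R_{(i,\sigma) \to (i \pm 1, \sigma')} = T^\pm_{i,\sigma}\,
  \mu_{\sigma \to \sigma'}, \qquad
  R_{(i,\sigma) \to (i, \sigma')} = (1 - T^+_{i,\sigma} - T^-_{i,\sigma})\,
  \mu_{\sigma \to \sigma'} .$$
In continuous time, environment switches (rates $m_{\sigma\to\sigma'}$) and
birth–death events (rates $\tilde T^\pm_{i,\sigma}$) are separate
exponential-clock events.

Without mutation, $i = 0$ and $i = N$ are absorbing and the quantities of
interest are the fixation probability $\phi_{i,\sigma}$ (probability of
eventually reaching the all-mutant state from $(i,\sigma)$), the mean
unconditional absorption time $t_{i,\sigma}$, and the mean fixation time
conditioned on fixation, $\tau^A_{i,\sigma}$. All three satisfy backward
(first-step) equations; for example
$$\phi_{i,\sigma} = \sum_{\sigma'} \mu_{\sigma\to\sigma'}
  \left[ T^+_{i,\sigma}\,\phi_{i+1,\sigma'} + T^-_{i,\sigma}\,\phi_{i-1,\sigma'}
  + (1 - T^+_{i,\sigma} - T^-_{i,\sigma})\,\phi_{i,\sigma'} \right],$$
with $\phi_{0,\sigma} = 0$ and $\phi_{N,\sigma} = 1$. Conditional times are
computed through $\theta_{i,\sigma} = \phi_{i,\sigma}\tau^A_{i,\sigma}$,
which satisfies the same linear operator with inhomogeneity
$\phi_{i,\sigma}$ and zero boundaries — the ratio $\theta/\phi$ is taken only
where $\phi > 0$, and $\tau^A_{0,\sigma}$ is reported as `NA`.

## Solvers and numerical choices

**Direct solver (primary).** The backward equations are a sparse linear
system over the $(N-1)\,\Omega$ interior joint states (at most $3\Omega$
nonzeros per row). We assemble it with `Matrix` and solve by sparse LU with
up to two steps of iterative refinement; the residual
$\lVert b - Ax \rVert_\infty$ is stored in the solution's diagnostics and is
typically at machine precision. This route places no condition on
$\mu$ — singular switching matrices (e.g. the two-state case
$p_+ + p_- = 1$) are handled without special treatment.

**Recursion solver (cross-check).** Writing $\psi_i = \mu\,\phi_i$ and
$\upsilon_i = \psi_i - \psi_{i-1}$, the balance equations become a forward
recursion expressing $\upsilon_{i+1}$ in terms of $\upsilon_1,\dots,
\upsilon_i$, closed by the boundary constraint $\sum_i \upsilon_i =
\mathbf 1$ (and analogously, with inhomogeneities $-1$ and $-\phi$, for the
two time systems). This requires $\mu^{-1}$; near-singular matrices
(relative condition number above $10^{12}$) are rejected with a pointer to
the direct solver. Being a shooting method, the recursion amplifies its
dominant mode exponentially: at $N = 50$ it is exact (agreement with the
direct solver to $10^{-8}$ or better) for slow-to-moderate switching but
becomes rank-deficient for strong coupling, which the solver detects and
reports rather than returning an inaccurate answer. The direct solver is
therefore the default and the recursion is retained purely as an
independent validation path.

**No diffusion approximation.** The environmental switching process has no
continuum limit in the population coordinate, so all times are computed from
the exact backward systems, never from a diffusion approximation.

**Times and units.** Discrete-time results are in elementary steps;
`fixationTimes(sol, units = "generations")` divides by $N$ (one generation
= $N$ birth–death steps). Continuous-time results are in model time units.

## The switching game

The built-in application is the frequency-dependent Moran process for a
$2\times 2$ game whose payoff matrix depends on the environment. Expected
payoffs exclude self-interaction,
$$\pi_A(i) = \frac{a_\sigma (i-1) + b_\sigma (N-i)}{N-1}, \qquad
  \pi_B(i) = \frac{c_\sigma i + d_\sigma (N-i-1)}{N-1},$$
fitness is the exponential mapping $f = e^{\beta \pi}$ with selection
intensity $\beta \ge 0$, and the Moran update gives
$$T^+_{i,\sigma} = \frac{i f_A}{i f_A + (N-i) f_B}\cdot\frac{N-i}{N},
  \qquad
  T^-_{i,\sigma} = \frac{(N-i) f_B}{i f_A + (N-i) f_B}\cdot\frac{i}{N}.$$
The canonical parametrization (`switchingGame`) sets $a_\sigma = d_\sigma =
1$, $b_\sigma = 1 + \sigma b$, $c_\sigma = 1 + \sigma c$ over $\sigma = \pm
1$: with $b, c > 0$ the $+1$ environment is a coexistence game and the $-1$
environment a coordination game, with a common selection-balance point
$i^*$ solving $\pi_A(i) = \pi_B(i)$ (to leading order $i^*/N \approx
b/(b+c)$). At $N = 50$, $b = 0.5$, $c = 0.9$ the root is $i^* = 17.86$,
i.e. state 18:

```{r}
selectionBalancePoint(switchingGame(N = 50, b = 0.5, c = 0.9, beta = 0.5), "+1")
```

Mutation enters at the birth step: with probability $u$ the offspring is of
the opposite type, giving
$$T^+_{i,\sigma} = \frac{N-i}{N}\,
  \frac{(1-u)\, i f_A + u (N-i) f_B}{i f_A + (N-i) f_B}$$
(and symmetrically for $T^-$), so the escape probabilities from the
monomorphic states are exactly $u$ and the $u \to 0$ limit recovers the
absorbing process. This convention is isolated in `moranModel()` so an
alternative mutation scheme can be swapped in one place. The balance point
is reported both as the real root and the nearest integer state; a tie at
$.5$ rounds towards $N/2$.

## Effective theory for fast switching

When switching is much faster than fixation, the population sees the
occupancy-weighted *effective* probabilities. For the two-state telegraph
environment the fraction of time spent in state $\sigma$ is
$p_{-\sigma}/(p_+ + p_-)$, so
$$T^\pm_{i,\mathrm{eff}} = \frac{p_- T^\pm_{i,+1} + p_+ T^\pm_{i,-1}}
  {p_+ + p_-}.$$
Fixation quantities of the effective one-environment chain are evaluated
with the classical closed forms in $\gamma_i = T^-_{i,\mathrm{eff}} /
T^+_{i,\mathrm{eff}}$; all products and sums are accumulated in log space
(with a common max-shift), so exponential fitness at large $N$ cannot
overflow. `closedFormTimes()` evaluates the double sums for the headline
single-mutant case and fills the remaining starting states through the
algebraically equivalent first-step linear system of the same chain. The
effective description is exposed for $\Omega = 2$; occupancy weighting for
general $\Omega$ follows the same logic but is gated behind
`extension = TRUE` because the telegraph derivation does not cover it. The
theory is quantitative for fast switching (relative error of $\phi_1$ below
5% at $p_\pm = 0.1$ for the headline game, shrinking as switching speeds
up) and deliberately *not* expected to hold for slow switching, where
fixation depends on the initial environment.

## Stationary distributions with mutation

With $u > 0$ nothing is absorbing and the joint chain has a unique
stationary distribution $\rho_{i,\sigma}$, computed as the left eigenvector
of the one-step kernel at eigenvalue 1 (direct sparse solve of
$(R^\top - I)\rho = 0$ with a normalization row, plus refinement; the
residual $\lVert \rho^\top R - \rho^\top\rVert_\infty$ is reported and
checked at $10^{-10}$). Two approximations bracket the exact solution:

* **slow switching** — the occupancy-weighted average $\bar\rho_i =
  \sum_\sigma \rho_\sigma \rho^{(\sigma)}_i$ of the single-environment
  product forms $\rho^{(\sigma)}_i \propto \prod_{j \le i}
  T^+_{j-1,\sigma}/T^-_{j,\sigma}$;
* **fast switching** — the product form of the effective chain.

A frozen environment (diagonal $\mu$) makes the joint chain block-reducible;
`stationaryExact()` then solves each environment block's eigenvector
separately (still the eigen route, so the product form remains an
independent cross-check) and combines slices with caller-supplied weights,
uniform by default. Genuinely reducible non-diagonal chains are rejected
with the offending closed subset named.

The accuracy diagnostic is the Euclidean (L2) distance between the
instantaneous simulated marginal distribution and a candidate stationary
distribution, time-averaged over the second half of the run (the first half
is discarded as equilibration). The L1 norm is available through the
`norm` argument. We compare on the population marginal rather than the
joint distribution because the approximations under test are defined on the
marginal.

## Simulator

The Monte Carlo simulator (compiled code) reproduces the solver's chain
exactly: discrete steps draw the population move with the step-start
environment and then the environment move — any other ordering would
silently bias solver/simulation comparisons. Continuous time uses the
Gillespie algorithm. All draws use R's global RNG, so a single `set.seed`
(or the `seed` argument) makes whole ensembles bit-reproducible; runs are
sequential, not per-run counter streams. Ensemble estimators return
binomial standard errors for $\hat\phi$ and sample standard errors for the
time estimates; conditional times average over fixed runs only. Runs that
exhaust their step budget unabsorbed are flagged and counted, never raised
as errors.

```{r}
g <- switchingGame(N = 50, b = 0.5, c = 0.9, beta = 0.5)
m <- moranModel(g)
ch <- twoEnvChain(0.01, 0.01)
sol <- solveFixation(m, ch)
est <- estimateFixation(m, ch, i0 = 1, sigma0 = "+1", nRuns = 2e4, seed = 1)
c(exact = fixationProb(sol)[2, "+1"], mc = est@phiHat, se = est@phiSE)
```

## What the tests do and do not show

The test suite validates every solver against independent dense-chain
oracles (fundamental-matrix hitting probabilities and times, and the
Doob-transformed conditioned chain) on hundreds of randomized small models
($N \le 12$, $\Omega \le 3$), checks the classical closed forms and
neutrality ($\beta = 0 \Rightarrow \phi_1 = 1/N$), and reproduces the
headline phenomenology of the switching game at $N = 50$: an interior
maximum of $\phi_1(p_+)$ near $p_+ \approx p_-$, monotone decreasing
conditional times in $p_+$, the fast/slow crossover of the two stationary
approximations against ensembles of $10^4$ runs over $2\times 10^3$
generations, and the collapse onto the dominant environment for disparate
switching rates. Problem sizes were chosen so the whole suite runs on a
laptop in about a minute; the randomized models draw interior transition
probabilities bounded away from 0, so the suite does not probe
nearly-degenerate chains with vanishing interior rates, and the synthetic
models do not emulate features of real populations such as demographic
size changes or more than two types.

## Known limitations

* The recursion solver is a cross-check, not a production path; it reports
  rank-deficiency rather than attempting to stabilize strongly coupled
  large-$N$ systems.
* The continuous-time theory treats the birth–death rates as free inputs;
  `asContinuous()` maps discrete probabilities one-to-one onto rates as a
  convenience, which is a choice, not a derived correspondence.
* Multi-player games, pairwise-comparison update rules, and
  population-state-dependent switching are out of scope.
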
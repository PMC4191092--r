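#' Load a model configuration from YAML
#'
#' Reads a config with blocks `environment` (either `type: discrete` with a
#' `matrix` or `p_plus`/`p_minus`, or `type: continuous` with `rates`) and
#' `game` (`N`, `beta`, and either amplitudes `b`/`c` or an explicit
#' `payoffs` list per environment; optional `u`). All object-level
#' validations run on construction.
#'
#' @param path path to a YAML file.
#' @return List with components `chain`, `game` and `model`.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  # keep YAML-1.1 boolean-like keys (N, y, ...) as literal strings: the
  # schema has no boolean keys, and `N` is a key we need verbatim
  cfg <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(v) v, "bool#no" = function(v) v))
  missing <- setdiff(c("environment", "game"), names(cfg))
  if (length(missing))
    stop("config is missing block(s): ", paste(missing, collapse = ", "))
  env <- cfg$environment
  type <- env$type %||% "discrete"
  chain <- if (type == "discrete") {
    if (!is.null(env$matrix)) {
      envChainDiscrete(do.call(rbind, env$matrix))
    } else if (!is.null(env$p_plus) && !is.null(env$p_minus)) {
      twoEnvChain(env$p_plus, env$p_minus)
    } else stop("environment block needs 'matrix' or 'p_plus'/'p_minus'")
  } else if (type == "continuous") {
    if (is.null(env$rates)) stop("continuous environment block needs 'rates'")
    envChainContinuous(do.call(rbind, env$rates))
  } else stop("environment type must be 'discrete' or 'continuous'")

  g <- cfg$game
  missingG <- setdiff("N", names(g))
  if (length(missingG))
    stop("game block is missing key(s): ", paste(missingG, collapse = ", "))
  if (is.null(g$beta)) stop("game block is missing key(s): beta")
  spec <- if (!is.null(g$b) && !is.null(g$c)) {
    switchingGame(N = g$N, b = g$b, c = g$c, beta = g$beta, u = g$u %||% 0)
  } else if (!is.null(g$payoffs)) {
    po <- do.call(rbind, lapply(g$payoffs, function(p)
      c(p$a, p$b, p$c, p$d)))
    gameSpec(po, beta = g$beta, N = g$N, u = g$u %||% 0,
             labels = chain@labels)
  } else stop("game block needs 'b'/'c' or 'payoffs'")
  model <- moranModel(spec)
  if (model@omega != chain@omega)
    stop("environment and game disagree on the number of environments")
  list(chain = chain, game = spec, model = model)
}

#' Sweep fixation statistics over a grid of switching probabilities
#'
#' Evaluates the exact solver on a grid of \eqn{p_+} values at fixed
#' \eqn{p_-} and reports the single-mutant fixation probability and mean
#' conditional fixation time for each starting environment. Solver failures
#' at individual grid points are flagged (`ok = FALSE`) and the sweep
#' continues.
#'
#' @param spec a two-environment [GameSpec][GameSpec-class] with `u = 0`.
#' @param pPlusGrid numeric vector of \eqn{p_+} values in \eqn{[0,1]}.
#' @param pMinus fixed \eqn{p_-}.
#' @return Data frame with columns `p_plus`, `sigma0`, `phi1`,
#'   `tau1_steps`, `tau1_generations`, `t1_steps`, `ok`.
#' @examples
#' sw <- runSweep(switchingGame(20, 0.5, 0.9, beta = 0.5),
#'                pPlusGrid = 10^seq(-3, -1), pMinus = 0.01)
#' @export
runSweep <- function(spec, pPlusGrid, pMinus) {
  if (!length(pPlusGrid)) stop("empty p_plus grid")
  if (any(pPlusGrid < 0 | pPlusGrid > 1) || pMinus < 0 || pMinus > 1)
    stop("switching probabilities must lie in [0, 1]")
  model <- moranModel(spec)
  rows <- lapply(pPlusGrid, function(pp) {
    res <- tryCatch({
      sol <- solveFixation(model, twoEnvChain(pp, pMinus))
      data.frame(p_plus = pp, sigma0 = spec@labels,
                 phi1 = sol@phi[2L, ],
                 tau1_steps = sol@tCond[2L, ],
                 tau1_generations = sol@tCond[2L, ] / spec@N,
                 t1_steps = sol@tUncond[2L, ],
                 ok = TRUE, row.names = NULL)
    }, error = function(e)
      data.frame(p_plus = pp, sigma0 = spec@labels, phi1 = NA_real_,
                 tau1_steps = NA_real_, tau1_generations = NA_real_,
                 t1_steps = NA_real_, ok = FALSE, row.names = NULL))
    res
  })
  do.call(rbind, rows)
}

#' Switching probability that maximizes single-mutant fixation
#'
#' Scans a \eqn{p_+} grid at fixed \eqn{p_-} and returns the grid argmax of
#' \eqn{\phi_{1,\sigma}} per starting environment.
#'
#' @inheritParams runSweep
#' @return Data frame with columns `sigma0`, `p_plus_opt`, `phi1_max`.
#' @export
optimalPPlus <- function(spec, pPlusGrid, pMinus) {
  sw <- runSweep(spec, pPlusGrid, pMinus)
  sw <- sw[sw$ok, ]
  out <- do.call(rbind, lapply(split(sw, sw$sigma0), function(d) {
    k <- which.max(d$phi1)
    data.frame(sigma0 = d$sigma0[k], p_plus_opt = d$p_plus[k],
               phi1_max = d$phi1[k], row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Export a fixation solution as a CSV table
#'
#' Columns: `i`, `sigma`, `phi`, `t_uncond_steps`, `t_uncond_generations`,
#' `t_cond_steps`, `t_cond_generations`.
#'
#' @param sol a [FixationSolution][FixationSolution-class].
#' @param path output file path.
#' @return The written data frame, invisibly.
#' @export
writeFixationCSV <- function(sol, path) {
  N <- sol@N
  df <- data.frame(
    i = rep(0:N, length(sol@labels)),
    sigma = rep(sol@labels, each = N + 1L),
    phi = as.vector(sol@phi),
    t_uncond_steps = as.vector(sol@tUncond),
    t_uncond_generations = as.vector(sol@tUncond) / N,
    t_cond_steps = as.vector(sol@tCond),
    t_cond_generations = as.vector(sol@tCond) / N
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
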
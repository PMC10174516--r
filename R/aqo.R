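#' Aquila optimizer parameters
#'
#' The optimizer alternates four hunting behaviours — high soar with
#' vertical stoop, contour flight with short glide attack, low flight with
#' slow descent, and swooping — switching from the exploration pair to the
#' exploitation pair once two thirds of the iteration budget has elapsed.
#' The update-rule internals follow the canonical Aquila formulation; their
#' coefficients are exposed here.
#'
#' @param n_agents population size N (>= 2).
#' @param max_iter iteration budget T.
#' @param seed integer seed.
#' @param update_rule_set identifier of the rule set (only `"canonical"`).
#' @param alpha,delta exploitation adjustment constants (default 0.1).
#' @param levy_beta,levy_s Levy-flight stability index and scale
#'   (1.5, 0.01).
#' @param spiral_u,spiral_omega,spiral_r0 contour-flight spiral shape
#'   constants.
#' @return Object of class `gs_aqo_params`.
#' @export
aqo_params <- function(n_agents = 20L, max_iter = 50L, seed = 1L,
                       update_rule_set = "canonical", alpha = 0.1,
                       delta = 0.1, levy_beta = 1.5, levy_s = 0.01,
                       spiral_u = 0.00565, spiral_omega = 0.005,
                       spiral_r0 = 10) {
  stopifnot(n_agents >= 2L, max_iter >= 1L,
            identical(update_rule_set, "canonical"))
  structure(
    list(n_agents = as.integer(n_agents), max_iter = as.integer(max_iter),
         seed = as.integer(seed), update_rule_set = update_rule_set,
         alpha = alpha, delta = delta, levy_beta = levy_beta,
         levy_s = levy_s, spiral_u = spiral_u, spiral_omega = spiral_omega,
         spiral_r0 = spiral_r0),
    class = "gs_aqo_params"
  )
}

#' Phase of the Aquila schedule
#'
#' Exploration while `t <= (2/3) T` (inclusive), exploitation afterwards.
#'
#' @param t iteration, `1 <= t <= max_iter`.
#' @param max_iter iteration budget T.
#' @return `"exploration"` or `"exploitation"`.
#' @export
aqo_phase <- function(t, max_iter) {
  stopifnot(t >= 1, t <= max_iter)
  if (t <= (2 / 3) * max_iter) "exploration" else "exploitation"
}

#' Initialize the Aquila population
#'
#' `X_i = LB + rand(1, D) (UB - LB)`, fresh uniforms per agent/dimension.
#'
#' @param space a [search_space()].
#' @param params an [aqo_params()].
#' @return N x D position matrix.
#' @export
initialize_aqo <- function(space, params) {
  N <- params$n_agents
  D <- space$dim
  matrix(space$lower, N, D, byrow = TRUE) +
    matrix(runif(N * D), N, D) *
    matrix(space$upper - space$lower, N, D, byrow = TRUE)
}

levy_flight <- function(d, beta, s) {
  sigma <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- rnorm(d) * sigma
  v <- rnorm(d)
  s * u / abs(v)^(1 / beta)
}

#' Run the Aquila optimizer
#'
#' Minimizes `objective` over the box `space`. Each iteration every agent
#' proposes a move with one of the two phase-appropriate behaviours (chosen
#' with probability 1/2), the proposal is clamped to the bounds and accepted
#' greedily if it improves the agent's fitness; the swarm best is tracked
#' elitistically. Deterministic given `params$seed`.
#'
#' @param objective minimization objective, position -> finite scalar.
#' @param space a [search_space()].
#' @param params an [aqo_params()].
#' @param init_positions optional N x D seed positions.
#' @return A `gs_optim_result` (same trace format as [run_hgso()]).
#' @export
run_aqo <- function(objective, space, params, init_positions = NULL) {
  with_rng_seed(params$seed, {
    N <- params$n_agents
    D <- space$dim
    X <- if (is.null(init_positions)) {
      initialize_aqo(space, params)
    } else {
      stopifnot(nrow(init_positions) == N, ncol(init_positions) == D)
      clamp_rows(as.matrix(init_positions), space$lower, space$upper)
    }
    fit <- apply(X, 1, function(x) check_finite_objective(objective(x)))
    ib <- which.min(fit)
    best_pos <- X[ib, ]
    best_fit <- fit[ib]
    iters <- params$max_iter
    best_trace <- numeric(iters)
    div <- numeric(iters)
    temp <- numeric(iters)
    to <- seq_len(D)
    rspiral <- params$spiral_r0 + params$spiral_u * to
    phi <- -params$spiral_omega * to + 3 * pi / 2
    ycomp <- rspiral * cos(phi)
    xcomp <- rspiral * sin(phi)
    for (t in seq_len(iters)) {
      xm <- colMeans(X)
      explore <- identical(aqo_phase(t, iters), "exploration")
      for (i in seq_len(N)) {
        cand <- if (explore) {
          if (runif(1) < 0.5) {
            # high soar with vertical stoop (expanded exploration)
            best_pos * (1 - t / iters) + (xm - best_pos * runif(1))
          } else {
            # contour flight with short glide attack (narrowed exploration)
            xr <- X[sample.int(N, 1L), ]
            best_pos * levy_flight(D, params$levy_beta, params$levy_s) +
              xr + (ycomp - xcomp) * runif(1)
          }
        } else {
          if (runif(1) < 0.5) {
            # low flight with slow descent (expanded exploitation)
            (best_pos - xm) * params$alpha - runif(1) +
              ((space$upper - space$lower) * runif(1) + space$lower) *
              params$delta
          } else {
            # swooping (narrowed exploitation)
            qf <- t^((2 * runif(1) - 1) / (1 - iters)^2)
            g1 <- 2 * runif(1) - 1
            g2 <- 2 * (1 - t / iters)
            qf * best_pos - (g1 * X[i, ] * runif(1)) -
              g2 * levy_flight(D, params$levy_beta, params$levy_s) +
              runif(1) * g1
          }
        }
        cand <- clamp(cand, space$lower, space$upper)
        f <- check_finite_objective(objective(cand), i)
        if (f < fit[i]) { # greedy acceptance
          X[i, ] <- cand
          fit[i] <- f
          if (f < best_fit) {
            best_fit <- f
            best_pos <- cand
          }
        }
      }
      best_trace[t] <- best_fit
      div[t] <- diversity(X)
      temp[t] <- hgso_temperature(t, iters)
    }
    structure(
      list(best_position = best_pos, best_fitness = best_fit,
           trace = build_trace(best_trace, div, temp),
           population = list(positions = X, fitness = fit)),
      class = "gs_optim_result"
    )
  })
}

check_finite_objective <- function(f, agent = NULL) {
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
    stop("objective returned a non-finite value",
         if (!is.null(agent)) paste0(" for agent ", agent), call. = FALSE)
  }
  f
}

#' Run an optimizer strategy
#'
#' Dispatches to HGSO, AQO, or the sequential hybrid in which AQO explores
#' for the first half of the iteration budget and its final population seeds
#' the HGSO phase for the remainder (the hand-off coupling of the
#' "AQO + HGSO" pairing).
#'
#' @param objective minimization objective.
#' @param space a [search_space()].
#' @param strategy one of `"hgso"`, `"aqo"`, `"hybrid"`.
#' @param n_agents population size.
#' @param max_iter total iteration budget.
#' @param seed integer seed.
#' @param hgso_control,aqo_control named lists of extra arguments passed to
#'   [hgso_params()] / [aqo_params()].
#' @return A `gs_optim_result`; for the hybrid, traces of the two phases are
#'   concatenated and the exploration/exploitation percentages recomputed
#'   over the combined diversity series.
#' @export
run_optimizer <- function(objective, space, strategy = c("hgso", "aqo", "hybrid"),
                          n_agents = 10L, max_iter = 100L, seed = 1L,
                          hgso_control = list(), aqo_control = list()) {
  strategy <- match.arg(strategy)
  hp <- function(iters, sd) {
    do.call(hgso_params, c(list(n_agents = n_agents, max_iter = iters,
                                seed = sd), hgso_control))
  }
  ap <- function(iters, sd) {
    do.call(aqo_params, c(list(n_agents = n_agents, max_iter = iters,
                               seed = sd), aqo_control))
  }
  switch(
    strategy,
    hgso = run_hgso(objective, space, hp(max_iter, seed)),
    aqo = run_aqo(objective, space, ap(max_iter, seed)),
    hybrid = {
      first <- max(1L, floor(max_iter / 2))
      second <- max(1L, max_iter - first)
      stage1 <- run_aqo(objective, space, ap(first, seed))
      stage2 <- run_hgso(objective, space, hp(second, derive_seed(seed, 1L)),
                         init_positions = stage1$population$positions)
      best_fit <- cummin(c(stage1$trace$best_fitness,
                           stage2$trace$best_fitness))
      div <- c(stage1$trace$div, stage2$trace$div)
      temp <- c(stage1$trace$temperature, stage2$trace$temperature)
      res <- if (stage2$best_fitness <= stage1$best_fitness) stage2 else stage1
      structure(
        list(best_position = res$best_position,
             best_fitness = min(stage1$best_fitness, stage2$best_fitness),
             trace = transform(build_trace(best_fit, div, temp),
                               iteration = seq_along(best_fit)),
             population = stage2$population),
        class = "gs_optim_result"
      )
    }
  )
}
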
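#' Box-bounded search space
#'
#' @param dim number of decision variables.
#' @param lower,upper bounds, scalars or length-`dim` vectors
#'   (default `[-1, 1]`, the feature-selection domain range).
#' @return Object of class `gs_search_space`.
#' @export
search_space <- function(dim, lower = -1, upper = 1) {
  stopifnot(dim >= 1)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (!all(lower < upper)) stop("lower must be < upper elementwise",
                                call. = FALSE)
  structure(list(dim = as.integer(dim), lower = lower, upper = upper),
            class = "gs_search_space")
}

#' Henry gas solubility optimizer parameters
#'
#' Constants of the gas-solubility model. `l1`, `l2`, `l3` scale the random
#' initial Henry coefficients, partial pressures and Van't-Hoff constants
#' (defaults 5e-2, 100, 1e-2); `t_theta` is the reference temperature 298.15;
#' `c1`, `c2` bound the randomly drawn worst-agent fraction (0.1, 0.2). `K`
#' (solubility), `alpha` (swarm-best influence), `beta` (interaction) and
#' `epsilon` (fitness-ratio stabilizer) are not pinned by the model
#' description; identity-scale defaults `K = alpha = beta = 1`,
#' `epsilon = 0.05` are used and all are configurable.
#'
#' @param n_agents population size N.
#' @param n_clusters number of gas types (clusters), default 2.
#' @param l1,l2,l3 initialization scale constants.
#' @param K,alpha,beta,epsilon update constants, see Details.
#' @param c1,c2 worst-fraction bounds, `0 <= c1 < c2 <= 1`.
#' @param t_theta reference temperature.
#' @param max_iter iteration budget.
#' @param seed integer seed.
#' @return Object of class `gs_hgso_params`.
#' @export
hgso_params <- function(n_agents = 30L, n_clusters = 2L, l1 = 5e-2,
                        l2 = 100, l3 = 1e-2, K = 1, alpha = 1, beta = 1,
                        epsilon = 0.05, c1 = 0.1, c2 = 0.2,
                        t_theta = 298.15, max_iter = 50L, seed = 1L) {
  stopifnot(n_agents >= n_clusters, n_clusters >= 1L, max_iter >= 1L,
            c1 >= 0, c1 < c2, c2 <= 1,
            l1 > 0, l2 > 0, l3 > 0, K > 0, alpha > 0, beta > 0,
            epsilon > 0, t_theta > 0)
  structure(
    list(n_agents = as.integer(n_agents), n_clusters = as.integer(n_clusters),
         l1 = l1, l2 = l2, l3 = l3, K = K, alpha = alpha, beta = beta,
         epsilon = epsilon, c1 = c1, c2 = c2, t_theta = t_theta,
         max_iter = as.integer(max_iter), seed = as.integer(seed)),
    class = "gs_hgso_params"
  )
}

#' Partition agents into contiguous, near-equal gas clusters
#'
#' Sizes differ by at most one; the remainder is spread over the first
#' clusters.
#'
#' @param n_agents number of agents.
#' @param n_clusters number of clusters (gas types).
#' @return integer vector of cluster ids, length `n_agents`.
#' @examples
#' assign_clusters(7, 3) # sizes 3, 2, 2
#' @export
assign_clusters <- function(n_agents, n_clusters) {
  if (n_clusters > n_agents) {
    stop("n_clusters (", n_clusters, ") exceeds n_agents (", n_agents, ")",
         call. = FALSE)
  }
  base <- n_agents %/% n_clusters
  extra <- n_agents %% n_clusters
  sizes <- rep(base, n_clusters) + c(rep(1L, extra),
                                     rep(0L, n_clusters - extra))
  rep(seq_len(n_clusters), times = sizes)
}

#' Iteration temperature schedule
#'
#' `T(t) = exp(-t / max_iter)`, strictly decreasing over the run.
#'
#' @param t iteration, `1 <= t <= max_iter`.
#' @param max_iter iteration budget.
#' @return scalar temperature.
#' @export
hgso_temperature <- function(t, max_iter) {
  if (t < 1 || t > max_iter) {
    stop("t = ", t, " outside [1, ", max_iter, "]", call. = FALSE)
  }
  exp(-t / max_iter)
}

#' Henry coefficient update
#'
#' `H_j(t+1) = H_j(t) * exp(-C_j * (1/T(t) - 1/T_theta))` (Van't Hoff form).
#'
#' @param henry_j current Henry coefficient(s), > 0.
#' @param c_j Van't-Hoff constant(s), >= 0.
#' @param temp current temperature, > 0.
#' @param t_theta reference temperature, > 0.
#' @return updated coefficient(s), strictly positive.
#' @export
update_henry <- function(henry_j, c_j, temp, t_theta = 298.15) {
  if (any(temp <= 0) || t_theta <= 0) {
    stop("temperatures must be positive", call. = FALSE)
  }
  stopifnot(all(henry_j > 0), all(c_j >= 0))
  henry_j * exp(-c_j * (1 / temp - 1 / t_theta))
}

#' Gas solubility update
#'
#' `S_ij = K * H_j * P_ij` (Henry's law).
#'
#' @param k solubility constant K.
#' @param henry_j per-agent Henry coefficient (cluster value expanded).
#' @param pressure_ij per-agent partial pressure.
#' @return per-agent solubility.
#' @export
update_solubility <- function(k, henry_j, pressure_ij) {
  stopifnot(k > 0, all(henry_j > 0), all(pressure_ij > 0))
  k * henry_j * pressure_ij
}

#' Interaction ability of a gas
#'
#' `gamma = beta * exp(-(F_best + eps) / (F_ij + eps))`; for non-negative
#' fitness (minimization) this lies in (0, beta].
#'
#' @param f_best best fitness in the swarm.
#' @param f_ij fitness of the agent.
#' @param beta interaction constant.
#' @param epsilon stabilizer added to both numerator and denominator.
#' @return interaction coefficient(s).
#' @export
interaction_gamma <- function(f_best, f_ij, beta = 1, epsilon = 0.05) {
  if (any(f_ij + epsilon <= 0)) {
    stop("f_ij + epsilon must be positive", call. = FALSE)
  }
  beta * exp(-(f_best + epsilon) / (f_ij + epsilon))
}

#' Number of worst agents to re-randomize
#'
#' `Nw = floor(N * (rand * (c2 - c1) + c1))` with `rand` uniform on the unit interval,
#' so `Nw` lies between `floor(c1 N)` and `floor(c2 N)`. For `N >= 10` at
#' least one agent is always replaced. Consumes one uniform draw from the
#' global RNG.
#'
#' @param n_agents population size N.
#' @param c1,c2 fraction bounds.
#' @return integer count.
#' @export
count_worst <- function(n_agents, c1 = 0.1, c2 = 0.2) {
  stopifnot(n_agents >= 1)
  nw <- floor(n_agents * (runif(1) * (c2 - c1) + c1))
  if (n_agents >= 10L) nw <- max(1L, nw)
  as.integer(nw)
}

#' Initialize a gas population
#'
#' Positions are `X_min + r (X_max - X_min)` with fresh uniforms per
#' agent/dimension; `H_j = l1 rand`, `P_ij = l2 rand`, `C_j = l3 rand`;
#' solubility starts at `K H_j P_ij`. Fitness is `NA` until evaluated.
#' RNG draw order (column-major matrices): positions (N x D), henry
#' (n_clusters), pressure (N), cvals (n_clusters).
#'
#' @param space a [search_space()].
#' @param params a [hgso_params()].
#' @return Object of class `gs_population`.
#' @export
initialize_population <- function(space, params) {
  N <- params$n_agents
  D <- space$dim
  positions <- matrix(space$lower, N, D, byrow = TRUE) +
    matrix(runif(N * D), N, D) *
    matrix(space$upper - space$lower, N, D, byrow = TRUE)
  henry <- params$l1 * runif(params$n_clusters)
  pressure <- params$l2 * runif(N)
  cvals <- params$l3 * runif(params$n_clusters)
  cluster_id <- assign_clusters(N, params$n_clusters)
  structure(
    list(positions = positions, fitness = rep(NA_real_, N),
         cluster_id = cluster_id, henry = henry, pressure = pressure,
         cvals = cvals,
         solubility = params$K * henry[cluster_id] * pressure,
         cluster_best_pos = matrix(NA_real_, params$n_clusters, D),
         cluster_best_fit = rep(Inf, params$n_clusters),
         best_pos = rep(NA_real_, D), best_fit = Inf),
    class = "gs_population"
  )
}

evaluate_agents <- function(pop, objective, rows = seq_len(nrow(pop$positions))) {
  for (i in rows) {
    f <- objective(pop$positions[i, ])
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
      stop("objective returned a non-finite value for agent ", i,
           call. = FALSE)
    }
    pop$fitness[i] <- f
  }
  pop
}

refresh_bests <- function(pop) {
  for (j in seq_along(pop$henry)) {
    rows <- which(pop$cluster_id == j)
    b <- rows[which.min(pop$fitness[rows])]
    if (pop$fitness[b] < pop$cluster_best_fit[j]) {
      pop$cluster_best_fit[j] <- pop$fitness[b]
      pop$cluster_best_pos[j, ] <- pop$positions[b, ]
    }
  }
  j_best <- which.min(pop$cluster_best_fit)
  if (pop$cluster_best_fit[j_best] < pop$best_fit) {
    pop$best_fit <- pop$cluster_best_fit[j_best]
    pop$best_pos <- pop$cluster_best_pos[j_best, ]
  }
  pop
}

#' Re-randomize the worst agents inside the bounds
#'
#' The `n_worst` agents with the highest (worst) fitness — ties broken by
#' lowest agent index first — receive fresh uniform positions
#' `G_min + r (G_max - G_min)` and their fitness is marked stale (`NA`) for
#' re-evaluation. Draws `n_worst x D` uniforms (column-major).
#'
#' @param pop a `gs_population`.
#' @param n_worst how many agents to replace.
#' @param space a [search_space()].
#' @return list with the updated population and `replaced` (agent indices).
#' @export
reinitialize_worst <- function(pop, n_worst, space) {
  stopifnot(n_worst >= 0, n_worst <= nrow(pop$positions))
  if (n_worst == 0L) return(list(pop = pop, replaced = integer(0)))
  worst <- order(pop$fitness, decreasing = TRUE)[seq_len(n_worst)]
  D <- space$dim
  fresh <- matrix(space$lower, n_worst, D, byrow = TRUE) +
    matrix(runif(n_worst * D), n_worst, D) *
    matrix(space$upper - space$lower, n_worst, D, byrow = TRUE)
  pop$positions[worst, ] <- fresh
  pop$fitness[worst] <- NA_real_
  list(pop = pop, replaced = worst)
}

#' One full HGSO iteration
#'
#' Executes one pass of the algorithm's loop: position update toward cluster
#' and swarm bests scaled by interaction ability and solubility, clamping to
#' the bounds, fitness evaluation, Henry-coefficient and solubility updates,
#' worst-agent escape, and best refresh.
#'
#' RNG draw order (all from the global stream, column-major for matrices):
#' direction-flag uniforms (N), the shared step uniforms r (N x D), the
#' worst-count uniform (1), then the re-initialization uniforms
#' (Nw x D). The direction flag is -1 when its uniform is < 0.5, else +1;
#' the same r multiplies both attraction terms, as the update rule is
#' printed with a single r.
#'
#' @param pop an evaluated `gs_population` (no `NA` fitness).
#' @param t current iteration (1-based).
#' @param objective minimization objective, position -> finite scalar.
#' @param space a [search_space()].
#' @param params a [hgso_params()].
#' @return the updated `gs_population`.
#' @export
hgso_step <- function(pop, t, objective, space, params) {
  N <- nrow(pop$positions)
  D <- ncol(pop$positions)
  temp <- hgso_temperature(t, params$max_iter)

  gamma <- interaction_gamma(pop$best_fit, pop$fitness, params$beta,
                             params$epsilon)
  flag <- ifelse(runif(N) < 0.5, -1, 1)
  r <- matrix(runif(N * D), N, D)
  xc <- pop$cluster_best_pos[pop$cluster_id, , drop = FALSE]
  xb <- matrix(pop$best_pos, N, D, byrow = TRUE)
  step1 <- flag * r * gamma * (xc - pop$positions)
  step2 <- flag * r * params$alpha *
    (pop$solubility * xb - pop$positions)
  pop$positions <- clamp_rows(pop$positions + step1 + step2,
                              space$lower, space$upper)
  pop <- evaluate_agents(pop, objective)

  pop$henry <- update_henry(pop$henry, pop$cvals, temp, params$t_theta)
  pop$solubility <- update_solubility(params$K, pop$henry[pop$cluster_id],
                                      pop$pressure)

  nw <- count_worst(N, params$c1, params$c2)
  res <- reinitialize_worst(pop, nw, space)
  pop <- evaluate_agents(res$pop, objective, res$replaced)
  refresh_bests(pop)
}

#' Run the Henry gas solubility optimizer
#'
#' Minimizes `objective` over the box `space` for `params$max_iter`
#' iterations, returning the best position, its fitness, and a per-iteration
#' trace (best-so-far fitness, population diversity, exploration /
#' exploitation percentages, temperature). Deterministic given
#' `params$seed`.
#'
#' @param objective function mapping a position vector to a finite scalar
#'   (minimization; wrap with `function(x) -f(x)` to maximize).
#' @param space a [search_space()].
#' @param params a [hgso_params()].
#' @param init_positions optional N x D matrix seeding the initial positions
#'   (used by the hybrid AQO hand-off); bounds-clamped.
#' @return Object of class `gs_optim_result`: list with `best_position`,
#'   `best_fitness`, `trace` (data.frame with columns iteration,
#'   best_fitness, div, exploration_pct, exploitation_pct, temperature), and
#'   `population`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- run_hgso(sphere, search_space(3, -5, 5),
#'                 hgso_params(n_agents = 10, max_iter = 20, seed = 7))
#' res$best_fitness
#' @export
run_hgso <- function(objective, space, params, init_positions = NULL) {
  with_rng_seed(params$seed, {
    pop <- initialize_population(space, params)
    if (!is.null(init_positions)) {
      stopifnot(nrow(init_positions) == params$n_agents,
                ncol(init_positions) == space$dim)
      pop$positions <- clamp_rows(as.matrix(init_positions),
                                  space$lower, space$upper)
    }
    pop <- evaluate_agents(pop, objective)
    pop <- refresh_bests(pop)
    iters <- params$max_iter
    best_fit <- numeric(iters)
    div <- numeric(iters)
    temp <- numeric(iters)
    for (t in seq_len(iters)) {
      pop <- hgso_step(pop, t, objective, space, params)
      best_fit[t] <- pop$best_fit
      div[t] <- diversity(pop$positions)
      temp[t] <- hgso_temperature(t, iters)
    }
    trace <- build_trace(best_fit, div, temp)
    structure(
      list(best_position = pop$best_pos, best_fitness = pop$best_fit,
           trace = trace, population = pop),
      class = "gs_optim_result"
    )
  })
}

build_trace <- function(best_fit, div, temp) {
  if (max(div) > 0) {
    ee <- exploration_exploitation(div)
  } else {
    ee <- data.frame(exploration_pct = rep(NA_real_, length(div)),
                     exploitation_pct = NA_real_)
  }
  data.frame(iteration = seq_along(best_fit), best_fitness = best_fit,
             div = div, exploration_pct = ee$exploration_pct,
             exploitation_pct = ee$exploitation_pct, temperature = temp)
}

#' @export
print.gs_optim_result <- function(x, ...) {
  cat("<gs_optim_result> best fitness ", format(x$best_fitness),
      " after ", nrow(x$trace), " iterations\n", sep = "")
  invisible(x)
}

#' Dimension-wise population diversity
#'
#' Mean absolute deviation from the per-dimension median, averaged over
#' dimensions: `Div_j = mean_i |median(x_j) - x_ij|`, `Div_t = mean_j Div_j`.
#' The median over an even number of agents is the midpoint of the two
#' central values.
#'
#' @param positions N x D numeric matrix.
#' @return scalar diversity.
#' @export
diversity <- function(positions) {
  positions <- as.matrix(positions)
  med <- apply(positions, 2, median)
  mean(colMeans(abs(sweep(positions, 2, med))))
}

#' Exploration / exploitation percentages from a diversity series
#'
#' `Exploration% = 100 Div_t / Div_max`,
#' `Exploitation% = 100 |Div_t - Div_max| / Div_max`; the two always sum to
#' 100 since `Div_t <= Div_max`.
#'
#' @param div_series per-iteration diversity values.
#' @return data.frame with `exploration_pct` and `exploitation_pct`.
#' @export
exploration_exploitation <- function(div_series) {
  div_max <- max(div_series)
  if (div_max <= 0) {
    stop("all-zero diversity series: percentages undefined", call. = FALSE)
  }
  data.frame(exploration_pct = div_series / div_max * 100,
             exploitation_pct = abs(div_series - div_max) / div_max * 100)
}

#' Export an optimization trace
#'
#' Writes the per-iteration trace as CSV and a run manifest (seed and all
#' constants) as JSON.
#'
#' @param result a `gs_optim_result`.
#' @param params the parameter object used for the run.
#' @param csv_path,manifest_path output paths.
#' @return invisible list of paths.
#' @export
export_trace <- function(result, params, csv_path, manifest_path) {
  utils::write.csv(result$trace, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(params = unclass(params), best_fitness = result$best_fitness,
         best_position = result$best_position),
    manifest_path, digits = NA, auto_unbox = TRUE
  )
  invisible(list(csv = csv_path, manifest = manifest_path))
}
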
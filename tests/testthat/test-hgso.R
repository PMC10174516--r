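test_that("assign_clusters partitions near-equally with remainder first", {
  expect_equal(tabulate(assign_clusters(10, 2)), c(5L, 5L))
  expect_equal(tabulate(assign_clusters(7, 3)), c(3L, 2L, 2L))
  expect_equal(assign_clusters(4, 4), 1:4)
  expect_error(assign_clusters(3, 4), "exceeds")
})

test_that("temperature schedule follows exp(-t/iter) and decreases", {
  expect_equal(hgso_temperature(50, 100), exp(-0.5), tolerance = 1e-12)
  expect_equal(hgso_temperature(100, 100), exp(-1), tolerance = 1e-12)
  temps <- vapply(1:40, hgso_temperature, numeric(1), max_iter = 40)
  expect_true(all(diff(temps) < 0))
  expect_error(hgso_temperature(0, 10), "outside")
  expect_error(hgso_temperature(11, 10), "outside")
})

test_that("Henry update follows the Van't Hoff form", {
  expect_equal(update_henry(0.05, 0.01, 0.606531, 298.15), 0.049184,
               tolerance = 1e-6)
  expect_equal(update_henry(0.05, 0, 0.5, 298.15), 0.05)     # C = 0
  expect_equal(update_henry(0.07, 0.3, 298.15, 298.15), 0.07) # T = T_theta
  expect_error(update_henry(0.05, 0.01, -1, 298.15), "positive")
  # vectorized over clusters, stays positive
  h <- update_henry(c(0.01, 0.04), c(0.002, 0.009), 0.4)
  expect_true(all(h > 0))
})

test_that("solubility is the Henry-law product", {
  expect_equal(update_solubility(1, 0.05, 50), 2.5)
  expect_equal(update_solubility(1, 0.025, 50), 1.25)
  expect_equal(update_solubility(2, 1, 7), 14)
})

test_that("interaction ability matches its closed form", {
  expect_equal(interaction_gamma(0.1, 0.2, 1, 0.05), exp(-0.6),
               tolerance = 1e-12)
  expect_equal(interaction_gamma(0.3, 0.3, 2, 0.05), 2 * exp(-1))
  expect_equal(interaction_gamma(0.1, 0.2, 4, 0.05),
               4 * interaction_gamma(0.1, 0.2, 1, 0.05))
  expect_error(interaction_gamma(0.1, -0.2, 1, 0.05), "positive")
})

test_that("initialization follows the documented draw order and scales", {
  space <- search_space(3, c(-2, 0, 1), c(2, 1, 4))
  params <- hgso_params(n_agents = 6, n_clusters = 2, max_iter = 5,
                        seed = 1)
  set.seed(31)
  pop <- initialize_population(space, params)
  set.seed(31) # replay the documented draw order
  r_pos <- matrix(runif(6 * 3), 6, 3)
  h_exp <- 0.05 * runif(2)
  p_exp <- 100 * runif(6)
  c_exp <- 0.01 * runif(2)
  pos_exp <- matrix(space$lower, 6, 3, byrow = TRUE) +
    r_pos * matrix(space$upper - space$lower, 6, 3, byrow = TRUE)
  expect_equal(pop$positions, pos_exp, tolerance = 1e-15)
  expect_equal(pop$henry, h_exp)
  expect_equal(pop$pressure, p_exp)
  expect_equal(pop$cvals, c_exp)
  expect_equal(pop$solubility, params$K * h_exp[pop$cluster_id] * p_exp)
  expect_true(all(pop$henry > 0 & pop$henry < 0.05))
  expect_true(all(pop$pressure > 0 & pop$pressure < 100))
  expect_true(all(pop$cvals > 0 & pop$cvals < 0.01))
})

test_that("worst-agent count respects the 10-20% band and floor rule", {
  set.seed(4)
  nws <- replicate(200, count_worst(30))
  expect_true(all(nws >= 3L & nws <= 6L))
  set.seed(9)
  u <- runif(1)
  set.seed(9)
  expect_identical(count_worst(30), as.integer(floor(30 * (u * 0.1 + 0.1))))
  # N >= 10 always replaces at least one agent
  set.seed(5)
  expect_true(all(replicate(50, count_worst(10)) >= 1L))
})

test_that("reinitialize_worst replaces the right agents inside bounds", {
  space <- search_space(2, -1, 1)
  params <- hgso_params(n_agents = 4, n_clusters = 2, max_iter = 5)
  set.seed(2)
  pop <- initialize_population(space, params)
  pop$fitness <- c(1, 5, 5, 3)

  expect_identical(reinitialize_worst(pop, 0, space)$pop$positions,
                   pop$positions)
  # tie on worst fitness: lowest index replaced first
  res <- reinitialize_worst(pop, 1, space)
  expect_identical(res$replaced, 2L)
  expect_true(is.na(res$pop$fitness[2]))
  res_all <- reinitialize_worst(pop, 4, space)
  expect_true(all(res_all$pop$positions >= -1 & res_all$pop$positions <= 1))
  expect_true(all(is.na(res_all$pop$fitness)))
})

test_that("diversity is the mean absolute deviation from the median", {
  expect_equal(diversity(matrix(3, 5, 4)), 0)
  expect_equal(diversity(rbind(c(0, 0), c(2, 2))), 1)
  m <- matrix(rnorm(40), 10, 4)
  expect_equal(diversity(3 * m), 3 * diversity(m), tolerance = 1e-12)
  expect_equal(diversity(-2 * m), 2 * diversity(m), tolerance = 1e-12)
})

test_that("exploration/exploitation percentages are complementary", {
  ee <- exploration_exploitation(c(4, 2, 1))
  expect_equal(ee$exploration_pct, c(100, 50, 25))
  expect_equal(ee$exploitation_pct, c(0, 50, 75))
  expect_equal(ee$exploration_pct + ee$exploitation_pct, rep(100, 3))
  expect_error(exploration_exploitation(c(0, 0)), "undefined")
})

test_that("run_hgso: flat landscape, determinism, bounds, error contract", {
  space <- search_space(3, -2, 2)
  params <- hgso_params(n_agents = 8, n_clusters = 2, max_iter = 12,
                        seed = 21)
  flat <- run_hgso(function(x) 7, space, params)
  expect_equal(flat$trace$best_fitness, rep(7, 12))
  expect_equal(flat$best_fitness, 7)

  r1 <- run_hgso(sphere, space, params)
  r2 <- run_hgso(sphere, space, params)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_position, r2$best_position)
  expect_true(all(r1$population$positions >= -2 &
                    r1$population$positions <= 2))
  expect_true(all(r1$population$henry > 0))
  expect_true(all(r1$population$solubility > 0))
  expect_true(all(r1$population$pressure > 0))

  expect_error(run_hgso(function(x) NaN, space, params), "non-finite")
})

test_that("best-so-far is non-increasing for varied objectives and seeds", {
  space <- search_space(4, -3, 3)
  objectives <- list(sphere,
                     function(x) sum(abs(x)) + 1,
                     function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)))
  for (obj in objectives) {
    for (s in 1:3) {
      tr <- run_hgso(obj, space,
                     hgso_params(n_agents = 10, max_iter = 15, seed = s))$trace
      expect_true(all(diff(tr$best_fitness) <= 0))
      expect_equal(tr$exploration_pct + tr$exploitation_pct, rep(100, 15))
      expect_true(all(tr$exploration_pct >= 0 & tr$exploration_pct <= 100))
    }
  }
})

test_that("diversity trends downward on the sphere", {
  lasts <- firsts <- numeric(5)
  for (s in 1:5) {
    tr <- run_hgso(sphere, search_space(5, -5, 5),
                   hgso_params(n_agents = 20, max_iter = 40, seed = s))$trace
    k <- max(1, floor(0.1 * nrow(tr)))
    firsts[s] <- mean(head(tr$div, k))
    lasts[s] <- mean(tail(tr$div, k))
  }
  expect_lt(median(lasts), median(firsts))
})

test_that("trace export writes CSV and manifest", {
  params <- hgso_params(n_agents = 6, max_iter = 5, seed = 3)
  res <- run_hgso(sphere, search_space(2, -1, 1), params)
  csv <- withr::local_tempfile(fileext = ".csv")
  mf <- withr::local_tempfile(fileext = ".json")
  export_trace(res, params, csv, mf)
  tr <- read.csv(csv)
  expect_equal(nrow(tr), 5L)
  expect_named(tr, c("iteration", "best_fitness", "div", "exploration_pct",
                     "exploitation_pct", "temperature"))
  man <- jsonlite::read_json(mf)
  expect_equal(man$params$seed, 3L)
})
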
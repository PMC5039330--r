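test_that("parent sampling is growth-weighted with replacement", {
  p <- unit_params()
  set.seed(501)

  # identical growth rates: uniform over indices
  pop <- init_population(p, 10, g0 = 0.5)
  draws <- sample_parent(pop, 1e5)
  expect_gt(stats::chisq.test(tabulate(draws, 10))$p.value, 0.001)

  # two cells with growth 2:1 are drawn 2/3 : 1/3
  pop2 <- init_population(update_params(p, g_max = 2), 2, g0 = 1)
  pop2$g <- c(2, 1)
  f <- mean(sample_parent(pop2, 1e5) == 1L)
  expect_lt(abs(f - 2 / 3), 3 * sqrt((2 / 9) / 1e5))

  # a single reproducing cell among inert ones is always chosen
  pop3 <- init_population(p, 5, g0 = 0.4)
  pop3$g <- c(0, 0, 0.7, 0, 0)
  expect_true(all(sample_parent(pop3, 1000) == 3L))

  # all-zero growth signals a degenerate population, not uniform sampling
  pop3$g <- rep(0, 5)
  expect_error(sample_parent(pop3), "degenerate")
})

test_that("mutation kernel is unbiased, clamped, and switchable", {
  p <- unit_params()
  set.seed(502)

  expect_equal(mutate_growth(0.5, update_params(p, mutation_scale = 0)), 0.5)

  m <- mutate_growth(rep(0.5, 1e5), p)
  expect_lt(abs(mean(m) - 0.5), 3 * p$mutation_scale / sqrt(1e5))
  expect_lt(abs(stats::sd(m) - p$mutation_scale), 3e-3)

  expect_true(all(mutate_growth(rep(p$g_max, 1e4), p) <= p$g_max))
  expect_true(all(mutate_growth(rep(0, 1e4), p) >= 0))

  # rare mode: ~5% of offspring receive a fixed +/- effect
  pr <- update_params(p, mutation_mode = "rare")
  mr <- mutate_growth(rep(0.5, 1e5), pr)
  hit <- mr != 0.5
  expect_lt(abs(mean(hit) - pr$mutation_prob),
            3 * sqrt(pr$mutation_prob * (1 - pr$mutation_prob) / 1e5))
  expect_true(all(abs(abs(mr[hit] - 0.5) - pr$mutation_effect) < 1e-12))
})

test_that("reproduction attempts kill offspring at their projected-damage rate", {
  set.seed(503)
  # saturating damage at steep Hill: essentially certain death
  p <- unit_params(alpha = 10, delta_t = 0)
  out <- attempt_reproduction(rep(0.5, 1e4), rep(10 * p$K, 1e4), p)
  expect_gte(mean(!out$viable), 0.99)

  # undamaged parent with fully parental damage control: no deaths possible
  out0 <- attempt_reproduction(rep(0.5, 1e4), rep(0, 1e4), p)
  expect_true(all(out0$viable))
  expect_true(all(out0$D == 0))

  # death frequency matches the mutation-averaged Hill mortality
  p2 <- unit_params(alpha = 2, delta_t = 0.5)
  parent_g <- 0.8
  parent_D <- 1.2
  out2 <- attempt_reproduction(rep(parent_g, 1e5), rep(parent_D, 1e5), p2)
  g_mc <- mutate_growth(rep(parent_g, 1e5), p2)
  expected <- mean(mortality_probability(
    projected_damage(rep(parent_D, 1e5), g_mc, p2), p2))
  se <- sqrt(expected * (1 - expected) / 1e5)
  # both sides are 1e5-sample Monte-Carlo estimates: allow 3 s.e. for each
  expect_lt(abs(mean(!out2$viable) - expected), 6 * se)
})

test_that("the generation loop keeps size fixed and counts deaths monotonely", {
  p <- unit_params()
  set.seed(504)
  pop <- init_population(p, 200)
  d_prev <- pop$selective_deaths
  for (i in 1:5) {
    pop <- advance_generation(pop, p)
    expect_length(pop$g, 200)
    expect_length(pop$D, 200)
    expect_gte(pop$selective_deaths, d_prev)
    d_prev <- pop$selective_deaths
  }
  expect_identical(pop$generation, 5L)
})

test_that("neutral resampling limit preserves the trait multiset and kills no one", {
  p <- unit_params(K = Inf, mutation_scale = 0)
  set.seed(505)
  pop <- init_population(p, 100, g0 = 0.5)
  pop$g <- stats::runif(100, 0.2, 0.9)
  pop$D <- equilibrium_damage(pop$g, p)
  nxt <- run_generations(pop, p, 10)
  expect_true(all(nxt$g %in% pop$g))
  expect_identical(nxt$selective_deaths, 0)
})

test_that("compiled generation step agrees with the R-level damage bookkeeping", {
  # mutation off and mortality off makes one generation deterministic in
  # traits: every offspring of a parent with (g, D) carries projected damage
  p <- unit_params(K = Inf, mutation_scale = 0, delta_t = 0.3)
  set.seed(506)
  pop <- init_population(p, 50, g0 = 0.6, D0 = 4)
  nxt <- advance_generation(pop, p)
  expect_equal(unique(nxt$g), 0.6)
  expect_equal(unique(nxt$D), projected_damage(4, 0.6, p), tolerance = 1e-12)
  # iterating relaxes the whole population toward equilibrium damage
  for (i in 1:60) pop <- advance_generation(pop, p)
  expect_equal(unique(pop$D), equilibrium_damage(0.6, p), tolerance = 1e-6)
})

test_that("attempt counts follow the geometric-trials expectation", {
  # constant viability: delta_t = 0 and no mutation make V identical across
  # attempts, so filling N slots takes N/(1-V) attempts in expectation
  p <- unit_params(alpha = 2, delta_t = 0, mutation_scale = 0)
  D0 <- p$K  # V = 0.5 exactly
  set.seed(507)
  att <- replicate(100, {
    pop <- init_population(p, 200, g0 = 0.5, D0 = D0)
    pop <- run_generations(pop, p, 1, record = TRUE)
    attr(pop, "trajectory")$attempts[1]
  })
  expect_lt(abs(mean(att) - 200 / 0.5), 0.1 * (200 / 0.5))
})

test_that("trajectories are bit-identical under a fixed seed", {
  p <- model_params(delta_t = 0.1)
  run_once <- function() {
    set.seed(20240917)
    pop <- init_population(p, 300)
    run_generations(pop, p, 50, record = TRUE)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$g, b$g)
  expect_identical(a$D, b$D)
  expect_identical(attr(a, "trajectory"), attr(b, "trajectory"))
})

test_that("hopeless mortality raises a tagged extinction error", {
  p <- unit_params(K = 1e-6, alpha = 10, delta_t = 10)
  set.seed(508)
  pop <- init_population(p, 50, g0 = 0.5)
  expect_error(
    run_generations(pop, p, 5, max_attempts_per_gen = 500),
    class = "prodigal_extinction")
  err <- tryCatch(
    run_generations(pop, p, 5, max_attempts_per_gen = 500),
    prodigal_extinction = function(e) e)
  expect_identical(err$generation, 1L)

  popz <- init_population(unit_params(), 10, g0 = 0)
  expect_error(run_generations(popz, unit_params(), 1),
               class = "prodigal_degenerate")
})

test_that("ancestral initialisation equilibrates and resets its counters", {
  p <- model_params(delta_t = 0.1)
  set.seed(509)
  pop0 <- init_ancestral_population(p, 40, burn_in = 0, g0 = 0.5)
  expect_length(pop0$g, 40)
  expect_true(all(pop0$g == 0.5))
  expect_equal(unique(pop0$D), equilibrium_damage(0.5, p))

  pop <- init_ancestral_population(p, 1000, burn_in = 1000)
  expect_identical(pop$generation, 0L)
  expect_identical(pop$selective_deaths, 0)
  expect_lt(mean(pop$g), p$g_max)

  # stationarity: consecutive 100-generation windows agree closely
  tr <- attr(run_generations(pop, p, 200, record = TRUE), "trajectory")
  expect_lt(abs(mean(tr$mean_g[101:200]) - mean(tr$mean_g[1:100])), 0.02)
})
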
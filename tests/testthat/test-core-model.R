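test_that("repair rate follows the linear trade-off and its clamps", {
  p <- unit_params()
  expect_equal(repair_rate(0, p), p$R_max)
  expect_equal(repair_rate(p$g_max, p), p$R_min)

  # shallower slope diverts fewer resources from repair: 5 - 0.25*4*0.5 = 4.5
  p_cheap <- unit_params(repair_slope = 0.25)
  expect_equal(repair_rate(0.5 * p_cheap$g_max, p_cheap), 4.5)

  # beyond the physiological reference range repair is pinned at R_min
  p_enr <- update_params(unit_params(), g_max = 2)  # g_ref stays 1
  expect_equal(repair_rate(c(1, 1.5, 2), p_enr), rep(p_enr$R_min, 3))

  gs <- seq(0, 1, length.out = 101)
  r <- repair_rate(gs, p)
  expect_true(all(diff(r) <= 1e-12))
  expect_true(all(r >= p$R_min & r <= p$R_max))
  expect_true(all(r > 0))

  expect_error(repair_rate(-0.1, p), "growth rate")
  expect_error(repair_rate(1.1, p), "growth rate")
})

test_that("damage derivative vanishes at equilibrium and has the right signs", {
  p <- unit_params()
  for (g in c(0, 0.3, 0.7, 1)) {
    expect_equal(damage_derivative(equilibrium_damage(g, p), g, p), 0,
                 tolerance = 1e-12)
  }
  # non-growing damaged cell: pure repair at R_max
  expect_equal(damage_derivative(1, 0, p), -5)
  # undamaged growing cell accrues damage at g * D_max
  expect_equal(damage_derivative(0, 0.6, p), 0.6 * p$D_max)
  expect_error(damage_derivative(-1, 0.5, p), "non-negative")
})

test_that("equilibrium damage matches an independent ODE integration", {
  p <- unit_params()
  expect_equal(equilibrium_damage(0, p), 0)
  expect_equal(equilibrium_damage(1, p), 5)  # D_max * 1 / R_min

  gs <- seq(0, 1, length.out = 201)
  expect_true(all(diff(equilibrium_damage(gs, p)) > 0))

  # oracle: integrate dD/dt = g*D_max - R(g)*D numerically to steady state
  set.seed(401)
  for (i in 1:100) {
    pr <- random_params()
    g <- stats::runif(1, 0, 1)
    D0 <- stats::runif(1, 0, 10)
    R <- repair_rate(g, pr)
    t_end <- 50 / R  # many relaxation times
    sol <- deSolve::ode(
      y = c(D = D0), times = c(0, t_end),
      func = function(t, y, parms) list(g * pr$D_max - R * y[1]),
      rtol = 1e-12, atol = 1e-12)
    expect_equal(unname(sol[2, "D"]), equilibrium_damage(g, pr),
                 tolerance = 1e-8)
  }
})

test_that("projected damage interpolates between parent and equilibrium", {
  p <- unit_params(delta_t = 0.1)

  # relaxation-time limits: fully parental vs fully offspring-determined
  p0 <- update_params(p, delta_t = 0)
  expect_equal(projected_damage(2.7, 0.6, p0), 2.7)
  pinf <- update_params(p, delta_t = 1e6)
  expect_equal(projected_damage(2.7, 0.6, pinf),
               equilibrium_damage(0.6, pinf), tolerance = 1e-12)

  # frozen closed-form value: D_eq = 5, R = 1, so 5 + (2-5) e^{-0.1}
  expect_equal(projected_damage(2, 1, p), 5 - 3 * exp(-0.1))

  # cross-check against numerical integration over the relaxation window
  R <- repair_rate(1, p)
  sol <- deSolve::ode(
    y = c(D = 2), times = c(0, 0.1),
    func = function(t, y, parms) list(1 * p$D_max - R * y[1]),
    rtol = 1e-12, atol = 1e-12)
  expect_equal(projected_damage(2, 1, p), unname(sol[2, "D"]),
               tolerance = 1e-8)

  # convex combination of D_p and D_eq, monotone in delta_t toward D_eq
  set.seed(402)
  for (i in 1:50) {
    pr <- random_params()
    g <- stats::runif(1, 0, 1)
    Dp <- stats::runif(1, 0, 12)
    deq <- equilibrium_damage(g, pr)
    dts <- sort(stats::runif(6, 0, 5))
    vals <- vapply(dts, function(dt) {
      projected_damage(Dp, g, update_params(pr, delta_t = dt))
    }, numeric(1))
    expect_true(all(vals >= min(Dp, deq) - 1e-12))
    expect_true(all(vals <= max(Dp, deq) + 1e-12))
    gaps <- abs(vals - deq)
    expect_true(all(diff(gaps) <= 1e-12))
  }
  expect_error(projected_damage(-0.5, 0.5, p), "non-negative")
})

test_that("Hill mortality is half-maximal at K, monotone, and bounded", {
  for (a in c(0.5, 1, 2, 4, 10, 25)) {
    p <- unit_params(alpha = a)
    expect_equal(mortality_probability(p$K, p), 0.5)
  }
  p <- unit_params(alpha = 2)
  expect_equal(mortality_probability(0, p), 0)
  expect_equal(mortality_probability(2 * p$K, p), 0.8)  # 4K^2/(K^2+4K^2)

  D <- seq(0, 50, length.out = 500)
  V <- mortality_probability(D, p)
  expect_true(all(diff(V) >= 0))
  expect_true(all(V >= 0 & V < 1))

  # neutral limit: infinite tolerance means nothing ever dies
  expect_equal(mortality_probability(c(0, 1, 1e6), unit_params(K = Inf)),
               rep(0, 3))
  # huge damage at large alpha must saturate to 1 without overflow
  expect_equal(mortality_probability(1e30, unit_params(alpha = 25)), 1)
  expect_error(mortality_probability(-1, p), "non-negative")
})

test_that("viable equilibrium growth and its optimum match a grid search", {
  p <- unit_params()
  expect_equal(viable_equilibrium_growth(0, p), 0)

  # at the damage level K exactly half the offspring survive
  g <- 0.5
  pK <- unit_params(K = equilibrium_damage(0.5, unit_params()))
  expect_equal(viable_equilibrium_growth(g, pK), 0.5 * g)

  for (pars in list(unit_params(alpha = 2), unit_params(alpha = 10),
                    model_params(), model_params(g_max = 2, alpha = 4))) {
    pred <- predicted_equilibrium_growth(pars)
    gs <- seq(0, pars$g_max, length.out = 1e5)
    vals <- viable_equilibrium_growth(gs, pars)
    i <- which.max(vals)
    expect_lt(abs(pred$g_opt - gs[i]), 1e-4)
    expect_gte(pred$value, vals[i] - 1e-10)
  }

  # when tolerance is far above any reachable damage the cap is optimal
  p_free <- unit_params(K = 1e6)
  expect_equal(predicted_equilibrium_growth(p_free)$g_opt, p_free$g_max,
               tolerance = 1e-6)
})

test_that("model_params validates its domain", {
  expect_error(model_params(R_min = 0), "R_min")
  expect_error(model_params(R_min = 2, R_max = 1), "R_min")
  expect_error(model_params(repair_slope = 0), "repair_slope")
  expect_error(model_params(repair_slope = 1.5), "repair_slope")
  expect_error(model_params(alpha = -1), "alpha")
  expect_error(model_params(delta_t = -0.1), "delta_t")
  expect_error(model_params(K = 0), "K")
  expect_error(update_params(model_params(), nonsense = 1), "unknown")
  # defaults: trade-off anchored at the environment's own range
  p <- model_params(g_max = 2)
  expect_equal(p$g_ref, 2)
  expect_equal(p$K, p$D_max * p$g_ref / (2 * p$R_min))
})
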
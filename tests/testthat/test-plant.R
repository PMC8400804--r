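test_that("muscle activation follows the exact first-order lag", {
  p <- plant_params()
  # equilibrium at zero drive
  expect_equal(activation_step(0, 0, p, 0.01), 0)
  # one time constant after a step reaches 1 - 1/e of the DC gain
  target <- p$G * 400
  expect_equal(activation_step(0, 400, p, p$tau), (1 - exp(-1)) * target,
               tolerance = 1e-9)
  # DC gain: repeated stepping converges to G * pw
  T_a <- 0
  for (i in 1:4000) T_a <- activation_step(T_a, 400, p, 0.01)
  expect_equal(T_a, target, tolerance = 1e-6)
  # exact discretization is step-size invariant: two half steps = one step
  one <- activation_step(0.1, 300, p, 0.02)
  two <- activation_step(activation_step(0.1, 300, p, 0.01), 300, p, 0.01)
  expect_equal(one, two, tolerance = 1e-12)
})

test_that("the shank stays put at rest and under zero torque", {
  p <- plant_params()
  s <- dynamics_step(plant_state(0, 0, 0), 0, p, 1e-3)
  expect_equal(s$theta, 0)
  expect_equal(s$omega, 0)
})

test_that("constant torque drives the shank to the bisection equilibrium", {
  p <- plant_params()
  for (T_a in c(0.4, 0.9, 1.5)) {
    tr <- plant_simulate(rep(T_a / p$G, 120), p)  # 12 s of constant drive
    th_end <- tr$theta[nrow(tr)]
    expect_equal(th_end, oracle_equilibrium_deg(T_a, p), tolerance = 0.05)
  }
})

test_that("the integrator matches the analytic damped second-order solution", {
  # gravity off, linear spring about 45 deg: the dynamics are exactly the
  # damped oscillator J th'' + B th' + K (th - rest) = 0, so the integrator
  # must track the closed form to integration accuracy.  (A hanging-pendulum
  # variant would swing through the 0-degree hard stop, which clamps.)
  rest_deg <- 45
  p <- plant_params(J = 0.05, mgl = 0, B = 0.03, K = 1.2,
                    rest = rest_deg * pi / 180, G = 0, tau = 0.2)
  th0 <- 2  # degrees of initial deflection from equilibrium
  state <- plant_state(rest_deg + th0, 0, 0)
  dt <- 1e-3
  ts <- seq(dt, 2, by = dt)
  sim <- numeric(length(ts))
  for (i in seq_along(ts)) {
    state <- dynamics_step(state, 0, p, dt)
    sim[i] <- state$theta
  }
  wn <- sqrt(p$K / p$J); zeta <- p$B / (2 * sqrt(p$K * p$J))
  wd <- wn * sqrt(1 - zeta^2)
  ana <- rest_deg + th0 * exp(-zeta * wn * ts) *
    (cos(wd * ts) + zeta * wn / wd * sin(wd * ts))
  expect_lt(max(abs(sim - ana)), 1e-4 * th0)
})

test_that("the plant is passive: released from any state it returns to rest", {
  p <- plant_params()
  for (init in list(plant_state(60, 0, 0), plant_state(20, 50, 0),
                    plant_state(85, -30, 0))) {
    tr <- plant_simulate(rep(0, 120), p, state = init)
    expect_lt(abs(tr$theta[nrow(tr)]), 0.2)
    # mechanical energy decreases while moving
    d2r <- pi / 180
    E <- 0.5 * p$J * (tr$omega * d2r)^2 +
      p$mgl * (1 - cos(tr$theta * d2r)) +
      0.5 * p$K * (tr$theta * d2r - p$rest)^2
    moving <- abs(tr$omega) > 1e-6
    expect_true(all(diff(E)[moving[-1]] < 1e-9))
  }
})

test_that("steady-state angle is non-decreasing in pulse width", {
  p <- plant_params()
  finals <- vapply(seq(0, 500, by = 100), function(pw) {
    tr <- plant_simulate(rep(pw, 100), p)
    tr$theta[nrow(tr)]
  }, numeric(1))
  expect_true(all(diff(finals) >= -1e-9))
  expect_lte(max(finals), 90)
})

test_that("halving the inner step changes a 5 s trajectory by less than 0.01 deg", {
  p <- plant_params()
  pw <- rep(c(380, 420, 380, 360, 380), each = 10)  # 5 s of varying drive
  a <- plant_simulate(pw, p, dt = 1e-3)
  b <- plant_simulate(pw, p, dt = 5e-4)
  at <- a$theta[match(round(b$t, 6), round(a$t, 6), nomatch = 0)]
  bt <- b$theta[round(b$t, 6) %in% round(a$t, 6)]
  expect_lt(max(abs(at - bt)), 0.01)
})

test_that("hard stops clamp the angle and zero the velocity", {
  p <- plant_params()
  tr <- plant_simulate(rep(3000, 60), p)  # far beyond any equilibrium
  expect_lte(max(tr$theta), 90)
  expect_equal(tr$theta[nrow(tr)], 90)
  expect_equal(tr$omega[nrow(tr)], 0)
})
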
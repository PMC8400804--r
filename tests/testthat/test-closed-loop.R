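test_that("step metrics recover closed-form values on synthetic traces", {
  # first-order approach: 10-90% rise time is tau * ln(9)
  t <- seq(0, 12, by = 1e-3)
  ref <- 70
  tr <- data.frame(t = t, theta = ref * (1 - exp(-t)))
  m <- step_metrics(tr, ref)
  expect_equal(m$rise_time_s, log(9), tolerance = 1e-3)
  expect_equal(m$overshoot_deg, 0)
  expect_lt(m$sse_deg, 0.01)
  # settling: last exit from the 2% band of a pure exponential is ln(50)
  expect_equal(m$settling_time_s, log(1 / 0.02), tolerance = 1e-2)

  # underdamped second-order: overshoot is ref * exp(-pi*zeta/sqrt(1-zeta^2))
  zeta <- 0.6; wn <- 2
  wd <- wn * sqrt(1 - zeta^2)
  th <- ref * (1 - exp(-zeta * wn * t) *
                 (cos(wd * t) + zeta / sqrt(1 - zeta^2) * sin(wd * t)))
  m2 <- step_metrics(data.frame(t = t, theta = th), ref)
  expect_equal(m2$overshoot_deg, ref * exp(-pi * zeta / sqrt(1 - zeta^2)),
               tolerance = 0.05)

  # an ideal instantaneous step has all-zero metrics
  m3 <- step_metrics(data.frame(t = t, theta = rep(ref, length(t))), ref)
  expect_equal(m3$rise_time_s, 0)
  expect_equal(m3$settling_time_s, 0)
  expect_equal(m3$overshoot_deg, 0)
  expect_equal(m3$sse_deg, 0)
})

test_that("a never-settling trace is flagged rather than given a time", {
  t <- seq(0, 10, by = 0.01)
  m <- step_metrics(data.frame(t = t, theta = 70 + 10 * sin(3 * t)), 70)
  expect_false(m$settled)
  expect_true(is.na(m$settling_time_s))
})

test_that("with the controller bypassed at zero width the knee never moves", {
  tr <- simulate_closed_loop(70, duration_s = 2, pulse_override = 0)
  expect_true(all(tr$dense$theta == 0))
})

test_that("closed-loop sampling is exact and pulse equals defuzzy x 10", {
  tr <- simulate_closed_loop(40, duration_s = 3)
  s <- tr$samples
  expect_equal(diff(s$t), rep(0.1, nrow(s) - 1))
  expect_equal(s$pulse, s$defuzzy * 10)
  # power-on interval runs at the reset (ME singleton) width
  expect_identical(s$defuzzy[1], 22)
})

test_that("percentage-error comparison reproduces the published rounding", {
  expect_equal(compare_traces(43.8, 43)$per_sample, 1.8)
  expect_equal(compare_traces(12.9, 12)$per_sample, 7.0)
  expect_equal(compare_traces(31.6, 30)$per_sample, 5.1)
  ident <- compare_traces(c(38, 45, 15), c(38, 45, 15))
  expect_equal(ident$per_sample, c(0, 0, 0))
  expect_equal(ident$average, 0)
  # the published 70-degree comparison column and its average
  mat <- c(38, 45, 43.8, 41.2, 40.8, 40.8, 41.9, 31.6, 19, rep(15, 5))
  hdl <- c(38, 45, 43, 41, 40, 40, 41, 30, 18, rep(15, 5))
  expect_equal(compare_traces(mat, hdl)$average, 1.3)
  expect_warning(out <- compare_traces(c(0, 10), c(1, 10)), "excluded")
  expect_true(is.na(out$per_sample[1]))
})
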
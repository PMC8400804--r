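test_that("acquisition takes 235 us at the 75 us converter latency", {
  acq <- run_acquisition_cycle(101)
  expect_identical(acq$duration_us, 235)
  expect_identical(acq$delay_us, 75)
  expect_identical(acq$sample, 101)
})

test_that("testbench mode (interrupt tied low) transits Delay in one cycle", {
  acq <- run_acquisition_cycle(0, interrupt_held_low = TRUE)
  expect_identical(acq$duration_us, 161)
  expect_identical(acq$delay_us, 1)
})

test_that("acquisition duration is 160 us plus the delay-state dwell", {
  for (lat in c(0, 1, 10, 75, 200, 5000)) {
    acq <- run_acquisition_cycle(50, latency_us = lat)
    expect_identical(acq$duration_us, 160 + max(lat, 1))
  }
})

test_that("a stuck converter raises a timeout", {
  expect_error(run_acquisition_cycle(50, latency_us = 2e5),
               "never asserted")
})

test_that("control outputs follow the state table in every traced cycle", {
  acq <- run_acquisition_cycle(50)
  tr <- acq$trace
  expected <- list(SOC = c(0, 0, 1), Delay = c(1, 1, 1),
                   EOC = c(0, 1, 0), Idle = c(1, 1, 1))
  states <- tr[tr$signal == "state", ]
  state_names <- c("Idle", "SOC", "Delay", "EOC")[states$value + 1]
  for (k in seq_len(nrow(states))) {
    at <- states$cycle[k]
    cs <- tr$value[tr$signal == "cs" & tr$cycle == at]
    wr <- tr$value[tr$signal == "wr" & tr$cycle == at]
    rd <- tr$value[tr$signal == "rd" & tr$cycle == at]
    expect_equal(c(cs, wr, rd), expected[[state_names[k]]],
                 info = state_names[k])
  }
  # the sample strobe fires exactly once, at EOC exit
  strobe <- tr[tr$signal == "sample_data_ADC", ]
  expect_identical(nrow(strobe), 1L)
  expect_identical(strobe$cycle, 235)
})

test_that("error conversion always takes exactly three cycles", {
  cases <- list(c(70, 4, 70), c(40, 40, 0), c(30, 90, -20), c(70, 0, 0))
  for (cs in cases) {
    conv <- run_error_conversion(cs[1], cs[2], cs[3])
    expect_identical(conv$cycles, 3L)
  }
  conv <- run_error_conversion(70, 4, 70)
  expect_identical(conv$err_cur, 66)
  expect_identical(conv$derr_cur, -4)
  expect_identical(conv$result$defuzzy, 43)
  # outputs become valid on the Store tick, 3 us after the strobe
  expect_identical(conv$trace$cycle[conv$trace$signal == "defuzzy_out"], 3)
})

test_that("pwm pulses have the commanded width at the commanded period", {
  ev <- generate_pwm(240, pwm_config(50), horizon_us = 60000)
  rises <- ev$cycle[ev$value == 1]
  falls <- ev$cycle[ev$value == 0]
  expect_equal(rises, c(0, 20000, 40000))
  expect_equal(falls - rises, rep(240, 3))
  # defuzzy extremes 10 and 50 map to the 100-500 us range
  ev <- generate_pwm(100, pwm_config(50), 20000)
  expect_equal(ev$cycle[ev$value == 0] - ev$cycle[ev$value == 1], 100)
  ev <- generate_pwm(500, pwm_config(20), 50000)
  expect_equal(ev$cycle[ev$value == 0] - ev$cycle[ev$value == 1], 500)
  expect_warning(generate_pwm(600, pwm_config(50), 20000), "clamped")
  expect_error(generate_pwm(21000, pwm_config(50), 40000), "shorter")
})

test_that("the full controller trace is periodic and causally ordered", {
  sw <- generate_ramp_sweep(0.9, 0.6)
  sim <- ffc_simulate(sw, horizon_us = 1200000, ref = 70, freq = 50)
  s <- sim$samples
  expect_equal(diff(s$trigger_us), rep(100000, nrow(s) - 1))
  expect_true(all(s$acq_duration_us == 235))
  # pulse register updates acquisition + 3 us after each trigger
  expect_equal(s$pulse_valid_us - s$trigger_us, rep(238, nrow(s)))
  # trace stamps non-decreasing
  expect_true(!is.unsorted(sim$trace$cycle))
  # a saturated sweep ends at the VS singleton
  expect_identical(s$defuzzy[nrow(s)], 15)
})
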
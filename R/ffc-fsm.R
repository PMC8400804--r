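# Cycle-level simulation of the controller's state machines at a 1 us tick
# (the 1 MHz clock derived from the board's 50 MHz master; the divider is
# abstracted away since nothing the simulator reports resolves below 1 us).

SAMPLE_PERIOD_US <- 100000L  # acquisition trigger every 100 ms

# control outputs (cs, wr, rd) per acquisition FSM state
ADC_FSM_OUTPUTS <- list(
  Idle  = c(cs = 1, wr = 1, rd = 1),
  SOC   = c(cs = 0, wr = 0, rd = 1),
  Delay = c(cs = 1, wr = 1, rd = 1),
  EOC   = c(cs = 0, wr = 1, rd = 0)
)

new_trace <- function() {
  ev <- new.env(parent = emptyenv())
  ev$cycle <- numeric(0); ev$signal <- character(0); ev$value <- numeric(0)
  ev
}

trace_add <- function(tr, cycle, signal, value) {
  tr$cycle <- c(tr$cycle, cycle)
  tr$signal <- c(tr$signal, signal)
  tr$value <- c(tr$value, value)
}

trace_df <- function(tr) {
  data.frame(cycle = tr$cycle, signal = tr$signal, value = tr$value,
             stringsAsFactors = FALSE)
}

#' Simulate one ADC data-acquisition FSM cycle
#'
#' Runs the four-state acquisition handshake at 1 us ticks:
#' Idle -> SOC (80 us, cs/wr low) -> Delay (until the converter's interrupt
#' line goes low) -> EOC (80 us, cs/rd low, data sampled) -> Idle, with the
#' `sample_data_ADC` strobe pulsed on EOC exit.  The modelled converter
#' pulls interrupt low exactly `latency_us` after SOC completes; in
#' testbench mode (`interrupt_held_low = TRUE`) the line is low throughout
#' and the Delay state is a single-cycle transit.
#'
#' @param code 8-bit conversion result the device returns (0..255).
#' @param latency_us device conversion latency in microseconds (default 75,
#'   the hardware figure).
#' @param interrupt_held_low if TRUE, emulate the testbench where the
#'   interrupt line is tied low.
#' @param start_cycle tick at which the trigger is seen (trace stamps only).
#' @param timeout_us abort if the interrupt never falls within this horizon
#'   (default one sampling period).
#' @return list with `sample` (latched code), `duration_us` (SOC entry to
#'   EOC exit), `delay_us` (ticks spent in the Delay state) and `trace`
#'   (data.frame of signal-change events).
#' @examples
#' run_acquisition_cycle(101)$duration_us                             # 235
#' run_acquisition_cycle(101, interrupt_held_low = TRUE)$duration_us  # 161
#' @export
run_acquisition_cycle <- function(code, latency_us = 75,
                                  interrupt_held_low = FALSE,
                                  start_cycle = 0,
                                  timeout_us = SAMPLE_PERIOD_US) {
  stopifnot(code >= 0, code <= 255, latency_us >= 0)
  tr <- new_trace()
  t <- start_cycle
  set_state <- function(state) {
    out <- ADC_FSM_OUTPUTS[[state]]
    trace_add(tr, t, "state", match(state, names(ADC_FSM_OUTPUTS)) - 1)
    for (s in names(out)) trace_add(tr, t, s, out[[s]])
  }
  # SOC: 80 ticks
  set_state("SOC")
  t <- t + 80
  soc_done <- t
  # Delay: one tick per poll of the interrupt line; leave on the tick the
  # line reads low (a pre-asserted line gives a single-cycle transit)
  set_state("Delay")
  delay <- 0
  repeat {
    delay <- delay + 1
    t <- t + 1
    interrupt_low <- interrupt_held_low || (t - soc_done) >= latency_us
    if (interrupt_low) break
    if (delay > timeout_us) {
      stop("ADC interrupt never asserted within one sampling period")
    }
  }
  trace_add(tr, t, "interrupt", 0)
  # EOC: 80 ticks, data latched and strobe pulsed on exit
  set_state("EOC")
  t <- t + 80
  trace_add(tr, t, "sample_data_ADC", 1)
  trace_add(tr, t, "acq_ADC", code)
  set_state("Idle")
  list(sample = code, duration_us = t - start_cycle, delay_us = delay,
       trace = trace_df(tr))
}

#' Simulate the three-state fuzzy error-conversion FSM
#'
#' After the `sample_data_ADC` strobe the datapath takes exactly three
#' 1 us ticks: Sample latches the reference and actual angle, Calculate
#' forms the error, Store forms the change in error and updates the
#' previous-error register.  The fuzzification/inference/defuzzification
#' stages are combinational, so the defuzzy and pulse outputs are valid at
#' the Store tick.
#'
#' @param ref reference angle in degrees.
#' @param act_deg actual angle in integer degrees (from
#'   [adc_counts_to_degrees()]).
#' @param prev_err previous raw error register.
#' @param config an [flc_config()].
#' @param start_cycle tick of the strobe (trace stamps only).
#' @return list with `err_cur`, `derr_cur`, `cycles` (always 3), `result`
#'   (the [flc_step()] `defuzzy_result`), `prev_err` and `trace`.
#' @export
run_error_conversion <- function(ref, act_deg, prev_err = 0,
                                 config = flc_config(), start_cycle = 0) {
  tr <- new_trace()
  t <- start_cycle
  trace_add(tr, t + 1, "ref_cur", ref)       # Sample
  trace_add(tr, t + 1, "act_cur", act_deg)
  st <- flc_step(ref, act_deg, prev_err, config)
  trace_add(tr, t + 2, "err_cur", st$result$err)    # Calculate
  trace_add(tr, t + 3, "derr_cur", st$result$derr)  # Store
  trace_add(tr, t + 3, "defuzzy_out", st$result$defuzzy)
  trace_add(tr, t + 3, "pulse_out", st$result$pulse)
  list(err_cur = st$result$err, derr_cur = st$result$derr, cycles = 3L,
       result = st$result, prev_err = st$prev_err, trace = trace_df(tr))
}

#' Stimulus pulse-width generation settings
#'
#' @param frequency stimulation frequency in Hz (20, 30, 40 or 50).
#' @return list with `frequency` and the period in microseconds.
#' @export
pwm_config <- function(frequency = 50) {
  stopifnot(frequency %in% c(20, 30, 40, 50))
  list(frequency = frequency, period_us = 1e6 / frequency)
}

#' Generate the periodic stimulus pulse train
#'
#' Emits a high pulse of width `pulse_us` at every period of the configured
#' stimulation frequency over the horizon.  Commanded widths outside the
#' physiological 100..500 us range are clamped with a warning; a width at
#' or beyond the period is an error.
#'
#' @param pulse_us commanded pulse width in microseconds (defuzzy x 10).
#' @param cfg a [pwm_config()].
#' @param horizon_us simulation horizon in microseconds.
#' @return data.frame of `pwm_out` transition events (cycle, signal, value).
#' @examples
#' ev <- generate_pwm(240, pwm_config(50), 40000)
#' # high for 240 us at t = 0 and t = 20000
#' @export
generate_pwm <- function(pulse_us, cfg = pwm_config(), horizon_us) {
  stopifnot(horizon_us > 0)
  if (pulse_us >= cfg$period_us) {
    stop("pulse width must be shorter than the stimulation period")
  }
  if (pulse_us < 100 || pulse_us > 500) {
    warning("pulse width clamped to the 100-500 us stimulation range")
    pulse_us <- min(max(pulse_us, 100), 500)
  }
  starts <- seq(0, horizon_us - 1, by = cfg$period_us)
  tr <- new_trace()
  for (s in starts) {
    trace_add(tr, s, "pwm_out", 1)
    if (s + pulse_us <= horizon_us) trace_add(tr, s + pulse_us, "pwm_out", 0)
  }
  trace_df(tr)
}

#' Cycle-level open-loop simulation of the whole feedback controller
#'
#' Ties the pieces together at the 1 us tick: an acquisition is triggered
#' every 100 ms (the first one 100 ms after reset), the emulated converter
#' digitizes the supplied angle signal, the three-cycle error-conversion
#' datapath updates the defuzzy/pulse registers, and the PWM stage emits
#' pulses at the selected stimulation frequency, latching a new width only
#' at a period boundary (never mid-pulse).
#'
#' @param angle_fn function of time in seconds returning the emulated knee
#'   angle in degrees (e.g. built from [generate_ramp_sweep()]), or a
#'   `sweep_fixture`.
#' @param horizon_us simulation horizon in microseconds.
#' @param ref reference angle in degrees (70, 40 or 30).
#' @param freq stimulation frequency in Hz.
#' @param latency_us ADC conversion latency in microseconds.
#' @param interrupt_held_low testbench mode (see [run_acquisition_cycle()]).
#' @param config an [flc_config()].
#' @return list with `samples` (data.frame: trigger time, ADC code, degrees,
#'   err, derr, defuzzy, pulse, acquisition duration and the tick at which
#'   the pulse register updated), `pwm` (pulse-train events) and `trace`
#'   (all signal events, stamps non-decreasing).
#' @export
ffc_simulate <- function(angle_fn, horizon_us = 1500000, ref = 70,
                         freq = 50, latency_us = 75,
                         interrupt_held_low = FALSE,
                         config = flc_config()) {
  if (inherits(angle_fn, "sweep_fixture")) angle_fn <- sweep_angle_fn(angle_fn)
  stopifnot(is.function(angle_fn))
  cfg <- pwm_config(freq)
  triggers <- seq(SAMPLE_PERIOD_US, horizon_us, by = SAMPLE_PERIOD_US)
  prev_err <- 0
  rows <- vector("list", length(triggers))
  events <- list()
  # reset-state registers: pulse register starts at the reset defuzzy value
  reset <- defuzzify(
    infer_rules(fuzzify(scale_to_digital(0), config$membership),
                fuzzify(scale_to_digital(0), config$membership)),
    select_singletons(config, ref), config$pulse_multiplier, config$rules)
  pulse_updates <- data.frame(cycle = 0, pulse = reset$pulse)
  for (i in seq_along(triggers)) {
    t0 <- triggers[i]
    code <- angle_to_adc(angle_fn(t0 / 1e6))
    acq <- run_acquisition_cycle(code, latency_us, interrupt_held_low,
                                 start_cycle = t0)
    deg <- adc_counts_to_degrees(code)
    conv <- run_error_conversion(ref, deg, prev_err, config,
                                 start_cycle = t0 + acq$duration_us)
    prev_err <- conv$prev_err
    t_valid <- t0 + acq$duration_us + conv$cycles
    pulse_updates <- rbind(pulse_updates,
                           data.frame(cycle = t_valid,
                                      pulse = conv$result$pulse))
    rows[[i]] <- data.frame(
      trigger_us = t0, code = code, act_deg = deg,
      err = conv$err_cur, derr = conv$derr_cur,
      defuzzy = conv$result$defuzzy, pulse = conv$result$pulse,
      acq_duration_us = acq$duration_us, pulse_valid_us = t_valid)
    events[[length(events) + 1]] <- acq$trace
    events[[length(events) + 1]] <- conv$trace
  }
  # PWM: width latched at each period boundary from the pulse register
  pwm <- new_trace()
  for (s in seq(0, horizon_us - 1, by = cfg$period_us)) {
    w <- pulse_updates$pulse[max(which(pulse_updates$cycle <= s))]
    w <- min(max(w, 100), 500)
    trace_add(pwm, s, "pwm_out", 1)
    if (s + w <= horizon_us) trace_add(pwm, s + w, "pwm_out", 0)
  }
  trace <- do.call(rbind, c(events, list(trace_df(pwm))))
  trace <- trace[order(trace$cycle), ]
  rownames(trace) <- NULL
  list(samples = do.call(rbind, rows), pwm = trace_df(pwm), trace = trace)
}
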
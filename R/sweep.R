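#' Synthetic potentiometer ramp sweep
#'
#' Emulates the bench fixture used to exercise the controller open loop: a
#' rotary angle sensor swept linearly from 0 to 90 degrees and then held at
#' the top of its range, sampled at the 100 ms acquisition period.  This
#' stands in for the recorded sweep a knee would produce on the bench; it
#' is a synthetic input, not a measured one.
#'
#' @param ramp_duration_s time to sweep 0 -> 90 degrees (> 0).
#' @param hold_s hold time at 90 degrees after the ramp (> 0).
#' @param sample_period_s sampling spacing (default 0.1 s).
#' @param noise_sd optional Gaussian sensor noise in degrees (default 0,
#'   i.e. the noise-free bench condition); requires `seed`.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return an object of class `sweep_fixture`: data.frame with columns `t`
#'   (s) and `angle` (degrees in 0..90, non-decreasing when noise-free).
#' @examples
#' sw <- generate_ramp_sweep(0.9, 0.5)
#' sw$angle[1:10] # 0, 10, 20, ..., 90
#' @export
generate_ramp_sweep <- function(ramp_duration_s, hold_s,
                                sample_period_s = 0.1,
                                noise_sd = 0, seed = NULL) {
  stopifnot(ramp_duration_s > 0, hold_s > 0, sample_period_s > 0)
  t <- seq(0, ramp_duration_s + hold_s, by = sample_period_s)
  angle <- pmin(t / ramp_duration_s, 1) * 90
  if (noise_sd > 0) {
    if (is.null(seed)) stop("sensor noise requires an explicit seed")
    set.seed(seed)
    angle <- pmin(pmax(angle + stats::rnorm(length(angle), 0, noise_sd), 0), 90)
  }
  structure(data.frame(t = t, angle = angle),
            class = c("sweep_fixture", "data.frame"))
}

# piecewise-linear interpolator over a sweep fixture (constant beyond ends)
sweep_angle_fn <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_fixture"))
  function(t_s) {
    stats::approx(sweep$t, sweep$angle, xout = t_s, rule = 2)$y
  }
}

#' Write a trace table to CSV
#'
#' Plain CSV with a header row; integer columns survive the round trip
#' bit-exactly, doubles to full precision (15 significant digits).
#'
#' @param trace data.frame (e.g. `samples` from [simulate_closed_loop()] or
#'   an event trace from [ffc_simulate()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  out <- trace
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace table written by [write_trace()]
#'
#' @param path CSV file.
#' @return data.frame with numeric columns where possible.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot open trace file '%s'", path))
  tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("malformed trace file '%s': %s",
                                     path, conditionMessage(e))))
}

#' Top-level run configuration
#'
#' Bundles the dip-switch settings, controller configuration, plant
#' parameters and simulation settings; defaults reproduce the shipped
#' constants (membership/rule/singleton tables, 50 Hz stimulation, 100 ms
#' sampling, 75 us converter latency, noise-free sensing).
#'
#' @param ref_set 2-bit reference-angle code (see [decode_ref_setting()]).
#' @param freq_sel 2-bit frequency code (see [decode_freq_setting()]).
#' @param flc an [flc_config()].
#' @param plant a [plant_params()].
#' @param duration_s simulation horizon in seconds.
#' @param latency_us ADC conversion latency in microseconds.
#' @param noise_sd sensor noise standard deviation in degrees.
#' @param seed RNG seed for the sensor noise.
#' @return an object of class `run_config`.
#' @export
run_config <- function(ref_set = 0, freq_sel = 3, flc = flc_config(),
                       plant = plant_params(), duration_s = 8,
                       latency_us = 75, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(flc, "flc_config"), inherits(plant, "plant_params"),
            duration_s > 0, latency_us >= 0, noise_sd >= 0)
  structure(list(ref_set = decode_2bit(ref_set),
                 freq_sel = decode_2bit(freq_sel),
                 ref = decode_ref_setting(ref_set),
                 freq = decode_freq_setting(freq_sel),
                 flc = flc, plant = plant, duration_s = duration_s,
                 latency_us = latency_us, noise_sd = noise_sd, seed = seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "run config: ref %g deg (code %d), %g Hz (code %d), %g s, latency %g us\n",
    x$ref, x$ref_set, x$freq, x$freq_sel, x$duration_s, x$latency_us))
  invisible(x)
}

#' Write a run configuration to YAML
#'
#' @param config a [run_config()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_flc_config(config$flc, tmp)
  obj <- list(ref_set = config$ref_set, freq_sel = config$freq_sel,
              flc = yaml::read_yaml(tmp),
              plant = unclass(config$plant),
              duration_s = config$duration_s,
              latency_us = config$latency_us,
              noise_sd = config$noise_sd, seed = config$seed)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path file written by [write_run_config()].
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(obj$flc, tmp, precision = 15)
  run_config(ref_set = obj$ref_set, freq_sel = obj$freq_sel,
             flc = read_flc_config(tmp),
             plant = do.call(plant_params, obj$plant),
             duration_s = obj$duration_s, latency_us = obj$latency_us,
             noise_sd = obj$noise_sd, seed = obj$seed)
}
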
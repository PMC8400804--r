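#' Closed-loop simulation of controller and plant
#'
#' Couples the fuzzy controller (integer datapath or floating-point
#' reference pipeline) to the knee-extension plant at 100 ms sampling.
#' At each sample instant the knee angle is read back (through the 8-bit
#' ADC quantization in integer mode, directly in float mode), one
#' controller step produces a new pulse width, and that width is held on
#' the plant until the next sample.  Over the first sampling interval the
#' plant sees the power-on (reset) output of the controller, i.e. the ME
#' singleton times the pulse multiplier.
#'
#' @param ref reference angle in degrees (70, 40 or 30 by default config).
#' @param duration_s simulated time in seconds, >= 1.
#' @param mode `"integer"` (bit-exact datapath) or `"float"` (continuous
#'   reference pipeline).
#' @param config an [flc_config()].
#' @param params a [plant_params()].
#' @param dt inner plant integration step in seconds.
#' @param pulse_override optional fixed pulse width in microseconds that
#'   bypasses the controller (e.g. 0 to verify the plant stays at rest).
#' @return an object of class `closed_loop_trace`: list with `samples`
#'   (data.frame at controller instants: `t`, `theta_ref`, `theta_act`,
#'   `err`, `derr`, `defuzzy`, `pulse`), `dense` (the full plant
#'   trajectory) and the run settings.
#' @export
simulate_closed_loop <- function(ref, duration_s = 8,
                                 mode = c("integer", "float"),
                                 config = flc_config(),
                                 params = plant_params(),
                                 dt = 1e-3, pulse_override = NULL) {
  mode <- match.arg(mode)
  stopifnot(duration_s >= 1)
  sample_period <- 0.1
  n <- round(duration_s / sample_period)
  table <- select_singletons(config, ref)  # validates the reference angle

  state <- plant_state()
  prev_err <- 0
  reset <- defuzzify(
    infer_rules(fuzzify(scale_to_digital(0), config$membership),
                fuzzify(scale_to_digital(0), config$membership)),
    table, config$pulse_multiplier, config$rules)
  pulse <- if (is.null(pulse_override)) reset$pulse else pulse_override

  samp <- data.frame(t = numeric(n + 1), theta_ref = ref,
                     theta_act = numeric(n + 1), err = numeric(n + 1),
                     derr = numeric(n + 1), defuzzy = numeric(n + 1),
                     pulse = numeric(n + 1))
  samp[1, c("theta_act", "err", "derr")] <- c(0, 0, 0)
  samp$defuzzy[1] <- if (is.null(pulse_override)) reset$defuzzy else NA
  samp$pulse[1] <- pulse
  dense <- vector("list", n)

  for (k in seq_len(n)) {
    seg <- plant_simulate(pulse, params, state,
                          sample_period_s = sample_period, dt = dt)
    m <- nrow(seg)
    state <- plant_state(seg$theta[m], seg$omega[m], seg$torque[m])
    seg$t <- seg$t + (k - 1) * sample_period
    dense[[k]] <- if (k == 1) seg else seg[-1, ]

    t_k <- k * sample_period
    if (mode == "integer") {
      act <- adc_counts_to_degrees(angle_to_adc(state$theta))
    } else {
      act <- state$theta
    }
    if (is.null(pulse_override)) {
      if (mode == "integer") {
        st <- flc_step(ref, act, prev_err, config)
        out <- list(defuzzy = st$result$defuzzy, pulse = st$result$pulse,
                    err = st$result$err, derr = st$result$derr)
        prev_err <- st$prev_err
      } else {
        st <- flc_step_float(ref, act, prev_err, config)
        out <- list(defuzzy = st$defuzzy, pulse = st$pulse,
                    err = st$err, derr = st$derr)
        prev_err <- st$prev_err
      }
      pulse <- out$pulse
    } else {
      out <- list(defuzzy = NA, pulse = pulse, err = ref - act,
                  derr = NA)
    }
    samp[k + 1, ] <- data.frame(t = t_k, theta_ref = ref, theta_act = act,
                                err = out$err, derr = out$derr,
                                defuzzy = out$defuzzy, pulse = out$pulse)
  }
  dense <- do.call(rbind, dense)
  rownames(dense) <- NULL
  structure(list(samples = samp, dense = dense, ref = ref, mode = mode,
                 duration_s = duration_s),
            class = "closed_loop_trace")
}

#' @export
print.closed_loop_trace <- function(x, ...) {
  cat(sprintf("closed-loop trace: ref %g deg, %s mode, %g s (%d samples)\n",
              x$ref, x$mode, x$duration_s, nrow(x$samples)))
  cat(sprintf("  final angle %.2f deg, final pulse %g us\n",
              x$dense$theta[nrow(x$dense)],
              x$samples$pulse[nrow(x$samples)]))
  invisible(x)
}

#' Step-response metrics of a closed-loop trajectory
#'
#' Computed on the dense plant trajectory: rise time is the time from the
#' first crossing of 10 percent to the first crossing of 90 percent of the
#' reference (crossings linearly interpolated); settling time is the last
#' entry into the +/-2 percent band about the reference; overshoot is
#' `max(theta) - ref` floored at zero; steady-state error is the absolute
#' difference between the reference and the mean angle over the final
#' second.
#'
#' @param trace a `closed_loop_trace`, or any data.frame with columns `t`
#'   and `theta`.
#' @param ref reference angle in degrees (taken from the trace if omitted).
#' @param band settling band as a fraction of the reference (default 0.02).
#' @return an object of class `step_metrics`: list with `rise_time_s`,
#'   `settling_time_s`, `overshoot_deg`, `sse_deg` and `settled`.  If the
#'   final 20 percent of the trajectory is not within the band the result
#'   is flagged `settled = FALSE` and the times are `NA`.
#' @export
step_metrics <- function(trace, ref = NULL, band = 0.02) {
  if (inherits(trace, "closed_loop_trace")) {
    if (is.null(ref)) ref <- trace$ref
    trace <- trace$dense
  }
  stopifnot(!is.null(ref), all(c("t", "theta") %in% names(trace)))
  t <- trace$t; th <- trace$theta

  cross_up <- function(level) {
    i <- which(th >= level)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(t[1])
    # linear interpolation of the crossing instant
    t[i - 1] + (level - th[i - 1]) / (th[i] - th[i - 1]) * (t[i] - t[i - 1])
  }
  t10 <- cross_up(0.1 * ref)
  t90 <- cross_up(0.9 * ref)
  rise <- if (is.na(t10) || is.na(t90)) NA_real_ else t90 - t10

  tol <- band * ref
  outside <- abs(th - ref) > tol
  tail_idx <- which(t >= t[length(t)] - 0.2 * (t[length(t)] - t[1]))
  settled <- !any(outside[tail_idx])
  settle <- if (!settled) NA_real_
            else if (!any(outside)) t[1]
            else t[max(which(outside)) + 1]

  overshoot <- max(max(th) - ref, 0)
  final <- th[t >= t[length(t)] - 1]
  sse <- abs(ref - mean(final))
  structure(list(rise_time_s = rise, settling_time_s = settle,
                 overshoot_deg = overshoot, sse_deg = sse,
                 settled = settled, ref = ref, band = band),
            class = "step_metrics")
}

#' @export
print.step_metrics <- function(x, ...) {
  if (!x$settled) {
    cat(sprintf("step response (ref %g deg): NOT settled within +/-%g%%\n",
                x$ref, 100 * x$band))
  } else {
    cat(sprintf(
      "step response (ref %g deg): rise %.2f s, settling(%g%%) %.2f s, overshoot %.2f deg, sse %.2f deg\n",
      x$ref, x$rise_time_s, 100 * x$band, x$settling_time_s,
      x$overshoot_deg, x$sse_deg))
  }
  invisible(x)
}

#' Per-sample percentage error between two output sequences
#'
#' For each sample, `e_i = |ref_i - test_i| / ref_i * 100`, rounded to one
#' decimal place; the average of the rounded per-sample errors is also
#' rounded to one decimal.  Samples with a zero reference value are
#' excluded with a warning.
#'
#' @param reference_vals numeric vector of reference outputs (e.g. the
#'   floating-point pipeline).
#' @param test_vals numeric vector of the same length (e.g. the integer
#'   datapath).
#' @return list with `per_sample` (rounded percentages, `NA` where
#'   excluded) and `average`.
#' @examples
#' compare_traces(c(43.8, 15), c(43, 15)) # 1.8, 0.0; average 0.9
#' @export
compare_traces <- function(reference_vals, test_vals) {
  stopifnot(length(reference_vals) == length(test_vals))
  ok <- reference_vals != 0
  if (!all(ok)) {
    warning(sprintf("%d sample(s) with zero reference value excluded",
                    sum(!ok)))
  }
  per <- rep(NA_real_, length(reference_vals))
  per[ok] <- round(abs(reference_vals[ok] - test_vals[ok]) /
                     reference_vals[ok] * 100, 1)
  list(per_sample = per, average = round(mean(per[ok]), 1))
}
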
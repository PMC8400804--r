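#' One integer controller evaluation
#'
#' Runs the full integer datapath for one controller sample: the error is
#' `ref - act` (degrees), the change in error is the raw error minus the
#' previous raw error, both are clamped and scaled onto 0..255, fuzzified,
#' pushed through the 25-rule min-inference base and defuzzified with the
#' singleton table selected by the reference angle.
#'
#' The previous-error register holds the raw, unclamped error: clamping to
#' the +/-20 degree domain happens only inside the scaling step.  At
#' power-on both registers are zero, so the first registered output equals
#' the ME singleton of the selected table.
#'
#' @param ref reference angle in degrees; must have a singleton table in
#'   `config` (70, 40 or 30 by default).
#' @param act actual knee angle in integer degrees, 0..90.
#' @param prev_err previous raw error register (degrees); 0 at power-on.
#' @param config an [flc_config()].
#' @return list with `result` (a [defuzzify()] `defuzzy_result` with the
#'   intermediate `err` and `derr` added as fields) and `prev_err` (the new
#'   register value, i.e. the raw current error).
#' @examples
#' step <- flc_step(70, 4, prev_err = 70)
#' step$result$defuzzy # 43
#' step$result$pulse   # 430
#' @export
flc_step <- function(ref, act, prev_err = 0, config = flc_config()) {
  stopifnot(inherits(config, "flc_config"), act >= 0, act <= 90)
  table <- select_singletons(config, ref)
  err <- ref - act
  derr <- err - prev_err
  e <- fuzzify(scale_to_digital(err, config$clamp), config$membership)
  de <- fuzzify(scale_to_digital(derr, config$clamp), config$membership)
  res <- defuzzify(infer_rules(e, de), table,
                   pulse_multiplier = config$pulse_multiplier,
                   rules = config$rules)
  res$err <- err
  res$derr <- derr
  list(result = res, prev_err = err)
}

#' One floating-point reference controller evaluation
#'
#' Identical pipeline to [flc_step()] computed in real arithmetic directly
#' on the -20..20 degree domain: no 8-bit quantization, no floors.  The
#' membership set is the same five triangles mapped back to degrees
#' (NB(-20,-20,-10) ... PB(10,20,20)) with unit height.  Serves as the
#' continuous oracle the integer datapath is checked against; with the
#' default tables the two agree within 2 defuzzy units everywhere.
#'
#' @param ref reference angle in degrees (70, 40 or 30 by default config).
#' @param act actual knee angle in degrees (real-valued allowed).
#' @param prev_err previous raw error register (degrees).
#' @param config an [flc_config()]; only the clamp, rule grid and singleton
#'   tables are used (the float pipeline has its own degree-domain
#'   triangles).
#' @return list with `defuzzy` (real), `pulse` (real, microseconds),
#'   `err`, `derr`, and `prev_err` (new register value).
#' @export
flc_step_float <- function(ref, act, prev_err = 0, config = flc_config()) {
  stopifnot(inherits(config, "flc_config"))
  table <- select_singletons(config, ref)
  err <- ref - act
  derr <- err - prev_err
  cl <- function(x) min(max(x, -config$clamp), config$clamp)
  e <- fuzzify_float(cl(err))
  de <- fuzzify_float(cl(derr))
  defuzzy <- defuzzify_float(infer_rules(e, de), table, config$rules)
  list(defuzzy = defuzzy, pulse = defuzzy * config$pulse_multiplier,
       err = err, derr = derr, prev_err = err)
}

#' Run the integer controller over a sequence of sampled angles
#'
#' Open-loop convenience wrapper: starting from the power-on registers
#' (previous error 0), feeds each sampled actual angle through
#' [flc_step()] in turn.  Row `t = 0` of the result is the reset output
#' (both error registers zero) that the datapath presents before the first
#' sample is acquired.
#'
#' @param ref reference angle in degrees.
#' @param angles integer vector of sampled actual angles (degrees, 0..90).
#' @param config an [flc_config()].
#' @param sample_period_s spacing of the samples in seconds (default 0.1).
#' @return data.frame with columns `t`, `act`, `err`, `derr`, `defuzzy`,
#'   `pulse`; first row is the reset state.
#' @export
flc_run_sequence <- function(ref, angles, config = flc_config(),
                             sample_period_s = 0.1) {
  table <- select_singletons(config, ref)
  reset <- defuzzify(infer_rules(fuzzify(scale_to_digital(0), config$membership),
                                 fuzzify(scale_to_digital(0), config$membership)),
                     table, config$pulse_multiplier, config$rules)
  n <- length(angles)
  out <- data.frame(t = seq(0, by = sample_period_s, length.out = n + 1),
                    act = c(NA, angles), err = c(0, numeric(n)),
                    derr = c(0, numeric(n)),
                    defuzzy = c(reset$defuzzy, numeric(n)),
                    pulse = c(reset$pulse, numeric(n)))
  prev <- 0
  for (i in seq_len(n)) {
    st <- flc_step(ref, angles[i], prev, config)
    out$err[i + 1] <- st$result$err
    out$derr[i + 1] <- st$result$derr
    out$defuzzy[i + 1] <- st$result$defuzzy
    out$pulse[i + 1] <- st$result$pulse
    prev <- st$prev_err
  }
  out
}
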
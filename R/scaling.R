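#' Clamp-then-scale a crisp input onto the 8-bit fuzzy domain
#'
#' Crisp error inputs (error and change-in-error, in degrees) live on the
#' -20..20 degree fuzzy domain.  For the digital datapath they are first
#' clamped to that domain and then mapped onto the 8-bit scale 0..255 by
#' `floor(((x + 20) * 255) / 40)`, so -20 -> 0, 0 -> 127 and 20 -> 255.
#'
#' The clamp happens before the scaling, never after: the previous-error
#' register upstream stores the raw (unclamped) error, so inputs far outside
#' the domain are legal here and simply saturate.
#'
#' @param x integer crisp input (degrees); any signed value.
#' @param clamp positive clamp bound in degrees (default 20).
#' @return integer in 0..255.
#' @examples
#' scale_to_digital(-20) # 0
#' scale_to_digital(0)   # 127
#' scale_to_digital(66)  # clamps to 20 first -> 255
#' @export
scale_to_digital <- function(x, clamp = 20) {
  stopifnot(is.numeric(x), length(x) >= 1, clamp > 0)
  x <- pmin(pmax(x, -clamp), clamp)
  ((x + 20) * 255) %/% 40
}

#' Convert a knee angle in degrees to an 8-bit ADC code
#'
#' The feedback sensor maps 0..90 degrees onto codes 0..255; angles outside
#' the sensor range are clamped.
#'
#' @param theta angle in degrees.
#' @return integer code in 0..255.
#' @export
angle_to_adc <- function(theta) {
  theta <- pmin(pmax(theta, 0), 90)
  floor(theta * 255 / 90)
}

#' Convert an 8-bit ADC code to an integer knee angle in degrees
#'
#' Integer (floor) division mirrors the hardware conversion
#' `act_deg = (act_ADC * 90) / 255`, e.g. code 101 -> 35 deg and
#' code 113 -> 39 deg.
#'
#' @param code integer ADC code in 0..255.
#' @return integer angle in 0..90 degrees.
#' @export
adc_counts_to_degrees <- function(code) {
  stopifnot(all(code >= 0), all(code <= 255))
  (code * 90) %/% 255
}

#' Decode the 2-bit reference-angle dip-switch setting
#'
#' Codes 0..3 ("00".."11") select the reference angle: 0 -> 70, 1 -> 40,
#' 2 -> 30; the reserved code 3 falls back to 70.  The mapping is a design
#' choice of this simulator (the hardware wiring is not fixed by the
#' controller definition) and can be overridden via [run_config()].
#'
#' @param code integer 0..3, or a two-character bit string such as "01".
#' @return reference angle in degrees (70, 40 or 30).
#' @export
decode_ref_setting <- function(code) {
  code <- decode_2bit(code)
  c(70, 40, 30, 70)[code + 1]
}

#' Decode the 2-bit stimulation-frequency dip-switch setting
#'
#' Ascending mapping over the supported stimulation frequencies:
#' 0 -> 20 Hz, 1 -> 30 Hz, 2 -> 40 Hz, 3 -> 50 Hz.
#'
#' @inheritParams decode_ref_setting
#' @return stimulation frequency in Hz.
#' @export
decode_freq_setting <- function(code) {
  code <- decode_2bit(code)
  c(20, 30, 40, 50)[code + 1]
}

decode_2bit <- function(code) {
  if (is.character(code)) {
    stopifnot(grepl("^[01]{2}$", code))
    code <- strtoi(code, base = 2)
  }
  stopifnot(length(code) == 1, code %in% 0:3)
  code
}
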
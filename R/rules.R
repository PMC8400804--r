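#' The 25-rule base mapping (error, change-in-error) to output labels
#'
#' Fixed 5x5 grid over the linguistic labels NB, NS, ZE, PS, PB of the two
#' inputs.  Rule `min_k` sits at row `dE`, column `E`, with
#' `k = (row - 1) * 5 + column`, and fires with strength
#' `min(mu_E, mu_dE)`.  Output labels are the five singletons VS, SM, ME,
#' BG, VB: the more positive the error (under-extension), the bigger the
#' commanded pulse width.
#'
#' @return 5x5 character matrix; rows named by the change-in-error label,
#'   columns by the error label.
#' @export
rule_map <- function() {
  labs <- c("NB", "NS", "ZE", "PS", "PB")
  matrix(c(
    "VS", "VS", "VS", "SM", "ME",   # dE = NB
    "VS", "VS", "SM", "ME", "BG",   # dE = NS
    "VS", "SM", "ME", "BG", "VB",   # dE = ZE
    "SM", "ME", "BG", "VB", "VB",   # dE = PS
    "ME", "BG", "VB", "VB", "VB"    # dE = PB
  ), nrow = 5, byrow = TRUE, dimnames = list(dE = labs, E = labs))
}

#' Min-inference over the 25-rule base
#'
#' Each rule's firing strength is the minimum of its error-membership and
#' change-in-error-membership antecedents.  Rules are indexed 1..25 in
#' row-major order of the rule grid (row = dE label, column = E label).
#'
#' @param e,de named membership vectors from [fuzzify()]
#'   (components `nb`, `ns`, `ze`, `ps`, `pb`).
#' @return numeric vector of 25 rule strengths.
#' @export
infer_rules <- function(e, de) {
  stopifnot(length(e) == 5, length(de) == 5)
  # strength[k] = min(e[col], de[row]), k = (row-1)*5 + col
  as.vector(t(outer(de, e, pmin)))
}

#' Singleton output table for one reference angle
#'
#' Positions of the five output singletons (VS <= SM <= ME <= BG <= VB) in
#' defuzzy units; one table per supported reference angle.
#'
#' @param vs,sm,me,bg,vb integer singleton positions, non-decreasing,
#'   each in 10..50.
#' @param reference_angle reference angle in degrees (70, 40 or 30).
#' @return an object of class `singleton_table`.
#' @export
singleton_table <- function(vs, sm, me, bg, vb, reference_angle) {
  pos <- c(vs = vs, sm = sm, me = me, bg = bg, vb = vb)
  stopifnot(!is.unsorted(pos), all(pos >= 10), all(pos <= 50),
            reference_angle %in% c(70, 40, 30))
  structure(list(positions = pos, reference_angle = reference_angle),
            class = "singleton_table")
}

#' @export
print.singleton_table <- function(x, ...) {
  cat(sprintf("singleton table (ref %d deg): VS=%d SM=%d ME=%d BG=%d VB=%d\n",
              x$reference_angle, x$positions["vs"], x$positions["sm"],
              x$positions["me"], x$positions["bg"], x$positions["vb"]))
  invisible(x)
}

#' Default singleton tables for the three reference angles
#'
#' The tuned singleton positions: 70 deg -> (15, 20, 38, 42, 45),
#' 40 deg -> (10, 14, 22, 24, 30), 30 deg -> (10, 12, 16, 18, 26).
#'
#' @return named list of [singleton_table()] objects, keyed "70", "40", "30".
#' @export
default_singleton_tables <- function() {
  list(
    "70" = singleton_table(15, 20, 38, 42, 45, 70),
    "40" = singleton_table(10, 14, 22, 24, 30, 40),
    "30" = singleton_table(10, 12, 16, 18, 26, 30)
  )
}

# singleton position of each of the 25 rules, in rule-index order
rule_singletons <- function(table, rules = rule_map()) {
  lab <- as.vector(t(rules))
  unname(table$positions[c(VS = "vs", SM = "sm", ME = "me",
                           BG = "bg", VB = "vb")[lab]])
}

#' Singleton centre-of-gravity defuzzification (integer)
#'
#' Weighted average of the singleton positions by rule strength, with a
#' single floor division at the end:
#' `defuzzy = floor(sum(min_i * c_i) / sum(min_i))`.  The pulse width is
#' `defuzzy * pulse_multiplier` microseconds.
#'
#' @param strengths numeric vector of 25 rule strengths from
#'   [infer_rules()]; must not be all zero.
#' @param table a [singleton_table()].
#' @param pulse_multiplier microseconds of pulse width per defuzzy unit
#'   (default 10).
#' @param rules rule grid as from [rule_map()], assigning a singleton label
#'   to each rule index.
#' @return an object of class `defuzzy_result`: list with integer `defuzzy`,
#'   integer `pulse` (microseconds) and `fired_rules` (data.frame of rule
#'   index and strength for every rule with strength > 0).
#' @export
defuzzify <- function(strengths, table, pulse_multiplier = 10,
                      rules = rule_map()) {
  stopifnot(length(strengths) == 25, all(strengths >= 0),
            inherits(table, "singleton_table"), pulse_multiplier > 0)
  den <- sum(strengths)
  if (den == 0) {
    stop("all rule strengths are zero: invalid membership configuration")
  }
  ci <- rule_singletons(table, rules)
  defuzzy <- sum(strengths * ci) %/% den
  fired <- which(strengths > 0)
  structure(list(
    defuzzy = defuzzy,
    pulse = defuzzy * pulse_multiplier,
    fired_rules = data.frame(rule = fired, strength = strengths[fired])
  ), class = "defuzzy_result")
}

#' @export
print.defuzzy_result <- function(x, ...) {
  cat(sprintf("defuzzy %d (pulse %d us); %d rule(s) fired\n",
              x$defuzzy, x$pulse, nrow(x$fired_rules)))
  invisible(x)
}

# real-valued counterpart: no floors, unit-height strengths
defuzzify_float <- function(strengths, table, rules = rule_map()) {
  den <- sum(strengths)
  if (den == 0) {
    stop("all rule strengths are zero: invalid membership configuration")
  }
  sum(strengths * rule_singletons(table, rules)) / den
}
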
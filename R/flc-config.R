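#' Fuzzy-logic-controller configuration
#'
#' Bundles everything the controller datapath needs: the input membership
#' set (shared by error and change-in-error), the 25-rule base, the three
#' per-reference singleton tables, the pulse multiplier (microseconds of
#' stimulus pulse width per defuzzy unit) and the input clamp bound.
#'
#' @param membership membership set as from [default_membership_set()].
#' @param rules 5x5 label matrix as from [rule_map()].
#' @param singletons named list of [singleton_table()]s keyed by reference
#'   angle ("70", "40", "30").
#' @param pulse_multiplier microseconds per defuzzy unit (default 10).
#' @param clamp input clamp bound in degrees (default 20).
#' @return an object of class `flc_config`.
#' @export
flc_config <- function(membership = default_membership_set(),
                       rules = rule_map(),
                       singletons = default_singleton_tables(),
                       pulse_multiplier = 10,
                       clamp = 20) {
  stopifnot(length(membership) == 5,
            all(vapply(membership, inherits, logical(1), "triangle_params")),
            is.matrix(rules), all(dim(rules) == c(5, 5)),
            all(rules %in% c("VS", "SM", "ME", "BG", "VB")),
            length(singletons) >= 1,
            all(vapply(singletons, inherits, logical(1), "singleton_table")),
            pulse_multiplier > 0, clamp > 0)
  names(singletons) <- vapply(
    singletons, function(s) as.character(s$reference_angle), character(1))
  structure(list(membership = membership, rules = rules,
                 singletons = singletons,
                 pulse_multiplier = pulse_multiplier, clamp = clamp),
            class = "flc_config")
}

#' @export
print.flc_config <- function(x, ...) {
  cat("Fuzzy logic controller configuration\n")
  cat(sprintf("  input clamp: +/-%g deg; pulse multiplier: %g us/unit\n",
              x$clamp, x$pulse_multiplier))
  cat(sprintf("  reference angles: %s deg\n",
              paste(names(x$singletons), collapse = ", ")))
  invisible(x)
}

# singleton table for a reference angle, with a configuration error on miss
select_singletons <- function(config, ref) {
  key <- as.character(ref)
  if (!key %in% names(config$singletons)) {
    stop(sprintf("no singleton table for reference angle %s (have: %s)",
                 key, paste(names(config$singletons), collapse = ", ")))
  }
  config$singletons[[key]]
}

#' Serialize an FLC configuration to YAML
#'
#' Breakpoints are written in decimal; [read_flc_config()] additionally
#' accepts hexadecimal strings (e.g. "$3F" or "0x3F") for any breakpoint or
#' singleton position, matching the customary hex annotations of the 8-bit
#' scale.
#'
#' @param config an [flc_config()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_flc_config <- function(config, path) {
  stopifnot(inherits(config, "flc_config"))
  obj <- list(
    membership = lapply(config$membership,
                        function(t) list(a = t$a, b = t$b, c = t$c)),
    rules = apply(config$rules, 1, paste, collapse = " "),
    singletons = lapply(config$singletons, function(s) {
      c(as.list(s$positions), list(reference_angle = s$reference_angle))
    }),
    pulse_multiplier = config$pulse_multiplier,
    clamp = config$clamp
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read an FLC configuration from YAML
#'
#' @param path file written by [write_flc_config()] (or hand-edited; hex
#'   values like "$3F" are accepted).
#' @return an [flc_config()].
#' @export
read_flc_config <- function(path) {
  obj <- yaml::read_yaml(path)
  num <- function(v) {
    if (is.character(v)) strtoi(sub("^\\$", "0x", sub("^0x", "0x", v)), 16L)
    else v
  }
  membership <- lapply(obj$membership,
                       function(t) triangle_params(num(t$a), num(t$b), num(t$c)))
  rules <- do.call(rbind, strsplit(unlist(obj$rules), "\\s+"))
  labs <- c("NB", "NS", "ZE", "PS", "PB")
  dimnames(rules) <- list(dE = labs, E = labs)
  singletons <- lapply(obj$singletons, function(s) {
    singleton_table(num(s$vs), num(s$sm), num(s$me), num(s$bg), num(s$vb),
                    s$reference_angle)
  })
  flc_config(membership = membership, rules = rules, singletons = singletons,
             pulse_multiplier = obj$pulse_multiplier, clamp = obj$clamp)
}
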
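#' Triangular membership-function parameters on the 8-bit scale
#'
#' Breakpoints `a <= b <= c` on 0..255.  Shoulders are encoded by collapsing
#' one edge: a left shoulder has `a == b`, a right shoulder `b == c`, so the
#' saturated end of the scale still receives full membership 255.
#'
#' @param a,b,c integer breakpoints, `a <= b <= c`, each in 0..255.
#' @return an object of class `triangle_params`.
#' @export
triangle_params <- function(a, b, c) {
  stopifnot(a <= b, b <= c, a >= 0, c <= 255)
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c)),
            class = "triangle_params")
}

#' @export
print.triangle_params <- function(x, ...) {
  cat(sprintf("triangle(a=%d, b=%d, c=%d)\n", x$a, x$b, x$c))
  invisible(x)
}

#' Integer triangular membership degree
#'
#' Membership degree (0..255) of a scaled crisp input `x` in a triangular
#' set.  The peak `x == b` always returns 255 (this includes the flat side
#' of a shoulder set); the rising edge is `floor(255 * (x - a) / (b - a))`,
#' the falling edge `floor(255 * (c - x) / (c - b))`, and everything at or
#' beyond the feet is 0.  The single floor is applied at the end of each
#' rational expression, never to a pre-divided slope, so that the peak value
#' and the worked fixed-point results are reproduced exactly.
#'
#' @param x integer scaled input in 0..255.
#' @param t a [triangle_params()] object.
#' @return integer membership degree in 0..255.
#' @examples
#' triangular_membership(63, triangle_params(0, 63, 127))  # 255
#' triangular_membership(102, triangle_params(0, 63, 127)) # 99
#' @export
triangular_membership <- function(x, t) {
  stopifnot(inherits(t, "triangle_params"), x >= 0, x <= 255)
  if (x == t$b) return(255)
  if (x <= t$a || x >= t$c) return(0)
  if (x < t$b) (255 * (x - t$a)) %/% (t$b - t$a)
  else         (255 * (t$c - x)) %/% (t$c - t$b)
}

#' Default input membership set
#'
#' The five triangular sets shared by error and change-in-error on the
#' 8-bit scale: NB(0,0,63), NS(0,63,127), ZE(63,127,191), PS(127,191,255),
#' PB(191,255,255).  NB and PB are shoulders so that clamped extreme inputs
#' get full membership.
#'
#' @return named list of five [triangle_params()] objects
#'   (`nb`, `ns`, `ze`, `ps`, `pb`).
#' @export
default_membership_set <- function() {
  list(
    nb = triangle_params(0,   0,   63),
    ns = triangle_params(0,   63,  127),
    ze = triangle_params(63,  127, 191),
    ps = triangle_params(127, 191, 255),
    pb = triangle_params(191, 255, 255)
  )
}

#' Fuzzify a scaled input into the five membership degrees
#'
#' Applies [triangular_membership()] for each linguistic set.  With the
#' default set the five degrees always sum to 254 or 255 (partition of
#' unity up to one unit of floor loss) and at least one degree is >= 127.
#'
#' @param x integer scaled input in 0..255.
#' @param mfs membership set as returned by [default_membership_set()].
#' @return named integer vector `c(nb, ns, ze, ps, pb)`.
#' @export
fuzzify <- function(x, mfs = default_membership_set()) {
  vapply(mfs, function(t) triangular_membership(x, t), numeric(1))
}

# Real-valued counterparts on the -20..20 degree domain.  Used by the
# floating-point reference pipeline: same shapes, unit height, no floors.
float_membership_set <- function() {
  list(
    nb = c(-20, -20, -10),
    ns = c(-20, -10, 0),
    ze = c(-10, 0, 10),
    ps = c(0, 10, 20),
    pb = c(10, 20, 20)
  )
}

triangular_membership_float <- function(x, abc) {
  a <- abc[1]; b <- abc[2]; c <- abc[3]
  if (x == b) return(1)
  if (x <= a || x >= c) return(0)
  if (x < b) (x - a) / (b - a) else (c - x) / (c - b)
}

fuzzify_float <- function(x, mfs = float_membership_set()) {
  vapply(mfs, function(t) triangular_membership_float(x, t), numeric(1))
}
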
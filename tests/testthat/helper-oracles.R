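# Independent oracles used by the property tests.  These deliberately share
# no code with the package: the rule grid, triangle evaluation and weighted
# average are re-typed from first principles.

# literal 5x5 output-label grid (rows: dE = NB..PB, cols: E = NB..PB)
oracle_grid <- matrix(c(
  "VS", "VS", "VS", "SM", "ME",
  "VS", "VS", "SM", "ME", "BG",
  "VS", "SM", "ME", "BG", "VB",
  "SM", "ME", "BG", "VB", "VB",
  "ME", "BG", "VB", "VB", "VB"), nrow = 5, byrow = TRUE)

oracle_breaks <- list(c(0, 0, 63), c(0, 63, 127), c(63, 127, 191),
                      c(127, 191, 255), c(191, 255, 255))

oracle_tri <- function(x, abc) {
  a <- abc[1]; b <- abc[2]; c <- abc[3]
  if (x == b) return(255)
  if (x <= a || x >= c) return(0)
  if (x < b) floor(255 * (x - a) / (b - a)) else floor(255 * (c - x) / (c - b))
}

oracle_memberships <- function(x) {
  vapply(oracle_breaks, function(br) oracle_tri(x, br), numeric(1))
}

# brute-force defuzzification: loop over the grid cell by cell
oracle_defuzzy <- function(e_scaled, de_scaled, positions) {
  e <- oracle_memberships(e_scaled)
  de <- oracle_memberships(de_scaled)
  num <- 0; den <- 0
  for (i in 1:5) {
    for (j in 1:5) {
      s <- min(e[j], de[i])
      num <- num + s * positions[[oracle_grid[i, j]]]
      den <- den + s
    }
  }
  floor(num / den)
}

oracle_positions_70 <- list(VS = 15, SM = 20, ME = 38, BG = 42, VB = 45)

# static equilibrium of the shank under constant active torque, by bisection
oracle_equilibrium_deg <- function(T_a, p) {
  f <- function(th_deg) {
    th <- th_deg * pi / 180
    T_a - p$mgl * sin(th) - p$K * (th - p$rest)
  }
  lo <- 0; hi <- 90
  if (f(lo) <= 0) return(0)
  if (f(hi) >= 0) return(90)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
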
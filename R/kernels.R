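# Stable exponential response kernels.
#
# Every labelling model in the package is a cascade of linear first-order
# compartments forced by (piecewise) exponentials, so all closed-form
# solutions reduce to divided differences of x -> exp(-x t) over two or three
# decay rates.  Naive partial-fraction formulas suffer catastrophic
# cancellation when rates (nearly) coincide (e.g. d* = delta, the resonant
# case); the kernels below are uniformly accurate in the node gaps.

# (1 - exp(-x)) / x, accurate near x = 0
.phi1 <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-5
  xs <- x[small]
  out[small] <- 1 - xs / 2 + xs^2 / 6 - xs^3 / 24
  out[!small] <- -expm1(-x[!small]) / x[!small]
  out
}

# First-order response: (exp(-lam*t) - exp(-a*t)) / (a - lam),
# i.e. integral_0^t exp(-a (t-s)) exp(-lam s) ds.  lam, a scalars; t vector.
# Exact limit t * exp(-lam t) as a -> lam.
.edif <- function(lam, a, t) {
  t * exp(-lam * t) * .phi1((a - lam) * t)
}

# Second-order (cascade) response: integral of exp(-lam s) through two
# successive compartments with decay rates a1 then a2 equals the divided
# difference of x -> exp(-x t) over nodes {lam, a1, a2}.
.resp2 <- function(lam, a1, a2, t) {
  x <- sort(c(lam, a1, a2))
  spread <- x[3] - x[1]
  out <- numeric(length(t))
  ser <- spread * t < 0.5
  if (any(ser)) {
    # clustered regime: Taylor series of the divided difference around the
    # node mean; h_q are complete homogeneous symmetric polynomials
    m <- mean(x)
    y <- x - m
    tt <- t[ser]
    acc <- numeric(length(tt))
    for (q in 0:12) {
      hq <- 0
      for (j in 0:q) {
        hq <- hq + y[3]^j * sum(y[1]^(0:(q - j)) * y[2]^((q - j):0))
      }
      n <- q + 2
      acc <- acc + (-tt)^n / factorial(n) * hq
    }
    out[ser] <- exp(-m * tt) * acc
  }
  if (any(!ser)) {
    # separated regime: recurrence pivoting on the extreme nodes so the
    # cancellation divisor is the full spread
    tt <- t[!ser]
    dd12 <- -.edif(x[1], x[2], tt)
    dd23 <- -.edif(x[2], x[3], tt)
    out[!ser] <- (dd12 - dd23) / (x[1] - x[3])
  }
  out
}
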
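#' Von Mises density
#'
#' Circular density \eqn{f(x) = exp(\kappa cos(x - \mu)) / (2\pi I_0(\kappa))},
#' evaluated stably via the exponentially-scaled Bessel function so large
#' concentrations do not overflow. \eqn{\kappa = 0} gives the circular uniform.
#'
#' @param x angles in radians
#' @param mu mean direction (radians)
#' @param kappa concentration, >= 0
#' @param log if TRUE return log density
#' @return density values
#' @export
dvonmises <- function(x, mu = 0, kappa = 0, log = FALSE) {
  stopifnot(kappa >= 0)
  ld <- kappa * (cos(x - mu) - 1) - log(2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
  if (log) ld else exp(ld)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler based on a wrapped Cauchy envelope;
#' \eqn{\kappa = 0} falls back to uniform on (-pi, pi].
#'
#' @param n number of draws
#' @param mu mean direction (radians)
#' @param kappa concentration, >= 0
#' @return angles in (-pi, pi]
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(kappa >= 0)
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cv <- kappa * (r - f)
    ok <- (cv * (2 - cv) - u2 > 0) | (log(cv / u2) + 1 - cv >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    out <- c(out, th)
  }
  ang <- out[seq_len(n)] + mu
  atan2(sin(ang), cos(ang))  # wrap to (-pi, pi]
}
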
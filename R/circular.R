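# Circular utilities for the 180-degree stimulus space.
#
# All response domains (orientation, colour, luminance) are represented on a
# 180-unit circle. For von Mises sampling and density evaluation, values are
# doubled onto the full 360-degree circle and halved back -- the standard
# orientation-space convention.

#' Wrap angles into the 180-degree stimulus space
#'
#' @param x numeric vector of angles (degrees).
#' @return Angles wrapped into `[0, 180)`.
#' @export
wrap180 <- function(x) x %% 180

#' Signed circular difference on the 180-degree space
#'
#' Returns `a - b` wrapped into `(-90, 90]`.
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return Signed differences in `(-90, 90]`.
#' @export
circ_diff180 <- function(a, b) {
  d <- (a - b) %% 180
  ifelse(d > 90, d - 180, d)
}

# Log von Mises density per radian on the (doubled) circle.
# Uses the exponentially scaled Bessel function so large kappa never
# overflows: log I0(k) = log(besselI(k, 0, scaled)) + k.
log_dvm <- function(theta, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(rep(-log(2 * pi), length(theta)))
  kappa * cos(theta) - log(2 * pi) - (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
}

# von Mises sampler (Best & Fisher 1979 rejection method), mean mu, in
# radians on (-pi, pi].
rvm <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-9) {
    theta <- stats::runif(n, -pi, pi)
    return(((theta + mu + pi) %% (2 * pi)) - pi)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nacc <- sum(ok)
    if (nacc > 0L) {
      theta <- sign(stats::runif(nacc) - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      out[(got + 1L):(got + nacc)] <- theta
      got <- got + nacc
    }
  }
  ((out + mu + pi) %% (2 * pi)) - pi
}

# Draw von Mises noise expressed in degrees of the 180-space: sample on the
# doubled circle and halve back.
rvm_deg180 <- function(n, kappa) {
  rvm(n, mu = 0, kappa = kappa) / 2 * (180 / pi)
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
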
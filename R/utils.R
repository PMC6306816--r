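# Internal helpers: seeded evaluation, angle arithmetic, axial sampling.

# Evaluate expr under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards (no global side effects).
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

degToRad <- function(x) x * pi / 180
radToDeg <- function(x) x * 180 / pi

# Reduce an axial angle (degrees) into [-90, 90).
wrapAxialDeg <- function(x) {
  y <- (x + 90) %% 180
  y - 90
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# von Mises sampler (Best & Fisher 1979 rejection scheme), mean mu (radians),
# concentration kappa > 0. Used through sampleAxialOrientations below.
rVonMises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric(0))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    m <- max(n - filled, 16L)
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    acc <- f[ok]
    if (length(acc) > 0L) {
      take <- min(length(acc), n - filled)
      th <- sign(u3[ok][seq_len(take)] - 0.5) * acos(acc[seq_len(take)])
      out[(filled + 1L):(filled + take)] <- mu + th
      filled <- filled + take
    }
  }
  # wrap into (-pi, pi]
  ((out + pi) %% (2 * pi)) - pi
}

#' Sample axial orientations from the doubled-angle von Mises law
#'
#' Fibril orientations are axial (phi and phi + 180 degrees are the same
#' fibril), so the generator draws the doubled angle 2*phi from a von Mises
#' distribution with mean 2*meanAngleDeg and concentration kappa, then halves
#' it. \code{kappa = 0} gives orientations uniform on \code{[-90, 90)}; for
#' large kappa the circular standard deviation of the orientation is about
#' \code{1/(2*sqrt(kappa))} radians.
#'
#' @param n number of orientations to draw.
#' @param meanAngleDeg mean orientation in degrees.
#' @param kappa non-negative concentration of the doubled-angle distribution.
#' @param seed optional integer seed; when given, sampling uses a private RNG
#'   stream and leaves the global RNG state untouched.
#' @return numeric vector of orientations in degrees, in \code{[-90, 90)}.
#' @examples
#' phi <- sampleAxialOrientations(1000, meanAngleDeg = 30, kappa = 50, seed = 1)
#' mean(phi)
#' @export
sampleAxialOrientations <- function(n, meanAngleDeg, kappa, seed = NULL) {
  stopifnot(n >= 0, kappa >= 0)
  draw <- function() {
    if (kappa == 0) {
      stats::runif(n, -90, 90)
    } else {
      psi <- rVonMises(n, degToRad(2 * meanAngleDeg), kappa)
      wrapAxialDeg(radToDeg(psi / 2))
    }
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

# Mean direction of axial angles (degrees in [-90, 90)) via the doubled-angle
# resultant.
circularMeanAxialDeg <- function(phiDeg) {
  psi <- degToRad(2 * phiDeg)
  wrapAxialDeg(radToDeg(atan2(mean(sin(psi)), mean(cos(psi))) / 2))
}
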
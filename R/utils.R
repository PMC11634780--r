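# Shared helpers: time grids, angles, circular statistics.

#' @useDynLib wmstates, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aov approx complete.cases cor.test density dbeta lm
#'   median optim anova qnorm quantile rbinom rgamma rnorm rpois runif sd
#'   setNames var wilcox.test dnorm
#' @importFrom utils read.csv write.csv head
NULL

# default analysis windows (ms, cue-aligned, half-open [start, end))
WM_RATE_START <- -400
WM_RATE_END <- 1400
WM_RATE_STEP <- 10
WM_LABEL_SPAN <- c(0, 1400)
WM_DELAY <- c(500, 1400)
WM_BASELINE <- c(-400, 0)

#' Default 10-ms sample grid for rate tensors
#'
#' Sample times are the left edges of half-open 10-ms bins, cue-aligned
#' (0 = cue onset).
#' @param start,end window in ms
#' @param step sample step in ms
#' @return numeric vector of sample times
#' @export
rate_time_axis <- function(start = WM_RATE_START, end = WM_RATE_END,
                           step = WM_RATE_STEP) {
  seq(start, end - step, by = step)
}

wrap_angle <- function(x) {
  # wrap to (-pi, pi]
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Circular mean of angles in radians
#' @param theta angles (radians)
#' @return mean direction in (-pi, pi]
#' @export
circ_mean <- function(theta) {
  atan2(mean(sin(theta)), mean(cos(theta)))
}

#' Magnitude of the angular difference between two directions
#' @param a,b angles (radians)
#' @return difference magnitude in `[0, pi]`
#' @export
ang_diff <- function(a, b) {
  abs(wrap_angle(a - b))
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 falls
# back to the uniform circle.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be non-negative")
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1)) + mu
        break
      }
    }
  }
  wrap_angle(out)
}

# index of the diametrically opposite cue location (8 locations, 45 deg apart)
opposite_location <- function(loc, n_cond = 8L) {
  ((loc - 1L + n_cond %/% 2L) %% n_cond) + 1L
}

# maximal runs of TRUE in a logical vector (NA breaks runs);
# returns data.frame(start, end) of 1-based inclusive indices
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
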
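# Signal conditioning: zero-phase Butterworth filtering and numerical
# differentiation.
#
# Filters are designed as a cascade of second-order sections rather than a
# single transfer function: an 8th-order design with a 0.1 Hz corner at
# 100 Hz sampling (normalized corner 0.002) is numerically unusable in
# direct polynomial form, while the biquad cascade stays well conditioned.

# Analog Butterworth prototype poles for order n, split into second-order
# (and at most one first-order) sections, bilinear-transformed at fs.
# Returns a list of sections, each c(b0, b1, b2, a1, a2) with a0 = 1.
butter_sections <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1, fc > 0, fc < fs / 2)
  wa <- 2 * fs * tan(pi * fc / fs)       # pre-warped analog corner (rad/s)
  k <- seq_len(floor(order / 2))
  # conjugate-pair prototype poles: |p| = 1, Re(p) < 0
  theta <- pi * (2 * k - 1) / (2 * order)
  K <- 2 * fs
  sections <- list()
  for (th in theta) {
    # analog pair: s^2 + 2 sin(th) wa s + wa^2 (lowpass);
    # highpass substitutes s -> wa^2/s which maps the pair onto itself with
    # numerator s^2 instead of wa^2.
    a1s <- 2 * sin(th) * wa
    a0s <- wa^2
    d0 <- K^2 + a1s * K + a0s
    az <- c((-2 * K^2 + 2 * a0s) / d0, (K^2 - a1s * K + a0s) / d0)
    bz <- if (type == "low") a0s * c(1, 2, 1) / d0 else K^2 * c(1, -2, 1) / d0
    sections[[length(sections) + 1L]] <- c(bz, az)
  }
  if (order %% 2 == 1) {                 # odd order: one real pole at -wa
    d0 <- K + wa
    az <- c((wa - K) / d0, 0)
    bz <- if (type == "low") wa * c(1, 1, 0) / d0 else K * c(1, -1, 0) / d0
    sections[[length(sections) + 1L]] <- c(bz, az)
  }
  sections
}

# Run one biquad over the series with the filter state initialized to the
# steady-state response for a constant input equal to the first sample, so
# that a series with a constant lead-in produces no start-up transient.
biquad_filter <- function(x, s) {
  b <- s[1:3]; a1 <- s[4]; a2 <- s[5]
  Hdc <- sum(b) / (1 + a1 + a2)
  x0 <- x[1]
  v <- stats::filter(c(x0, x0, x), b, method = "convolution", sides = 1)
  v <- as.numeric(v)[-(1:2)]
  y0 <- Hdc * x0
  as.numeric(stats::filter(v, c(-a1, -a2), method = "recursive",
                           init = c(y0, y0)))
}

apply_sections <- function(x, sections) {
  for (s in sections) x <- biquad_filter(x, s)
  x
}

#' Zero-phase Butterworth filter
#'
#' Applies a Butterworth filter of the requested order forward and backward
#' over the series, yielding exactly zero phase shift at all frequencies and
#' the squared Butterworth magnitude response (an order-8 design therefore
#' attenuates like a 16th-order filter).  Before filtering, the series is
#' extended at both ends by odd reflection so that the filter state has
#' settled when it re-enters the recorded samples; the extension is dropped
#' from the output.
#'
#' @param x numeric series, uniformly sampled.
#' @param fs sampling frequency, Hz.
#' @param fc corner frequency, Hz (0 < fc < fs/2).
#' @param order filter order of a single pass (default 8).
#' @param type `"high"` or `"low"`.
#' @return filtered series, same length as `x`.
#' @examples
#' fs <- 100; t <- seq(0, 40, by = 1/fs)
#' x <- sin(2 * pi * 1 * t) + 5          # 1 Hz riding on an offset
#' y <- zero_phase_butterworth(x, fs, fc = 0.1, type = "high")
#' @export
zero_phase_butterworth <- function(x, fs, fc, order = 8,
                                   type = c("high", "low")) {
  type <- match.arg(type)
  if (!is.numeric(fs) || fs <= 0) stop("'fs' must be positive", call. = FALSE)
  if (!(fc > 0 && fc < fs / 2))
    stop("'fc' must satisfy 0 < fc < fs/2 (got fc = ", fc, ", fs = ", fs,
         ")", call. = FALSE)
  n <- length(x)
  settle <- ceiling(fs / fc)         # roughly one corner period of samples
  if (n < 3 * settle)
    stop("series too short for stable zero-phase filtering at fc = ", fc,
         " Hz: need at least ", 3 * settle, " samples, got ", n,
         call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("non-finite values in input series", call. = FALSE)

  pad <- min(n - 1L, 3L * settle)
  left <- 2 * x[1] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xe <- c(left, x, right)
  sec <- butter_sections(order, fc, fs, type)
  y <- apply_sections(xe, sec)
  y <- rev(apply_sections(rev(y), sec))
  y[(pad + 1L):(pad + n)]
}

#' Numerical differentiation
#'
#' Central differences in the interior, second-order one-sided differences at
#' the two endpoints.  Exact for linear series; O(dt^2) error on smooth ones.
#'
#' @param x numeric series.
#' @param fs sampling frequency, Hz.
#' @return the derivative series, same length as `x`.
#' @export
differentiate <- function(x, fs) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate", call. = FALSE)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) * fs / 2
  d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) * fs / 2
  d
}

# Cumulative trapezoidal integration from zero initial condition.
cumtrapz1 <- function(x, fs) {
  c(0, cumsum((x[-length(x)] + x[-1]) / (2 * fs)))
}
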
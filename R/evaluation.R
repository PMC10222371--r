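# Accuracy metrics over the standard evaluation window, and the
# COP-correlation applicability test for the force-plate-only method.

window_index <- function(n, fs, t0, t1) {
  t <- (seq_len(n) - 1) / fs
  i <- which(t >= t0 & t < t1)
  if (!length(i) || max(t) + 1 / fs < t1 - 1e-9)
    stop("evaluation window [", t0, ", ", t1, ") outside the record",
         call. = FALSE)
  i
}

#' Windowed root-mean-square error
#'
#' RMSE between an estimate and its reference over the half-open window
#' `[t0, t1)` -- at 100 Hz with the default 5-35 s window this is a mean
#' over exactly 3000 samples.
#'
#' @param estimate,truth equal-length series on one grid starting at t = 0.
#' @param fs sampling frequency, Hz.
#' @param t0,t1 window limits, s.
#' @return scalar RMSE in the units of the inputs.
#' @export
rmse_windowed <- function(estimate, truth, fs, t0 = 5, t1 = 35) {
  if (length(estimate) != length(truth))
    stop("series lengths differ", call. = FALSE)
  i <- window_index(length(estimate), fs, t0, t1)
  sqrt(mean((estimate[i] - truth[i])^2))
}

#' Windowed Pearson correlation
#'
#' @inheritParams rmse_windowed
#' @return Pearson correlation coefficient over the window.
#' @export
pearson_cc <- function(estimate, truth, fs, t0 = 5, t1 = 35) {
  if (length(estimate) != length(truth))
    stop("series lengths differ", call. = FALSE)
  i <- window_index(length(estimate), fs, t0, t1)
  if (var(estimate[i]) == 0 || var(truth[i]) == 0)
    stop("zero variance in the evaluation window: correlation undefined",
         call. = FALSE)
  cor(estimate[i], truth[i])
}

#' Applicability test for the force-plate-only method
#'
#' The single-pendulum inversion is trustworthy only when the motion is
#' ankle-strategy-like; its failure mode (hip strategy) decorrelates the
#' estimated COM from the COP.  The test computes the Pearson correlation
#' `C_p` between the COP and the method-I COM displacement over the
#' evaluation window and declares the estimate valid when `C_p` exceeds the
#' threshold (default 0.8).
#'
#' @param cop COP series for the analysed plane (m).
#' @param com_method1 method-I COM displacement series (m), same grid.
#' @param fs sampling frequency, Hz.
#' @param t0,t1 evaluation window, s.
#' @param threshold validity threshold on `C_p`.
#' @return list with `C_p` and logical `valid`.
#' @export
cp_validity <- function(cop, com_method1, fs, t0 = 5, t1 = 35,
                        threshold = 0.8) {
  C_p <- pearson_cc(cop, com_method1, fs, t0, t1)
  list(C_p = C_p, valid = C_p > threshold)
}

#' Evaluate an estimate against ground truth
#'
#' Windowed RMSE and correlation for every quantity the estimate carries
#' (displacement, velocity, acceleration and -- for the two-segment method --
#' the segment accelerations), reported in mm-based units.
#'
#' @param est a `com_estimate`.
#' @param truth a `com_truth` (the matching plane is picked via
#'   `est$plane`), or a data frame with columns `xb`, `xbd`, `xbdd`
#'   (and optionally `x1dd`, `x2dd`).
#' @param t0,t1 evaluation window, s.
#' @return object of class `"com_metrics"`: data frame with columns
#'   `quantity`, `rmse`, `cc`, `unit`, plus attributes `window` and `n`.
#' @export
evaluate_com <- function(est, truth, t0 = 5, t1 = 35) {
  stopifnot(inherits(est, "com_estimate"))
  td <- if (inherits(truth, "com_truth")) truth[[est$plane]] else truth
  fs <- est$fs
  pairs <- list(
    displacement = list(est$data$xb, td$xb, "mm", 1000),
    velocity = list(est$data$vb, td$xbd, "mm/s", 1000),
    acceleration = list(est$data$ab, td$xbdd, "mm/s^2", 1000))
  if (!is.null(est$data$a1) && !is.null(td$x1dd)) {
    pairs$lower_acceleration <- list(est$data$a1, td$x1dd, "mm/s^2", 1000)
    pairs$upper_acceleration <- list(est$data$a2, td$x2dd, "mm/s^2", 1000)
  }
  rows <- lapply(names(pairs), function(nm) {
    p <- pairs[[nm]]
    if (is.null(p[[1]]) || is.null(p[[2]]) || !any(is.finite(p[[1]])))
      return(NULL)
    data.frame(quantity = nm,
               rmse = p[[4]] * rmse_windowed(p[[1]], p[[2]], fs, t0, t1),
               cc = pearson_cc(p[[1]], p[[2]], fs, t0, t1),
               unit = p[[3]])
  })
  out <- do.call(rbind, rows)
  i <- window_index(length(est$t), fs, t0, t1)
  structure(out, class = c("com_metrics", "data.frame"),
            window = c(t0, t1), n = length(i),
            method = est$method, plane = est$plane)
}

#' @export
print.com_metrics <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("Estimation accuracy, method %s, %s plane, window [%g, %g) s",
              attr(x, "method"), attr(x, "plane"), w[1], w[2]),
      sprintf("(%d samples)\n", attr(x, "n")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
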
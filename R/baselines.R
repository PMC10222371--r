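# Baseline COM estimators from the prior literature: COP low-pass filtering
# and double integration of the force-derived COM acceleration.  Both are
# standard formulations with the cutoffs exposed as configuration.

#' Center of pressure from plate channels
#'
#' `COP_x = Ny / Fz`, `COP_y = -Nx / Fz`: with these signs a static lean
#' places the COP at the ground projection of the whole-body COM under the
#' model's moment conventions.  The moment reference is taken at the plate
#' origin on the plate surface; a vertical offset `z0` between the moment
#' reference and the surface adds the usual `-R z0 / Fz` correction.
#'
#' @param plate plate data frame (`t, Rx, Ry, Fz, Nx, Ny`).
#' @param z0 moment-reference offset below the plate surface, m (default 0).
#' @return data frame `t, COPx, COPy` (m).
#' @export
compute_cop <- function(plate, z0 = 0) {
  if (any(!is.finite(plate$Fz)) || any(plate$Fz <= 0))
    stop("Fz must be positive throughout the record to define the COP",
         call. = FALSE)
  data.frame(t = plate$t,
             COPx = (plate$Ny - plate$Rx * z0) / plate$Fz,
             COPy = (-plate$Nx - plate$Ry * z0) / plate$Fz)
}

#' COP-filtering baseline (method III)
#'
#' Estimates the COM displacement as a zero-phase low-pass of the COP.
#' The default 0.5 Hz corner is this package's choice of a standard
#' formulation; velocity follows by numerical differentiation.
#'
#' @param cop output of [compute_cop()].
#' @param fs sampling frequency, Hz.
#' @param fc low-pass corner, Hz.
#' @param plane which COP component to use.
#' @param order Butterworth order (single pass).
#' @return list `t`, `xb` (m), `vb` (m/s), `ab` (m/s^2).
#' @export
estimate_method3 <- function(cop, fs, fc = 0.5,
                             plane = c("sagittal", "frontal"), order = 8) {
  plane <- match.arg(plane)
  if (fc >= fs / 2) stop("'fc' must be below fs/2", call. = FALSE)
  x <- if (plane == "sagittal") cop$COPx else cop$COPy
  xb <- zero_phase_butterworth(x, fs, fc, order, "low")
  vb <- differentiate(xb, fs)
  list(t = cop$t, xb = xb, vb = vb, ab = differentiate(vb, fs))
}

#' Double-integration baseline (method IV)
#'
#' COM acceleration from the horizontal force, integrated twice by the
#' trapezoidal rule with a zero-phase high-pass after each integration to
#' suppress drift; integration constants are zero.
#'
#' @param plane `"sagittal"` or `"frontal"`.
#' @param plate plate data frame (horizontal forces conditioned upstream).
#' @param support support-acceleration data frame.
#' @param params segment parameters.
#' @param fs sampling frequency, Hz.
#' @param highpass_hz stabilizing high-pass corner, Hz.
#' @param order Butterworth order (single pass).
#' @return list `t`, `xb` (m), `vb` (m/s), `ab` (m/s^2).
#' @export
estimate_method4 <- function(plane = c("sagittal", "frontal"), plate,
                             support, params, fs, highpass_hz = 0.1,
                             order = 8) {
  plane <- match.arg(plane)
  s <- as.list(params$sagittal)
  subj <- params$subject
  if (plane == "sagittal") {
    ab <- (-subj$M * support$Xsdd - plate$Rx) / s$m_b
  } else {
    ab <- (-subj$M * support$Ysdd - plate$Ry) / s$m_b
  }
  vb <- zero_phase_butterworth(cumtrapz1(ab, fs), fs, highpass_hz, order,
                               "high")
  xb <- zero_phase_butterworth(cumtrapz1(vb, fs), fs, highpass_hz, order,
                               "high")
  list(t = plate$t, xb = xb, vb = vb, ab = ab)
}
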
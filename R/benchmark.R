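# Six-motion synthetic benchmark comparing the four estimation methods.

#' Run the six-motion method-comparison benchmark
#'
#' Simulates the six motion conditions (linear inverse dynamics with sensor
#' noise), runs the requested methods in the plane(s) each motion excites,
#' and tabulates windowed RMSE and correlation against ground truth plus the
#' COP-correlation applicability statistic `C_p` of the force-plate-only
#' method.
#'
#' @param subject a [com_subject()].
#' @param seed integer master seed; each motion uses `seed + k`.
#' @param noise a [noise_spec()] or NULL for noise-free runs.
#' @param methods subset of `c("I","II","III","IV")`.
#' @param motions subset of the six motion tags.
#' @param ... forwarded to [estimate_com()].
#' @return data frame of class `"com_benchmark"`: one row per motion x
#'   plane x method with displacement/velocity RMSE (mm, mm/s), their
#'   correlations, and per motion x plane the `C_p` and the method-I
#'   validity flag.
#' @export
run_benchmark <- function(subject = com_subject(70, 1.75), seed = 1L,
                          noise = noise_spec(seed = seed),
                          methods = c("I", "II", "III", "IV"),
                          motions = c("quiet", "ankle_AP", "ankle_ML",
                                      "hip_AP", "sway_AP", "sway_ML"),
                          ...) {
  rows <- list()
  for (k in seq_along(motions)) {
    mo <- motions[k]
    if (!is.null(noise)) noise$seed <- as.integer(seed + 1000L + k)
    trial <- simulate_trial(mo, subject = subject, noise = noise,
                            seed = as.integer(seed + k))
    planes <- switch(mo,
                     quiet = c("sagittal", "frontal"),
                     ankle_AP = "sagittal", hip_AP = "sagittal",
                     sway_AP = "sagittal",
                     ankle_ML = "frontal", sway_ML = "frontal")
    for (pl in planes) {
      cop <- compute_cop(trial$plate)
      cop_series <- if (pl == "sagittal") cop$COPx else cop$COPy
      est1 <- estimate_com(trial, method = "I", plane = pl, ...)
      cp <- cp_validity(cop_series, est1$data$xb, trial$fs)
      for (me in methods) {
        est <- if (me == "I") est1
               else estimate_com(trial, method = me, plane = pl, ...)
        met <- evaluate_com(est, trial$truth)
        g <- function(q, col) {
          i <- match(q, met$quantity)
          if (is.na(i)) NA_real_ else met[[col]][i]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          motion = mo, plane = pl, method = me,
          rmse_disp_mm = g("displacement", "rmse"),
          rmse_vel_mms = g("velocity", "rmse"),
          cc_disp = g("displacement", "cc"),
          cc_vel = g("velocity", "cc"),
          C_p = cp$C_p, valid_method1 = cp$valid)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("com_benchmark", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' @export
print.com_benchmark <- function(x, ...) {
  cat("Six-motion synthetic benchmark (seed", attr(x, "seed"), ")\n")
  d <- as.data.frame(x)
  d$rmse_disp_mm <- round(d$rmse_disp_mm, 3)
  d$rmse_vel_mms <- round(d$rmse_vel_mms, 3)
  d$cc_disp <- round(d$cc_disp, 3)
  d$cc_vel <- round(d$cc_vel, 3)
  d$C_p <- round(d$C_p, 3)
  print(d, row.names = FALSE)
  invisible(x)
}
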
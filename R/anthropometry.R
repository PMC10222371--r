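# Anthropometric scaling of the standing-posture pendulum models.
#
# All segment masses scale with body mass M, lengths with height H, and
# moments of inertia with M*H^2.  The coefficients are a published young-male
# regression set; they close exactly on mass (lower + upper = body;
# 2 legs + pelvis + upper = body) but only approximately on COM height,
# because each coefficient was rounded independently.  The tabulated values
# are used verbatim -- the small COM-height inconsistency is deliberate and
# must not be "repaired".

.seg_coef <- list(
  sagittal = c(
    m_b = 0.978, J_b = 0.0425, l_b = 0.531,
    m_1 = 0.322, J_1 = 0.00223, l_1 = 0.285, L_1 = 0.460,
    m_2 = 0.656, J_2 = 0.0114, l_2 = 0.191, L_2 = 0.434,
    L_f = 0.038),
  frontal = c(
    m_l = 0.161, J_l = 0.00524, l_l = 0.285, L_l = 0.460,
    m_p = 0.187, l_p = 0.056, L_p = 0.144,
    m_u = 0.469, J_u = 0.00714, l_u = 0.109, L_u = 0.290,
    L_f = 0.038)
)

#' Describe a subject
#'
#' Creates the subject descriptor from which every model parameter is
#' derived.
#'
#' @param mass body mass M in kg.
#' @param height standing height H in m.
#' @param g gravitational acceleration in m/s^2 (default 9.81).
#' @return An object of class `"com_subject"`: a list with elements `M`,
#'   `H` and `g`.
#' @examples
#' subj <- com_subject(70, 1.75)
#' @export
com_subject <- function(mass, height, g = 9.81) {
  for (nm in c("mass", "height", "g")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single finite positive number, got ",
           deparse(v), call. = FALSE)
  }
  structure(list(M = mass, H = height, g = g), class = "com_subject")
}

#' Segment parameters from height and weight
#'
#' Evaluates the anthropometric regression table for a subject: masses (kg),
#' COM-to-joint lengths and segment lengths (m), and moments of inertia
#' about the segment COM (kg m^2), for the sagittal-plane single/double
#' pendulum (body; lower body + upper body) and the frontal-plane
#' leg--pelvis--upper-body linkage.
#'
#' Lengths are measured along the segment: `l_*` is the distance from the
#' proximal joint to the segment COM and `L_*` the full segment (or
#' joint-to-joint) length; `L_f` is the ankle height; `L_2` and `L_u` reach
#' from the hip/waist to the head-mounted sensor.
#'
#' @param subject a [com_subject()].
#' @return An object of class `"segment_params"`: list with components
#'   `sagittal` and `frontal` (named numeric vectors) plus the `subject`.
#' @examples
#' p <- segment_parameters(com_subject(83, 1.80))
#' p$sagittal[["m_b"]]   # 0.978 * 83
#' @export
segment_parameters <- function(subject) {
  if (!inherits(subject, "com_subject"))
    stop("'subject' must be a com_subject object", call. = FALSE)
  M <- subject$M; H <- subject$H
  scale_one <- function(coefs) {
    out <- coefs
    for (nm in names(coefs)) {
      kind <- substr(nm, 1, 1)
      out[[nm]] <- switch(kind,
        m = coefs[[nm]] * M,          # masses ~ M
        J = coefs[[nm]] * M * H^2,    # inertias ~ M H^2
        coefs[[nm]] * H)              # lengths ~ H
    }
    out
  }
  structure(list(
    sagittal = scale_one(.seg_coef$sagittal),
    frontal = scale_one(.seg_coef$frontal),
    subject = subject
  ), class = "segment_params")
}

#' Composite inertia coefficients of the linearized models
#'
#' Assembles the coefficients that multiply the segment COM accelerations in
#' the linearized (small-angle) moment equations about the plate origin.
#' Each is a moment-per-unit-acceleration with units kg m:
#'
#' \describe{
#'   \item{C_sag}{single-pendulum body coefficient,
#'     `J_b/l_b + m_b (L_f + l_b)`; identical form `C_front` uses the same
#'     body values (the whole-body segment is shared by both planes).}
#'   \item{J_x1, J_x2}{sagittal double pendulum,
#'     `J_x1 = J_1/l_1 + m_1 (L_f + l_1) - J_2 L_1/(l_1 l_2)`,
#'     `J_x2 = J_2/l_2 + m_2 (L_f + L_1 + l_2)`.}
#'   \item{J_y1, J_y2}{frontal linkage (legs rotate, pelvis translates with
#'     the hip, upper body rotates about the waist),
#'     `J_y1 = 2 J_l/l_l - J_u L_l/(l_l l_u) + 2 m_l (L_f + l_l) +
#'     m_p (L_l/l_l)(L_f + L_l + l_p)`,
#'     `J_y2 = J_u/l_u + m_u (L_f + L_l + L_p + l_u)`.}
#'   \item{J_yb}{frontal constrained model (leg and upper-body angles equal):
#'     `[2 J_l + J_u + 2 m_l l_l (L_f + l_l) + m_p L_l (L_f + L_l + l_p) +
#'     m_u (L_l + l_u)(L_f + L_l + L_p + l_u)] / l_b`.  The upper-body lever
#'     is `(L_l + l_u)` -- not `(L_l + L_p + l_u)` -- because the pelvis
#'     translates without rotating, so the pelvis height contributes no
#'     horizontal displacement.}
#' }
#'
#' All coefficients are homogeneous of degree one in both M and H.
#'
#' @param params a [segment_parameters()] set.
#' @return Object of class `"composite_inertias"`: named list with entries
#'   `C_sag`, `J_x1`, `J_x2`, `J_y1`, `J_y2`, `J_yb` (kg m).
#' @export
composite_inertias <- function(params) {
  if (!inherits(params, "segment_params"))
    stop("'params' must come from segment_parameters()", call. = FALSE)
  s <- as.list(params$sagittal); f <- as.list(params$frontal)
  for (nm in c("l_1", "l_2", "l_b")) if (s[[nm]] == 0)
    stop("zero-length lever '", nm, "' in sagittal parameters", call. = FALSE)
  for (nm in c("l_l", "l_u")) if (f[[nm]] == 0)
    stop("zero-length lever '", nm, "' in frontal parameters", call. = FALSE)

  out <- list(
    C_sag = s$J_b / s$l_b + s$m_b * (s$L_f + s$l_b),
    J_x1 = s$J_1 / s$l_1 + s$m_1 * (s$L_f + s$l_1) -
      s$J_2 * s$L_1 / (s$l_1 * s$l_2),
    J_x2 = s$J_2 / s$l_2 + s$m_2 * (s$L_f + s$L_1 + s$l_2),
    J_y1 = 2 * f$J_l / f$l_l - f$J_u * f$L_l / (f$l_l * f$l_u) +
      2 * f$m_l * (f$L_f + f$l_l) +
      f$m_p * (f$L_l / f$l_l) * (f$L_f + f$L_l + f$l_p),
    J_y2 = f$J_u / f$l_u + f$m_u * (f$L_f + f$L_l + f$L_p + f$l_u),
    J_yb = (2 * f$J_l + f$J_u +
              2 * f$m_l * f$l_l * (f$L_f + f$l_l) +
              f$m_p * f$L_l * (f$L_f + f$L_l + f$l_p) +
              f$m_u * (f$L_l + f$l_u) * (f$L_f + f$L_l + f$L_p + f$l_u)) /
      s$l_b
  )
  structure(out, class = "composite_inertias")
}

#' @export
print.com_subject <- function(x, ...) {
  cat(sprintf("Subject: M = %.1f kg, H = %.2f m (g = %.2f m/s^2)\n",
              x$M, x$H, x$g))
  invisible(x)
}

#' @export
print.segment_params <- function(x, ...) {
  cat("Segment parameters (anthropometric regression)\n")
  cat(sprintf("  subject: M = %.1f kg, H = %.2f m\n",
              x$subject$M, x$subject$H))
  cat("  sagittal:\n")
  print(round(x$sagittal, 4))
  cat("  frontal:\n")
  print(round(x$frontal, 4))
  invisible(x)
}
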
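# Shared fixtures: a reference subject and parameter sets.

ref_subject <- com_subject(70, 1.75)
ref_params <- segment_parameters(ref_subject)
ref_inertias <- composite_inertias(ref_params)

# A parameter set whose whole-body lever and composite inertia are made
# exactly consistent with the two-segment composition.  The tabulated
# coefficients are rounded independently, so the single- and double-pendulum
# models they imply disagree at the ~0.1% level; tests of exact
# single/double-model consistency need this self-consistent variant.
consistent_params <- function(subject = ref_subject) {
  p <- segment_parameters(subject)
  s <- as.list(p$sagittal)
  ci <- composite_inertias(p)
  lb <- (s$m_1 * s$l_1 + s$m_2 * (s$L_1 + s$l_2)) / s$m_b
  Cs <- (ci$J_x1 * s$l_1 + ci$J_x2 * (s$L_1 + s$l_2)) / lb
  Jb <- (Cs - s$m_b * (s$L_f + lb)) * lb
  p$sagittal[["l_b"]] <- lb
  p$sagittal[["J_b"]] <- Jb
  p
}

# Rebuild a trial object with selected fields replaced (e.g. head = NULL to
# force the IMU pathway).
trial_with <- function(trial, ...) {
  structure(utils::modifyList(unclass(trial), list(...)),
            class = "com_trial")
}
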
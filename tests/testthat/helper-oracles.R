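# Independent oracles, kept deliberately separate from the package's code
# paths: a scalar single-file transcription of the Rodgers-Rowland weak-base
# partition equations, and closed-form one-compartment PK expressions.

# Rodgers-Rowland weak-base Kp, transcribed independently as plain scalar
# arithmetic from the published equations. Composition is passed as plain
# scalars. Validated in test-distribution.R against a hand-computed worked
# example before being used as the cross-check for the package function.
rr_weak_base_kp_oracle <- function(logP, pKa, fu,
                                   f_ew, f_iw, f_nl, f_np, alb_ratio,
                                   ph_iw = 7.0, ph_p = 7.4,
                                   f_nl_p = 0.0023, f_np_p = 0.0013,
                                   adipose = FALSE) {
  P <- 10^logP
  P_nl <- if (adipose) 10^(1.115 * logP - 1.35) else P
  Y <- 1 + 10^(pKa - ph_p)
  X <- 1 + 10^(pKa - ph_iw)
  water <- f_ew + f_iw * X / Y
  lipid <- (P_nl * f_nl + (0.3 * P + 0.7) * f_np) / Y
  lipid_p <- (P * f_nl_p + (0.3 * P + 0.7) * f_np_p) / Y
  prot <- alb_ratio * max(0, 1 / fu - 1 - lipid_p)
  (water + lipid + prot) * fu
}

# closed-form one-compartment iv bolus
onecomp_conc <- function(t, dose_umol, v, cl) {
  dose_umol / v * exp(-cl / v * t)
}

# superposition for repeated iv bolus dosing
onecomp_superposition <- function(t, dose_umol, v, cl, tau, n_doses) {
  ke <- cl / v
  conc <- numeric(length(t))
  for (i in seq_len(n_doses)) {
    t0 <- (i - 1) * tau
    on <- t >= t0
    conc[on] <- conc[on] + dose_umol / v * exp(-ke * (t[on] - t0))
  }
  conc
}
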
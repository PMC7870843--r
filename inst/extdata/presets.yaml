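# Calibrated default parameter sets, one per model variant (and per link
# regime for the ideal circuit). Frozen after a one-time numerical
# calibration: each preset reproduces its reference phase-plane topology at
# the reference induction (see reference_protocol()):
#   CBS_IDEAL/WEAK_M1_TO_M2  -> stable fates {LL, LH, HH}
#   CBS_IDEAL/WEAK_M2_TO_M1  -> stable fates {LL, HL, HH}
#   CBS_IDEAL/BALANCED       -> stable fates {LL, HH}
#   CBS_COMPETITION          -> stable fates {LL, LH, HL}, coactivation lost
#   SBS_COMPETITION          -> stable fates {LH, HL, HH} at the printed doses
#   CBS_HYBRID_TETR          -> aTc sweep at fixed L-ara: LH (no aTc) -> HL
#   TWO_STRAIN_CBS           -> L-ara ladder LL -> HL -> HH (coactivation kept)
# Units: concentrations in arbitrary expression units, time in hours, doses
# in % w/v (L-ara), molar (C6), ng/ml (aTc).
#
# The CBS_COMPETITION module-2 (Plux) leak is far below the module-1 (Para)
# leak: tristability with both single-winner states requires the losing
# module's basal expression to stay below its own switching threshold under
# the winner's drive.

CBS_IDEAL:
  WEAK_M1_TO_M2: {alpha1: 100, alpha2: 100, beta1: 0.012, beta2: 0.012,
                  K1: 20, K2: 20, n1: 2, n2: 2, delta1: 1, delta2: 1,
                  c12: 0.015, c21: 0.05, lambda1: 0, lambda2: 0,
                  Ka: 9.5e-4, na: 2, Kc: 2.0e-8, nc: 2,
                  Kt: 20, nt: 2, tetR_strength: 0, copy_scale: 1}
  WEAK_M2_TO_M1: {alpha1: 100, alpha2: 100, beta1: 0.008, beta2: 0.015,
                  K1: 20, K2: 20, n1: 2, n2: 2, delta1: 1, delta2: 1,
                  c12: 1.1, c21: 0.008, lambda1: 0, lambda2: 0,
                  Ka: 9.5e-4, na: 2, Kc: 2.0e-8, nc: 2,
                  Kt: 20, nt: 2, tetR_strength: 0, copy_scale: 1}
  BALANCED:      {alpha1: 100, alpha2: 100, beta1: 0.012, beta2: 0.012,
                  K1: 20, K2: 20, n1: 2, n2: 2, delta1: 1, delta2: 1,
                  c12: 0.05, c21: 0.05, lambda1: 0, lambda2: 0,
                  Ka: 9.5e-4, na: 2, Kc: 2.0e-8, nc: 2,
                  Kt: 20, nt: 2, tetR_strength: 0, copy_scale: 1}

CBS_COMPETITION: {alpha1: 190, alpha2: 180, beta1: 0.013, beta2: 2.0e-4,
                  K1: 33, K2: 43, n1: 2, n2: 4, delta1: 1, delta2: 2,
                  c12: 3.3, c21: 0.006, lambda1: 2, lambda2: 2,
                  Ka: 6.0e-4, na: 2, Kc: 2.0e-8, nc: 2,
                  Kt: 20, nt: 2, tetR_strength: 0, copy_scale: 1}

# Separated switches: coupling only through the shared pool; both inducers
# half-saturate below their printed reference doses, with the C6 response
# slightly ahead of the L-ara response there (module 2 activates faster at
# simultaneous addition).
SBS_COMPETITION: {alpha1: 100, alpha2: 100, beta1: 0.05, beta2: 0.05,
                  K1: 20, K2: 20, n1: 2, n2: 2, delta1: 1, delta2: 1,
                  c12: 0, c21: 0, lambda1: 1, lambda2: 1,
                  Ka: 4.3e-4, na: 2, Kc: 2.02e-8, nc: 2,
                  Kt: 20, nt: 2, tetR_strength: 0, copy_scale: 1}

# Hybrid Para/tet link: TetR suppresses the module-1 to module-2 connection
# about 10-fold at zero aTc, relieved with half-maximal aTc 20 ng/ml.
CBS_HYBRID_TETR: {alpha1: 190, alpha2: 180, beta1: 0.03, beta2: 3.0e-3,
                  K1: 33, K2: 43, n1: 2, n2: 3, delta1: 1, delta2: 1,
                  c12: 2.7, c21: 0.006, lambda1: 2, lambda2: 2,
                  Ka: 2.5e-4, na: 2, Kc: 2.0e-8, nc: 2,
                  Kt: 20, nt: 2, tetR_strength: 9, copy_scale: 1}

# Two-strain division of labor: no module-2 to module-1 link (AraC cannot
# travel between cells) and per-strain resource pools.
TWO_STRAIN_CBS:  {alpha1: 100, alpha2: 100, beta1: 0.015, beta2: 0.01,
                  K1: 20, K2: 20, n1: 2, n2: 2, delta1: 1, delta2: 1,
                  c12: 2.3, c21: 0, lambda1: 1, lambda2: 1,
                  Ka: 9.5e-4, na: 2, Kc: 2.0e-8, nc: 2,
                  Kt: 20, nt: 2, tetR_strength: 0, copy_scale: 1}
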
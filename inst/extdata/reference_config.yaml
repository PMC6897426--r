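# Reference standing-balance scenario: 50% of critical ankle stiffness,
# 0.14 s neural delay, critically damped PD feedback.
plant:
  tau_m0: 0.3192754284987137   # 1/sqrt(9.81) s
  k_frac: 0.5
  d_mech: 0.0
  tau_delay: 0.14
controller:
  kind: PD
  critical: true
simulation:
  horizon: 6.0
  theta0: 1.0
  thetadot0: 0.0
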
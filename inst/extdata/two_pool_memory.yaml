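circuit:
  type: two_pool
  inhibition: 3
  self_excitation: 0
  local_fatigue: 1.2
  nonlocal_fatigue: 0
  tau_a_ms: 3000
  tau_s_ms: 3000
  ms_per_tau: 5
gain:
  variant: hard
integrator:
  dt: 0.05
protocol:
  T_frame_ms: 105
  n_frames: 60
  start_parity: UR-LL
  pulse:
    S_on: 1
    width_ms: 20
  background:
    mode: fixed
    S_off: 0.12
init:
  kick_pool: 1
  kick_eps: 0.001
seed: 1
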
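# Demo: archaeal two-state bending kinetics, small scale
seed: 42
stages: [simulate, idealize, kinetics]
simulate:
  n_traces: 8
  duration: 20          # s per trace
  n_states: 2
  state_E: [0.25, 0.49]
  dwell_means: [2.0, 0.5]   # s (fast demo kinetics)
  frame_period: 0.02        # s
  e_noise_sd: 0.05
idealize:
  K: 2
  n_restarts: 4
kinetics:
  topology: two-state
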
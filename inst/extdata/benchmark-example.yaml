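# Example experiment configuration for the oclr command line.
#
# `spec` describes the curriculum the teacher must complete:
spec:
  n_levels: 10      # N: length of the full action sequence
  T_attempts: 10    # T: episodes per teacher-student interaction
  tau: 0.85         # target success rate on the full task
  budget: 1500      # interactions before giving up
  beta: 0.1         # EMA decay of the success-rate tracker

# `student` gives the hidden ground truth used by `ocl simulate`:
student:
  n_steps: 10
  eps: -1.5         # innate bias (log-odds); scalar or per-step list
  alpha: 0.1        # TD learning rate

# `ocl benchmark` sweeps these:
teachers: [inc, adp, rand]
eps_grid: [-1.0, -1.5, -2.0]
repeats: 10

# Optional override of the adaptive teacher's thresholds:
# policy:
#   theta_inc: 0.81
#   mu: -0.084
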
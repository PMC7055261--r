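# Example session configuration for the mtlmem pipeline.
# Each session entry accepts any generator_config() field; `timing:` and
# `behavior:` sub-maps are forwarded to task_timing() / behavior_params().
alpha: 0.05
n_boot: 1000
sessions:
  - session_id: C01_s1
    variant: 1
    seed: 101
    n_units: 12
    frac_vs: 0.25
    frac_ms: 0.15
    subject_site: C
  - session_id: T02_s1
    variant: 2
    seed: 202
    n_units: 8
    subject_site: T
    behavior:
      d_prime: 1.2
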
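# Example configuration for the munoise CLI / run_all().
# Omitted keys take the default tibialis anterior pool values.
n_units: 200
rp: 25
u1: 0.01
ur: 0.8
recruitment_scheme: new_scheme
cv_mode: input_dependent
levels: [0.05, 0.2, 0.4, 0.6, 0.8, 1.0]
n_trials: 3
use_see: true
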
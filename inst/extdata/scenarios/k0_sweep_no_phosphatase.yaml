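name: k0_sweep_no_phosphatase
model: mm
overrides:
  X: 1.0
  k2: 0.0
  k4: 1.0
axis: k0
from: 0.01
to: 100.0
step_pct: 1.0
readouts:
- R
- Rp
- Rtot_free
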
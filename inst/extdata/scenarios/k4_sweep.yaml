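name: k4_sweep
model: mm
overrides:
  k4:
  - 0.0001
  - 0.001
  - 0.01
  - 0.1
  - 1.0
axis: X
from: 0.01
to: 100.0
step_pct: 1.0
readouts:
- R
- Rp
- Rtot_free
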
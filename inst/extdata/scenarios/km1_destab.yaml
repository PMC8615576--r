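name: km1_destab
model: mm
overrides:
  k4: 0.1
  Km1:
  - 0.1
  - 1.0
  - 10.0
  - 100.0
  - 1000.0
axis: X
from: 0.01
to: 10000.0
step_pct: 1.0
readouts:
- R
- Rp
- Rtot_free
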
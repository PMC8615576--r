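name: closed_cycle
model: mm
overrides:
  k0: 0.0
  k3: 0.0
  k4: 0.0
axis: X
from: 0.01
to: 100.0
step_pct: 1.0
readouts:
- R
- Rp
- Rtot_free
total: 100.0
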
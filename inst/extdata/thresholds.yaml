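# Quantitative AS grading thresholds (editable; validated at load).
# Each parameter lists disjoint, exhaustive intervals over [0, Inf).
# Boundary ties at severe-defining cut-points resolve toward severity:
# AVA exactly 1.0 cm2 -> severe; mean gradient exactly 40 mmHg -> severe.
ava_cm2:
  - {lower: 0.0, upper: 0.6, lower_closed: true,  upper_closed: true,  grade: critical}
  - {lower: 0.6, upper: 1.0, lower_closed: false, upper_closed: true,  grade: severe}
  - {lower: 1.0, upper: 1.5, lower_closed: false, upper_closed: true,  grade: moderate}
  - {lower: 1.5, upper: 2.0, lower_closed: false, upper_closed: true,  grade: mild}
  - {lower: 2.0, upper: .inf, lower_closed: false, upper_closed: false, grade: none}
mean_gradient_mmhg:
  - {lower: 0.0,  upper: 10.0, lower_closed: true, upper_closed: false, grade: none}
  - {lower: 10.0, upper: 20.0, lower_closed: true, upper_closed: false, grade: mild}
  - {lower: 20.0, upper: 40.0, lower_closed: true, upper_closed: false, grade: moderate}
  - {lower: 40.0, upper: 60.0, lower_closed: true, upper_closed: false, grade: severe}
  - {lower: 60.0, upper: .inf, lower_closed: true, upper_closed: false, grade: critical}
peak_velocity_ms:
  - {lower: 0.0, upper: 2.0, lower_closed: true, upper_closed: false, grade: none}
  - {lower: 2.0, upper: 3.0, lower_closed: true, upper_closed: false, grade: mild}
  - {lower: 3.0, upper: 4.0, lower_closed: true, upper_closed: false, grade: moderate}
  - {lower: 4.0, upper: 5.0, lower_closed: true, upper_closed: false, grade: severe}
  - {lower: 5.0, upper: .inf, lower_closed: true, upper_closed: false, grade: critical}
use_peak_velocity: true
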
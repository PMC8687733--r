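name: slow-ramp-cold
baseline_temp: 30.0
area_mm2: 8.0
total_duration: 9.6
stimulus_onsets: 0.0
segments:
- start_time: 0.0
  target_temp: 0.0
  ramp_rate: 4.0
  hold_duration: 0.0
- start_time: 7.5
  target_temp: 30.0
  ramp_rate: 300.0
  hold_duration: 2.0
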
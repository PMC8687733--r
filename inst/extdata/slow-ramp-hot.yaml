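name: slow-ramp-hot
baseline_temp: 30.0
area_mm2: 8.0
total_duration: 9.573333333333
stimulus_onsets: 0.0
segments:
- start_time: 0.0
  target_temp: 52.0
  ramp_rate: 3.0
  hold_duration: 0.166666666667
- start_time: 7.5
  target_temp: 30.0
  ramp_rate: 300.0
  hold_duration: 2.0
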
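name: iterative-single-hot-52C-1000ms-n30-1Hz
baseline_temp: 30.0
area_mm2: 8.0
total_duration: 32.073333333333
stimulus_onsets:
- 0.0
- 1.0
- 2.0
- 3.0
- 4.0
- 5.0
- 6.0
- 7.0
- 8.0
- 9.0
- 10.0
- 11.0
- 12.0
- 13.0
- 14.0
- 15.0
- 16.0
- 17.0
- 18.0
- 19.0
- 20.0
- 21.0
- 22.0
- 23.0
- 24.0
- 25.0
- 26.0
- 27.0
- 28.0
- 29.0
segments:
- start_time: 0.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 1.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 2.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 3.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 4.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 5.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 6.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 7.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 8.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 9.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 10.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 11.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 12.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 13.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 14.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 15.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 16.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 17.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 18.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 19.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 20.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 21.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 22.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 23.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 24.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 25.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 26.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 27.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 28.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 29.0
  target_temp: 52.0
  ramp_rate: 300.0
  hold_duration: 0.926666666667
- start_time: 30.0
  target_temp: 30.0
  ramp_rate: 300.0
  hold_duration: 2.0
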
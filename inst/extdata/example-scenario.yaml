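# Two clean crossings plus sparse flicker noise; for
#   fishcurtain simulate example-scenario.yaml --out hour.txt --seed 1
stream_length_s: 15
fish:
  - {length: 16.5, height: 6.4, depth_center: 29.25, speed: 30, direction: 1, entry_time: 2}
  - {length: 13.0, height: 6.4, depth_center: 24.0, speed: 25, direction: -1, entry_time: 9}
noise:
  spurious_rate: 0.5
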
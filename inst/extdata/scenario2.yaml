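name: scenario2
annual_change: -0.05
mode: relative
start_year: 2020
end_year: 2036
target_factor: obesity
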
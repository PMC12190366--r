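# Deadline-free calibration run: the full 121-trial task (one unscored
# lead-in, 30 scored trials per condition) with unlimited response time,
# used to measure per-condition required times.
protocol: calibration
key_variant: A
pressure_factor: 1.25
rounding_quantum_ms: 100
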
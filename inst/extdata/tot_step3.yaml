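# 30-minute time-on-task fatigue-induction protocol:
# 6 timed blocks, balanced 1:1:1:1 conditions, VAS after each block
# (baseline before block 1), 3-minute PVT before and after.
protocol: tot_induction
n_blocks: 6
block_duration_ms: 300000
isi_feedback_ms: 500
key_variant: A
available_times: [2300, 3000, 2600, 2800]   # ms, conditions 1-4
pvt_duration_ms: 180000
pvt_interval_bounds: [2000, 10000]          # ms, includes 1 s feedback
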
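# Blocked workload-comparison protocol: 8 blocks x 8 scored trials
# (each condition twice, pseudo-random), 20 s rest between blocks,
# workload scale after the task; practice gate 90%.
protocol: hmw_blocks
n_blocks: 8
per_condition_per_block: 2
rest_duration_ms: 20000
isi_feedback_ms: 500
key_variant: A
available_times: [2300, 3000, 2600, 2800]   # ms, conditions 1-4
practice_accuracy_gate: 0.90
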
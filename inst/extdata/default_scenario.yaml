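# Default simulation scenario: 8-h night of 30-s epochs scored by a
# three-stage (type II) device with a 20% uniform mislabel rate.
n_epochs: 960
epoch_duration: 30
start_time: "22:30:00"
dev_type: "II"
mislabel: 0.2
lag_epochs: 0
missing_prob: 0.0
seed: 1
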
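# dendiam model set: striatal spiny projection neurons, Lai archive only
cell_type: striatal SPN (Lai)
[model]
tree_label: generic
node_class: initial
features: TD
coefficients: 0.250
adj_r2: 0.786
n_train: NA
[model]
tree_label: generic
node_class: branching_child
features: PD
coefficients: 0.861
adj_r2: 0.967
n_train: NA
[model]
tree_label: generic
node_class: continuing
features: PD
coefficients: 0.997
adj_r2: 0.999
n_train: NA
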
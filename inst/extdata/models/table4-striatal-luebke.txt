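# dendiam model set: striatal spiny projection neurons, Luebke archives
cell_type: striatal SPN (Luebke)
[model]
tree_label: generic
node_class: initial
features: TL
coefficients: 0.003
adj_r2: 0.75
n_train: NA
[model]
tree_label: generic
node_class: branching_child
features: PD
coefficients: 0.934
adj_r2: 0.907
n_train: NA
[model]
tree_label: generic
node_class: continuing
features: PD
coefficients: 0.976
adj_r2: 0.962
n_train: NA
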
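# dendiam model set: striatal spiny projection neurons, pooled archives
# (basal-like dendrites; generic tree label applies to every tree)
cell_type: striatal SPN
[model]
tree_label: generic
node_class: initial
features: TL LP
coefficients: 0.00114 0.00713
adj_r2: 0.8126
n_train: NA
[model]
tree_label: generic
node_class: branching_child
features: PD
coefficients: 0.921
adj_r2: 0.915
n_train: NA
[model]
tree_label: generic
node_class: continuing
features: PD
coefficients: 0.9834
adj_r2: 0.9753
n_train: NA
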
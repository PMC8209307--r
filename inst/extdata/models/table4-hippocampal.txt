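# dendiam model set: hippocampal pyramidal cells (CA1 + CA3 pooled)
# Published node-class-specific diameter equations; adj_r2 is the
# training adjusted R^2 reported with each equation.
cell_type: hippocampal pyramidal
[model]
tree_label: apical
node_class: initial
features: PD LP
coefficients: 0.0755 0.0056
adj_r2: 0.7216
n_train: NA
[model]
tree_label: apical
node_class: branching_child
features: PD LP
coefficients: 0.2598 0.0034
adj_r2: 0.9151
n_train: NA
[model]
tree_label: apical
node_class: continuing
features: PD
coefficients: 0.9968
adj_r2: 0.9993
n_train: NA
[model]
tree_label: basal
node_class: initial
features: PD PS
coefficients: -0.5964 0.3535
adj_r2: 0.7246
n_train: NA
[model]
tree_label: basal
node_class: branching_child
features: PD PS
coefficients: 0.6351 0.0033
adj_r2: 0.9340
n_train: NA
[model]
tree_label: basal
node_class: continuing
features: PD
coefficients: 0.9926
adj_r2: 0.9984
n_train: NA
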
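# dendiam model set: cerebellar Purkinje cells (apical-like dendrites;
# the generic tree label applies the equations to every dendritic tree)
cell_type: cerebellar Purkinje
[model]
tree_label: generic
node_class: initial
features: PD
coefficients: 0.2331
adj_r2: 0.8879
n_train: NA
[model]
tree_label: generic
node_class: branching_child
features: PD TL
coefficients: 0.6842 0.6842
adj_r2: 0.8934
n_train: NA
note: TL coefficient shipped verbatim from the published equation; 0.6842 um per um of downstream arbor length yields implausibly large diameters on realistic arbors - consider refitting this model from data.
[model]
tree_label: generic
node_class: continuing
features: PD
coefficients: 1.0121
adj_r2: 0.9555
n_train: NA
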
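histotype	n_samples
melanoma	137
mammary_carcinoma	136
b_cell_lymphoma	103
osteosarcoma	98
t_cell_lymphoma	65
hemangiosarcoma	64
glioma	52
mast_cell_tumor	28
pulmonary_adenocarcinoma	5
urinary_carcinoma	4
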
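gene_id	gene_class	cell_type
acdh-1	coding	early_middle_intestine
Y38F1A.6	coding	early_middle_intestine
inx-15	coding	early_middle_intestine
nep-17	coding	early_middle_intestine
cpz-1	coding	early_middle_intestine
nep-22	coding	early_middle_intestine
T09E11.11	ncrna	early_middle_intestine
T21H3.1	coding	late_posterior_intestine
asp-5	coding	late_posterior_intestine
tts-1	ncrna	late_posterior_intestine
B0250.3	ncrna	late_posterior_intestine
nlp-28	coding	late_anterior_intestine
nspe-1	coding	late_anterior_intestine
fipr-2	coding	late_anterior_intestine
F57F5.1	coding	late_anterior_intestine
osm-11	coding	late_anterior_intestine
grl-21	coding	late_anterior_intestine
T04F8.8	coding	late_anterior_intestine
cnc-11	coding	late_anterior_intestine
F45E4.5	coding	late_anterior_intestine
Y7A9A.79	ncrna	late_anterior_intestine
F56C9.8	coding	pharynx
linc-22	ncrna	pharynx
C44H4.10	ncrna	hypodermis
K02E7.5	ncrna	hypodermis
clec-87	coding	early_embryonic
his-24	coding	early_embryonic
lbp-1	coding	early_embryonic
mig-6	coding	early_embryonic
T02G5.4	ncrna	early_embryonic
C33D9.5	ncrna	early_embryonic
F07H5.5	ncrna	early_embryonic
anr-1	ncrna	early_embryonic
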
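exposure	mediator	beta_total	se_total	beta1	se1	beta2	se2	reported_proportion_pct
Bifidobacterium kashiwanohense	CD40 on monocytes	-0.087	0.035	0.133	0.052	-0.018	0.008	2.82
Bifidobacterium kashiwanohense	CD45 on CD33+ HLA-DR+ CD14-	-0.087	0.035	0.211	0.078	-0.053	0.026	12.87
GCA-900066755 sp900066755	CD45 on CD33- HLA-DR+	0.072	0.029	0.155	0.077	0.018	0.009	3.94
Geminocystis	Terminally Differentiated CD4+ T cell	0.064	0.026	-0.148	0.056	-0.050	0.021	11.55
Saccharofermentanaceae	CD40 on monocytes	-0.133	0.052	0.174	0.073	-0.018	0.008	2.35
Saccharofermentanaceae	Central Memory CD4+ T cell	-0.133	0.052	0.144	0.068	-0.054	0.024	5.76
Saccharofermentanaceae	CD28 on CD28+ CD45RA+ CD8+ T cell	-0.133	0.052	0.160	0.073	-0.042	0.018	5.00
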
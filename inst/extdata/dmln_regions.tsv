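label	hemisphere	structure
Cg1_L	left	cingulate cortex area 1
Cg1_R	right	cingulate cortex area 1
Cg2_L	left	cingulate cortex area 2
Cg2_R	right	cingulate cortex area 2
OFC_L	left	orbitofrontal cortex
OFC_R	right	orbitofrontal cortex
prL_L	left	prelimbic cortex
prL_R	right	prelimbic cortex
V1_L	left	primary visual cortex
V1_R	right	primary visual cortex
V2_L	left	secondary visual cortex
V2_R	right	secondary visual cortex
RS_L	left	retrosplenial cortex
RS_R	right	retrosplenial cortex
CA1_L	left	hippocampus CA1
CA1_R	right	hippocampus CA1
CA2_L	left	hippocampus CA2
CA2_R	right	hippocampus CA2
CA3_L	left	hippocampus CA3
CA3_R	right	hippocampus CA3
TeA_L	left	auditory/temporal association cortex
TeA_R	right	auditory/temporal association cortex
PtA_L	left	parietal association cortex
PtA_R	right	parietal association cortex
BFB	midline	basal forebrain
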
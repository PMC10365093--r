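# synthetic placeholder centroids (RAS mm); not measured anatomy
label	hemisphere	x_mm	y_mm	z_mm
Left-Hippocampus	left	-28	-22	-14
Left-Caudate	left	-13	12	12
Left-Amygdala	left	-24	-4	-20
Left-Putamen	left	-26	2	2
Left-Lateral-Occipital	left	-32	-86	6
Left-Inferior-Temporal	left	-50	-30	-26
Left-Precentral	left	-38	-12	52
Left-Medial-Orbitofrontal	left	-7	36	-14
Right-Hippocampus	right	28	-22	-14
Right-Caudate	right	13	12	12
Right-Amygdala	right	24	-4	-20
Right-Putamen	right	26	2	2
Right-Lateral-Occipital	right	32	-86	6
Right-Inferior-Temporal	right	50	-30	-26
Right-Precentral	right	38	-12	52
Right-Medial-Orbitofrontal	right	7	36	-14
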
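pollinator	measure	trait	z_star	ci_lower	ci_upper	range_min	range_max
butterfly	visits	scent_intensity	-0.217	-0.430	0.150	-0.689	3.458
butterfly	visits	stem_height	0.843	-0.037	5.143	-3.024	2.638
butterfly	acquisition	tepal_color	-0.883	-1.666	-0.190	-5.380	0.359
butterfly	acquisition	scent_intensity	0.409	-0.297	2.496	-1.259	2.588
hawkmoth	donation	scent_intensity	-0.036	-1.821	1.370	-0.643	5.672
butterfly	combined	scent_intensity	-0.338	-0.462	0.019	-0.689	3.458
butterfly	combined	corolla_direction	0.001	-0.352	0.241	-3.751	1.559
butterfly	combined	asd	1.000	0.222	2.766	-2.201	4.386
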
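pollinator	measure	trait	mode	direction
butterfly	visits	tepal_color	none	
butterfly	visits	scent_intensity	stabilizing	
butterfly	visits	corolla_direction	none	
butterfly	visits	stem_height	stabilizing_or_directional	increasing
butterfly	visits	asd	none	
butterfly	acquisition	tepal_color	stabilizing	
butterfly	acquisition	scent_intensity	stabilizing	
butterfly	acquisition	corolla_direction	none	
butterfly	acquisition	stem_height	none	
butterfly	acquisition	asd	directional	decreasing
butterfly	donation	tepal_color	none	
butterfly	donation	scent_intensity	none	
butterfly	donation	corolla_direction	none	
butterfly	donation	stem_height	none	
butterfly	donation	asd	none	
butterfly	combined	tepal_color	none	
butterfly	combined	scent_intensity	stabilizing	
butterfly	combined	corolla_direction	stabilizing	
butterfly	combined	stem_height	none	
butterfly	combined	asd	disruptive	
hawkmoth	visits	tepal_color	directional	increasing
hawkmoth	visits	scent_intensity	none	
hawkmoth	visits	corolla_direction	none	
hawkmoth	visits	stem_height	none	
hawkmoth	visits	asd	none	
hawkmoth	acquisition	tepal_color	none	
hawkmoth	acquisition	scent_intensity	none	
hawkmoth	acquisition	corolla_direction	none	
hawkmoth	acquisition	stem_height	none	
hawkmoth	acquisition	asd	directional	decreasing
hawkmoth	donation	tepal_color	none	
hawkmoth	donation	scent_intensity	stabilizing_or_directional	decreasing
hawkmoth	donation	corolla_direction	none	
hawkmoth	donation	stem_height	none	
hawkmoth	donation	asd	none	
hawkmoth	combined	tepal_color	none	
hawkmoth	combined	scent_intensity	none	
hawkmoth	combined	corolla_direction	none	
hawkmoth	combined	stem_height	none	
hawkmoth	combined	asd	none	
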
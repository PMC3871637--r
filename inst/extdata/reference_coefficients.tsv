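pollinator	measure	trait	beta_mean	beta_sd	beta_lower	beta_upper	gamma_mean	gamma_sd	gamma_lower	gamma_upper
butterfly	visits	tepal_color	0.698	0.523	-0.274	1.778	-0.461	0.505	-1.518	0.470
butterfly	visits	scent_intensity	-1.665	1.446	-5.140	0.521	-3.842	1.909	-8.312	-1.015
butterfly	visits	corolla_direction	-0.020	0.172	-0.373	0.312	-0.211	0.140	-0.517	0.022
butterfly	visits	stem_height	0.452	0.183	0.088	0.822	-0.268	0.143	-0.569	-0.013
butterfly	visits	asd	-0.043	0.163	-0.359	0.291	0.000	0.089	-0.359	0.159
hawkmoth	visits	tepal_color	1.150	0.411	0.358	1.970	0.259	0.277	-0.287	0.824
hawkmoth	visits	scent_intensity	0.714	0.381	-0.023	1.453	-0.288	0.162	-0.617	0.008
hawkmoth	visits	corolla_direction	0.155	0.151	-0.135	0.460	-0.202	0.120	-0.459	0.008
hawkmoth	visits	stem_height	-0.120	0.138	-0.400	0.152	0.044	0.074	-0.113	0.177
hawkmoth	visits	asd	0.145	0.159	-0.299	0.465	-0.090	0.100	-0.299	0.101
butterfly	acquisition	tepal_color	-3.177	1.674	-6.689	-0.110	-1.799	0.859	-3.662	-0.237
butterfly	acquisition	scent_intensity	0.938	0.536	-0.095	2.035	-1.146	0.662	-2.646	-0.044
butterfly	acquisition	corolla_direction	-0.473	0.483	-1.460	0.486	-0.675	0.435	-1.639	0.050
butterfly	acquisition	stem_height	0.182	0.421	-0.639	1.015	-0.285	0.386	-1.116	0.420
butterfly	acquisition	asd	-0.820	0.369	-1.637	-0.171	-0.116	0.487	-1.150	0.700
butterfly	acquisition	visits_covariate	1.004	0.773	-0.451	2.511				
hawkmoth	acquisition	tepal_color	-0.682	1.045	-2.772	1.390	-0.111	0.264	-0.649	0.377
hawkmoth	acquisition	scent_intensity	-1.362	0.969	-3.538	0.406	0.100	0.247	-0.421	0.582
hawkmoth	acquisition	corolla_direction	-0.313	0.402	-1.105	0.480	-0.141	0.295	-0.746	0.418
hawkmoth	acquisition	stem_height	-0.325	0.493	-1.343	0.587	-0.666	0.402	-1.528	0.018
hawkmoth	acquisition	asd	-1.164	0.398	-2.044	-0.479	0.018	0.367	-0.755	0.734
hawkmoth	acquisition	visits_covariate	-2.181	1.996	-6.829	1.043				
butterfly	donation	tepal_color	0.479	2.293	-4.588	4.733	-0.223	0.945	-2.427	1.319
butterfly	donation	scent_intensity	-0.050	0.871	-1.833	1.768	-0.559	0.988	-2.889	1.022
butterfly	donation	corolla_direction	-0.023	0.587	-1.165	1.167	-0.342	0.498	-1.380	0.602
butterfly	donation	stem_height	0.537	0.590	-0.597	1.731	0.007	0.383	-0.784	0.723
butterfly	donation	asd	-0.153	0.467	-1.140	0.715	0.709	0.419	-0.064	1.635
butterfly	donation	visits_covariate	1.252	1.073	-0.658	3.604				
hawkmoth	donation	tepal_color	0.003	1.890	-4.075	3.465	-0.316	1.227	-3.045	1.718
hawkmoth	donation	scent_intensity	-0.182	1.332	-2.952	2.277	-2.507	1.749	-6.661	-0.129
hawkmoth	donation	corolla_direction	-0.115	0.375	-0.837	0.623	0.020	0.258	-0.525	0.511
hawkmoth	donation	stem_height	0.776	0.522	-0.087	1.910	-0.434	0.327	-1.126	0.154
hawkmoth	donation	asd	0.673	0.432	-0.084	1.584	-0.164	0.281	-0.720	0.379
hawkmoth	donation	visits_covariate	1.643	0.656	0.430	3.019				
butterfly	combined	tepal_color	2.157	1.815	-1.145	6.099	-2.999	2.832	-9.876	1.186
butterfly	combined	scent_intensity	-14.286	9.937	-38.232	0.178	-21.111	11.619	-49.508	-3.828
butterfly	combined	corolla_direction	0.002	0.335	-0.630	0.685	-1.253	0.362	-2.029	-0.612
butterfly	combined	stem_height	0.386	0.292	-0.174	0.945	0.028	0.240	-0.472	0.488
butterfly	combined	asd	-0.678	0.240	-1.083	-0.303	0.339	0.123	0.098	0.591
hawkmoth	combined	tepal_color	1.357	0.840	-0.150	3.166	0.187	0.554	-0.887	1.262
hawkmoth	combined	scent_intensity	-0.124	0.802	-1.676	1.417	-0.192	0.355	-0.956	0.463
hawkmoth	combined	corolla_direction	-0.271	0.226	-0.701	0.176	-0.268	0.188	-0.669	0.056
hawkmoth	combined	stem_height	0.041	0.266	-0.471	0.572	-0.244	0.193	-0.633	0.114
hawkmoth	combined	asd	-0.208	0.216	-0.619	0.217	0.021	0.158	-0.304	0.321
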
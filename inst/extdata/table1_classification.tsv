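cnv_id	trait	p_fdr	label
CNV1	MY	2.56E-06	IN*
CNV1	FY	2.12E-08	IN*
CNV1	PY	0.0246	IN*
CNV1	FP	0.0657	
CNV1	PP	3.96E-21	NN
CNV2	MY	8.53E-07	IN
CNV2	FY	1.32E-07	IN
CNV2	PY	0.0020	IN
CNV2	FP	0.8913	
CNV2	PP	1.46E-09	NN
CNV3	MY	0.0810	
CNV3	FY	0.1375	
CNV3	PY	0.9468	
CNV3	FP	0.6499	
CNV3	PP	1.32E-32	IN*
CNV4	MY	1.26E-09	IN**
CNV4	FY	1.99E-08	IN**
CNV4	PY	4.06E-09	IN**
CNV4	FP	0.1334	
CNV4	PP	0.0756	
CNV5	MY	0.2506	
CNV5	FY	0.0473	IN*
CNV5	PY	0.2410	
CNV5	FP	0.0758	
CNV5	PP	0.0008	IN*
CNV6	MY	0.0008	NN
CNV6	FY	1.91E-06	NN
CNV6	PY	4.95E-05	IN
CNV6	FP	0.0004	NN
CNV6	PP	6.95E-22	NN
CNV7	MY	0.0020	IN**
CNV7	FY	0.0001	IN**
CNV7	PY	0.0418	NN
CNV7	FP	0.2851	
CNV7	PP	1.38E-05	IN**
CNV8	MY	9.03E-10	IN*
CNV8	FY	5.38E-10	IN*
CNV8	PY	1.61E-06	IN*
CNV8	FP	1.0000	
CNV8	PP	9.35E-05	IN*
CNV9	MY	0.0005	IN**
CNV9	FY	2.50E-06	IN**
CNV9	PY	0.2701	
CNV9	FP	0.0049	NN
CNV9	PP	9.47E-18	IN
CNV10	MY	9.29E-12	IN
CNV10	FY	8.38E-12	IN
CNV10	PY	2.23E-07	IN*
CNV10	FP	1.0000	
CNV10	PP	0.0997	
CNV11	MY	3.81E-05	IN*
CNV11	FY	6.52E-05	IN*
CNV11	PY	0.0345	IN*
CNV11	FP	0.7610	
CNV11	PP	0.0037	IN
CNV12	MY	0.0006	IN*
CNV12	FY	0.1336	
CNV12	PY	0.5275	
CNV12	FP	3.70E-09	IN*
CNV12	PP	1.52E-22	NN
CNV13	MY		
CNV13	FY		
CNV13	PY		
CNV13	FP		
CNV13	PP		
CNV14	MY	0.1484	
CNV14	FY	0.5341	
CNV14	PY	0.7490	
CNV14	FP	0.0700	
CNV14	PP	0.0371	IN*
CNV15	MY		
CNV15	FY		
CNV15	PY		
CNV15	FP		
CNV15	PP		
CNV16	MY	0.2552	
CNV16	FY	0.8739	
CNV16	PY	0.0352	NN
CNV16	FP	0.0033	LD*
CNV16	PP	0.2416	
CNV17	MY	6.96E-07	IN*
CNV17	FY	2.87E-06	IN**
CNV17	PY	2.99E-05	IN*
CNV17	FP	0.4144	
CNV17	PP	0.9401	
CNV18	MY	0.0890	
CNV18	FY	2.02E-05	LD
CNV18	PY	0.0062	LD
CNV18	FP	1.79E-13	IN* + LD
CNV18	PP	6.21E-15	IN*
CNV19	MY	0.0032	IN*
CNV19	FY	3.53E-05	IN*
CNV19	PY	0.2698	
CNV19	FP	0.0061	IN*
CNV19	PP	0.0035	IN
CNV20	MY	0.9468	
CNV20	FY	0.8614	
CNV20	PY	0.6384	
CNV20	FP	1.0000	
CNV20	PP	0.0286	IN*
CNV21	MY	0.0798	
CNV21	FY	0.1692	
CNV21	PY	0.5656	
CNV21	FP	0.3360	
CNV21	PP	0.0433	IN + LD
CNV22	MY	0.6780	
CNV22	FY	0.4652	
CNV22	PY	0.3753	
CNV22	FP	0.9048	
CNV22	PP	0.0005	NN
CNV23	MY	0.0065	NN
CNV23	FY	0.0209	IN**
CNV23	PY	0.0008	IN**
CNV23	FP	0.5674	
CNV23	PP	7.60E-05	NN
CNV24	MY	0.0616	
CNV24	FY	0.0844	
CNV24	PY	0.6569	
CNV24	FP	0.8919	
CNV24	PP	6.98E-09	NN
CNV25	MY	4.43E-08	IN
CNV25	FY	1.58E-08	IN**
CNV25	PY	1.94E-05	IN**
CNV25	FP	0.9206	
CNV25	PP	0.4082	
CNV26	MY	0.8385	
CNV26	FY	0.7831	
CNV26	PY	0.8926	
CNV26	FP	0.9465	
CNV26	PP	2.51E-16	IN + LD
CNV28	MY	0.0016	LD* NS
CNV28	FY	1.70E-08	LD* NS
CNV28	PY	0.0008	LD* NS
CNV28	FP	2.21E-13	IN* + LD
CNV28	PP	0.0002	LD*
CNV29	MY	8.09E-07	IN + LD
CNV29	FY	2.03E-07	IN + LD
CNV29	PY	0.0007	IN + LD
CNV29	FP	0.7631	
CNV29	PP	3.02E-05	NN
CNV30	MY		
CNV30	FY		
CNV30	PY		
CNV30	FP		
CNV30	PP		
CNV31	MY	0.1197	
CNV31	FY	0.0159	IN
CNV31	PY	0.1152	
CNV31	FP	0.0773	
CNV31	PP	3.15E-05	IN**
CNV32	MY	9.08E-09	LD NS
CNV32	FY	3.95E-08	NN
CNV32	PY	0.0001	LD
CNV32	FP	0.5293	
CNV32	PP	4.20E-07	IN + LD
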
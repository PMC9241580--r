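variant_id	chrom	pos	effect_allele	other_allele	eaf	beta	se	pval	n
rs61813875	1	6000000	A	G	           0.146	            0.35	         0.00586	       2.23e-308	116863
rs12730935	6	31050000	G	A	            0.25	            0.08	         0.00478	        7.12e-63	116863
rs4713555	3	16000000	A	C	           0.127	          0.1545	         0.00621	       1.25e-136	116863
rs12188917	4	21000000	C	A	           0.415	          0.1559	          0.0042	       1.38e-301	116863
rs6419573	5	26000000	T	G	           0.248	          0.1414	         0.00479	        1.6e-191	116863
rs9000001	6	31000000	G	T	             0.3	            0.12	         0.00451	       5.55e-156	116863
rs9000002	7	36000000	T	C	           0.413	          0.1264	          0.0042	       5.59e-199	116863
rs9000003	8	41000000	C	T	           0.191	          0.2181	         0.00526	       2.23e-308	116863
rs9000004	9	46000000	A	G	           0.324	          0.0838	         0.00442	         3.7e-80	116863
rs9000005	10	51000000	G	A	           0.115	          0.1801	         0.00648	       5.24e-170	116863
rs9000006	11	56000000	A	C	           0.425	          0.1445	         0.00418	       7.29e-262	116863
rs9000007	12	61000000	C	A	           0.399	          0.1749	         0.00422	       2.23e-308	116863
rs9000008	13	66000000	T	G	           0.155	          0.2094	         0.00572	        2.1e-293	116863
rs9000009	14	71000000	G	T	           0.241	          0.1795	         0.00484	       4.59e-301	116863
rs9000010	15	76000000	T	C	           0.202	          0.2195	         0.00515	       2.23e-308	116863
rs9000011	16	81000000	C	T	           0.378	          0.2056	         0.00427	       2.23e-308	116863
rs9000012	17	86000000	A	G	           0.123	          0.2097	          0.0063	       6.22e-243	116863
rs9000013	18	91000000	G	A	           0.151	           0.207	         0.00578	       6.89e-281	116863
rs9000014	19	96000000	A	C	           0.418	          0.1652	         0.00419	       2.23e-308	116863
rs9000015	20	101000000	C	A	           0.377	          0.0521	         0.00427	        3.06e-34	116863
rs9000016	21	106000000	T	G	            0.17	          0.0855	         0.00551	        2.65e-54	116863
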
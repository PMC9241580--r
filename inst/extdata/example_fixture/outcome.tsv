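variant_id	chrom	pos	effect_allele	other_allele	eaf	beta	se	pval	n
rs61813875	1	6000000	A	G	           0.146	          0.0237	         0.00203	        1.71e-31	977323
rs12730935	6	31050000	G	A	            0.25	         0.00494	         0.00165	         0.00275	977323
rs4713555	3	16000000	A	C	           0.127	         0.01021	         0.00215	        2.05e-06	977323
rs9000001	6	31000000	G	T	             0.3	         0.00776	         0.00156	        6.55e-07	977323
rs9000002	7	36000000	T	C	           0.413	         0.00817	         0.00145	        1.76e-08	977323
rs9000003	8	41000000	T	C	           0.809	        -0.01575	         0.00182	        4.98e-18	977323
rs9000004	9	46000000	A	G	           0.324	         0.00505	         0.00153	        0.000965	977323
rs9000005	10	51000000	G	A	           0.115	         0.01314	         0.00224	        4.46e-09	977323
rs9000006	11	56000000	A	C	           0.425	          0.0102	         0.00145	           2e-12	977323
rs9000007	12	61000000	A	C	           0.601	        -0.01143	         0.00146	        4.93e-15	977323
rs9000008	13	66000000	T	G	           0.155	         0.01443	         0.00198	        3.15e-13	977323
rs9000009	14	71000000	G	T	           0.241	         0.01244	         0.00167	         9.4e-14	977323
rs9000010	15	76000000	T	C	           0.202	         0.01502	         0.00178	        3.22e-17	977323
rs9000011	16	81000000	C	T	           0.378	          0.0136	         0.00148	        3.96e-20	977323
rs9000012	17	86000000	A	G	           0.123	          0.0142	         0.00218	        7.33e-11	977323
rs9000013	18	91000000	G	A	           0.151	         0.01529	           0.002	        2.09e-14	977323
rs9000014	19	96000000	A	C	           0.418	         0.01114	         0.00145	        1.56e-14	977323
rs9000015	20	101000000	C	A	           0.377	         0.00408	         0.00148	         0.00584	977323
rs9000016	21	106000000	T	G	            0.17	         0.00619	          0.0019	         0.00112	977323
rs3091307	4	21030000	C	A	           0.415	         0.01088	         0.00145	        6.22e-14	977323
rs1035127	5	26030000	T	G	           0.248	         0.01025	         0.00166	        6.63e-10	977323
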